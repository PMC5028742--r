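test_that("niche expansion is the Cartesian product of attribute sets", {
  tr <- data.frame(family = "FamA", category = "epifauna",
                   habitat = "intertidal", mobility = "sessile")
  n <- expand_niches(tr)
  expect_equal(nrow(n), 1)
  expect_equal(n$niche, "epifauna|intertidal|sessile")

  tr <- data.frame(family = "FamB", category = "infauna;epifauna",
                   habitat = "intertidal;subtidal", mobility = "motile")
  n <- expand_niches(tr)
  expect_equal(nrow(n), 4)   # 2 x 2 x 1
  expect_equal(length(unique(n$niche)), 4)

  bad <- data.frame(family = "FamC", category = "plankton",
                    habitat = "subtidal", mobility = "motile")
  expect_error(expand_niches(bad), "plankton")
})

test_that("niche-set cardinality follows the product rule on random tables", {
  study <- cached_study(7)
  niches <- expand_niches(study$traits)
  sets <- split(niches$niche, niches$family)
  for (i in seq_len(nrow(study$traits))) {
    f <- study$traits$family[i]
    expected <- lengths(split_tokens(study$traits$category[i])) *
      lengths(split_tokens(study$traits$habitat[i])) *
      lengths(split_tokens(study$traits$mobility[i]))
    expect_equal(length(sets[[f]]), unname(expected))
  }
  # never more niches than the attribute alphabets allow (5 x 4 x 2)
  expect_lte(length(unique(niches$niche)), 40)
})

test_that("niche richness collapses redundancy and matches brute-force unions", {
  tr <- data.frame(family = c("FamA", "FamB"),
                   category = c("epifauna", "epifauna"),
                   habitat = c("intertidal", "intertidal"),
                   mobility = c("sessile", "sessile"))
  niches <- expand_niches(tr)
  inc <- inc_from_sets(list(S1 = c("FamA", "FamB")))
  expect_equal(niche_richness(inc, niches)$richness, 1)  # shared niche counted once
  none <- inc_from_sets(list(S1 = "FamZ"))
  expect_equal(niche_richness(none, niches)$richness, 0)

  # brute-force union oracle on the synthetic trait table
  study <- cached_study(7)
  niches <- expand_niches(study$traits)
  fams <- study$traits$family
  set.seed(18)
  for (rep in 1:5) {
    present <- sample(fams, 12)
    inc <- inc_from_sets(list(S = present))
    oracle <- length(unique(niches$niche[niches$family %in% present]))
    expect_equal(niche_richness(inc, niches)$richness, oracle)
  }
})

test_that("niches per family measures redundancy", {
  tr <- data.frame(family = paste0("Fam", 1:4),
                   category = "infauna", habitat = "subtidal",
                   mobility = "sessile")
  niches <- expand_niches(tr)
  one <- inc_from_sets(list(S1 = "Fam1"))
  expect_equal(niches_per_family(one, niches)$niches_per_family, 1)
  all4 <- inc_from_sets(list(S1 = paste0("Fam", 1:4)))
  expect_equal(niches_per_family(all4, niches)$niches_per_family, 0.25)
  empty <- matrix(0L, 1, 4, dimnames = list("S1", paste0("Fam", 1:4)))
  expect_warning(res <- niches_per_family(empty, niches), "no classified family")
  expect_true(is.na(res$niches_per_family))
})

test_that("ordination separates clusters and conserves variance", {
  inc <- rbind(S1 = c(1, 1, 1, 0, 0, 0), S2 = c(1, 1, 1, 0, 0, 0),
               S3 = c(0, 0, 0, 1, 1, 1), S4 = c(0, 0, 0, 1, 1, 1))
  colnames(inc) <- paste0("n", 1:6)
  ord <- ordinate(inc)
  expect_equal(ord$scores["S1", 1], ord$scores["S2", 1])   # duplicates coincide
  expect_equal(ord$var_explained[1] / ord$total_variance, 1)  # axis 1 is everything
  expect_true(ord$scores["S1", 1] * ord$scores["S3", 1] < 0)

  set.seed(19)
  x <- matrix(rbinom(6 * 9, 1, 0.5), 6, 9,
              dimnames = list(paste0("S", 1:6), paste0("n", 1:9)))
  ord <- ordinate(x)
  direct <- sum(apply(x, 2, var))
  expect_equal(ord$total_variance, direct, tolerance = 1e-12)
  expect_equal(sum(ord$var_explained), direct, tolerance = 1e-12)
  expect_true(all(diff(ord$var_explained) <= 1e-12))

  flat <- matrix(1, 3, 4, dimnames = list(paste0("S", 1:3), paste0("n", 1:4)))
  expect_warning(zo <- ordinate(flat), "zero-variance")
  expect_true(zo$degenerate)
  expect_true(all(zo$scores == 0))
})
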