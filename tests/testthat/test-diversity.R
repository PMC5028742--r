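test_that("Jaccard distances match hand enumeration", {
  inc <- inc_from_sets(list(a = c("x", "y"), b = c("y", "z"),
                            c = c("x", "y"), d = c("q", "r")))
  d <- as.matrix(jaccard_matrix(inc))
  expect_equal(d["a", "b"], 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)
  expect_equal(attr(jaccard_matrix(inc), "metric"), "jaccard")
})

test_that("empty units get the conventional zero distance with a flag", {
  inc <- rbind(a = c(1L, 0L), b = c(0L, 0L), c = c(0L, 0L))
  colnames(inc) <- c("s1", "s2")
  d <- jaccard_matrix(inc)
  m <- as.matrix(d)
  expect_equal(m["b", "c"], 0)
  expect_equal(m["a", "b"], 1)
  expect_equal(attr(d, "n_empty_pairs"), 1L)
})

test_that("Jaccard is a metric on random incidence matrices", {
  set.seed(11)
  for (rep in 1:5) {
    inc <- matrix(rbinom(6 * 15, 1, 0.5), 6, 15,
                  dimnames = list(paste0("u", 1:6), paste0("s", 1:15)))
    m <- as.matrix(jaccard_matrix(inc))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
  }
})

test_that("Whittaker beta matches hand computations and its bounds", {
  same <- inc_from_sets(list(t1 = c("a", "b"), t2 = c("a", "b"), t3 = c("a", "b")))
  expect_equal(whittaker_beta(same), 0)
  disj <- inc_from_sets(list(t1 = "a", t2 = "b", t3 = "c"))
  expect_equal(whittaker_beta(disj), 2)   # maximum for 3 transects
  hand <- inc_from_sets(list(t1 = c("A", "B", "C"), t2 = c("A", "B", "D"),
                             t3 = c("A", "E")))
  expect_equal(whittaker_beta(hand), 5 / (8 / 3) - 1)  # = 0.875
  expect_equal(whittaker_beta(hand), 0.875)
  expect_equal(whittaker_beta(hand, variant = "ratio"), 1.875)
  expect_warning(expect_true(is.na(whittaker_beta(rbind(a = 0L, b = 0L)))),
                 "empty")
})

test_that("Whittaker beta is relabel-invariant and falls when a shared taxon is added", {
  set.seed(12)
  inc <- matrix(rbinom(3 * 12, 1, 0.4), 3, 12,
                dimnames = list(paste0("t", 1:3), paste0("s", 1:12)))
  inc[1, 1] <- 1
  shuffled <- inc[, sample(ncol(inc))]
  expect_equal(whittaker_beta(inc), whittaker_beta(shuffled))
  b0 <- whittaker_beta(inc)
  # add a taxon absent everywhere to all transects: S and alpha both grow,
  # beta strictly decreases (if it was positive)
  wider <- cbind(inc, new = 1L)
  expect_lt(whittaker_beta(wider), b0)
})

test_that("Raup-Crick worked cases behave as the null model predicts", {
  # both samples equal the full pool: every null draw ties -> exactly 0
  full <- rbind(a = rep(1L, 20), b = rep(1L, 20))
  colnames(full) <- paste0("s", 1:20)
  expect_equal(unname(as.matrix(raup_crick(full, n_null = 99, seed = 1))["a", "b"]), 0)

  # identical 10-taxon samples from a 200-taxon even pool: far more shared
  # than null draws -> strongly negative
  pool <- setNames(rep(1, 200), paste0("s", 1:200))
  ident <- matrix(0L, 2, 200, dimnames = list(c("a", "b"), names(pool)))
  ident[, 1:10] <- 1L
  expect_lt(unname(as.matrix(raup_crick(ident, n_null = 999, seed = 2,
                                        pool_freq = pool))["a", "b"]), -0.9)

  # disjoint 10-taxon samples against the observed pool: fewer shared than
  # almost any null draw -> strongly positive
  disj <- matrix(0L, 2, 20, dimnames = list(c("a", "b"), paste0("s", 1:20)))
  disj[1, 1:10] <- 1L; disj[2, 11:20] <- 1L
  expect_gt(unname(as.matrix(raup_crick(disj, n_null = 999, seed = 3))["a", "b"]),
            0.9)

  expect_error(raup_crick(rbind(a = rep(1L, 5), b = rep(1L, 5))[, 1:5],
                          pool_freq = c(s1 = 1)), "richer than")
})

test_that("Raup-Crick agrees with an independent r1 null-model simulation", {
  set.seed(9)
  x <- matrix(rbinom(5 * 40, 1, 0.4), 5, 40,
              dimnames = list(paste0("u", 1:5), paste0("s", 1:40)))
  mine <- as.matrix(raup_crick(x, n_null = 999, seed = 5))
  # same statistic computed on vegan's r1 null model (richness fixed,
  # species weighted by occurrence frequency)
  sims <- simulate(vegan::nullmodel(x, "r1"), nsim = 999, seed = 5)
  for (pair in list(c(1, 2), c(2, 4))) {
    a <- pair[1]; b <- pair[2]
    obs <- sum(x[a, ] & x[b, ])
    ss <- apply(sims, 3, function(m) sum(m[a, ] & m[b, ]))
    raw <- (sum(ss > obs) + 0.5 * sum(ss == obs)) / length(ss)
    expect_lt(abs(mine[a, b] - 2 * (raw - 0.5)), 0.15)
  }
})

test_that("Raup-Crick is centred near zero for samples drawn from its own null", {
  # calibration: when both communities really are frequency-weighted draws
  # at fixed richness, the rescaled score must be symmetric around 0
  set.seed(13)
  P <- 100
  freq <- setNames(sample(1:5, P, replace = TRUE), paste0("s", 1:P))
  vals <- vapply(1:30, function(i) {
    inc <- matrix(0L, 2, P, dimnames = list(c("a", "b"), names(freq)))
    inc[1, sample.int(P, 25, prob = freq)] <- 1L
    inc[2, sample.int(P, 30, prob = freq)] <- 1L
    unname(as.matrix(raup_crick(inc, n_null = 199, seed = 100 + i,
                                pool_freq = freq))["a", "b"])
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.2)
  expect_gt(max(vals), 0)
  expect_lt(min(vals), 0)
})

test_that("accumulation curves follow the bootstrap expectations", {
  # single site: curve point is that site's richness with zero spread
  one <- inc_from_sets(list(S1 = paste0("s", 1:7)))
  acc <- gamma_accumulation(one, n_boot = 50, seed = 1)
  expect_equal(acc$mean, 7)
  expect_equal(acc$sd, 0)
  # identical sites: flat curve
  same <- inc_from_sets(list(S1 = paste0("s", 1:5), S2 = paste0("s", 1:5),
                             S3 = paste0("s", 1:5)))
  acc <- gamma_accumulation(same, n_boot = 100, seed = 2)
  expect_true(all(acc$mean == 5))
  # disjoint sites of equal richness: coupon-collector expectation
  # E[richness at m] = r * M * (1 - (1 - 1/M)^m)
  r <- 6; M <- 4
  disj <- inc_from_sets(lapply(setNames(1:M, paste0("S", 1:M)),
                               function(i) paste0("g", i, "_", 1:r)))
  acc <- gamma_accumulation(disj, n_boot = 2000, seed = 3)
  expected <- r * M * (1 - (1 - 1 / M)^acc$m)
  mc_se <- acc$sd / sqrt(2000)
  expect_true(all(abs(acc$mean - expected) <= 4 * mc_se + 1e-9))
  # means non-decreasing in m
  expect_true(all(diff(acc$mean) >= 0))
})

test_that("logarithmic curve fits recover exact and noisy coefficients", {
  m <- 1:8
  expect_equal(fit_log_curve(m, 2 + 3 * log(m)), c(a = 2, b = 3))
  expect_equal(fit_log_curve(m, rep(4.5, 8)), c(a = 4.5, b = 0))
  set.seed(14)
  reps <- t(vapply(1:50, function(i)
    fit_log_curve(m, 10 + 5 * log(m) + rnorm(8, 0, 0.5)), numeric(2)))
  expect_lt(abs(mean(reps[, "b"]) - 5), 2 * sd(reps[, "b"]) / sqrt(50))
  expect_error(fit_log_curve(1, 5), "two distinct")
})
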