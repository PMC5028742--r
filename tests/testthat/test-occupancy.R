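test_that("detection histories count positive replicates per bottle", {
  des <- make_toy_design(n_sites = 1, n_transects = 2, n_reps = 4)
  counts <- matrix(0L, 2, 8, dimnames = list(c("o1", "o2"), des$replicate_id))
  counts["o1", c("S1_T1_R1", "S1_T1_R3")] <- c(5L, 2L)
  h <- detection_histories(counts, des)
  expect_equal(unname(h$y["o1", ]), c(2L, 0L))
  expect_equal(unname(h$y["o2", ]), c(0L, 0L))
  expect_equal(unname(h$K), c(4L, 4L))
})

test_that("histories record the surviving replicate count for ragged bottles", {
  des <- make_toy_design(n_sites = 1, n_transects = 2, n_reps = 4)
  counts <- matrix(1L, 1, 8, dimnames = list("o1", des$replicate_id))
  counts <- counts[, -2, drop = FALSE]   # one replicate lost to QC
  h <- detection_histories(counts, des)
  expect_equal(unname(h$K), c(3L, 4L))
  expect_equal(unname(h$y["o1", ]), c(3L, 4L))
  # replicate absent from design is a hard error
  colnames(counts)[1] <- "mystery"
  expect_error(detection_histories(counts, des), "mystery")
})

test_that("saturated detection drives psi and the posteriors to 1", {
  fit <- fit_occupancy(rep(4, 12), K = 4)
  expect_gt(fit$estimates$psi, 0.99)
  expect_true(all(fit$posterior > 0.99))
})

test_that("posterior matches independent Bayes arithmetic and is monotone in y", {
  # hand computation for (psi=0.5, p11=0.8, p10=0.05, y=1, K=4)
  num <- 0.5 * choose(4, 1) * 0.8 * 0.2^3
  den <- num + 0.5 * choose(4, 1) * 0.05 * 0.95^3
  expect_equal(occupancy_posterior(0.5, 0.8, 0.05, 1, 4), num / den,
               tolerance = 1e-12)
  expect_equal(round(num / den, 3), 0.13)
  # non-decreasing in y whenever p11 > p10
  for (p in list(c(0.5, 0.8, 0.05), c(0.2, 0.6, 0.3), c(0.9, 0.99, 0.001))) {
    post <- occupancy_posterior(p[1], p[2], p[3], 0:4, 4)
    expect_true(all(diff(post) >= 0))
  }
  # p10 = 0: any detection is conclusive
  expect_equal(occupancy_posterior(0.3, 0.7, 0, 1:4, 4), rep(1, 4))
})

test_that("occupancy estimates recover known parameters on simulated bottles", {
  err <- t(vapply(1:5, function(s) {
    set.seed(s)
    z <- rbinom(500, 1, 0.6)
    y <- rbinom(500, 4, ifelse(z == 1, 0.8, 0.05))
    e <- fit_occupancy(y, K = 4)$estimates
    abs(c(e$psi, e$p11, e$p10) - c(0.6, 0.8, 0.05))
  }, numeric(3)))
  expect_true(all(apply(err, 2, median) < 0.05))
})

test_that("posterior filtering honours the threshold limits", {
  study <- cached_study(7)
  h <- detection_histories(study$counts, study$design)
  fit <- fit_occupancy(h)
  ident <- filter_by_posterior(study$counts, study$design, fit, threshold = 0)
  expect_equal(unname(sum(attr(ident, "removed"))), 0)
  expect_true(all(ident == study$counts))
  strict <- filter_by_posterior(study$counts, study$design, fit, threshold = 1)
  # every imperfect posterior is zeroed: only cells with posterior exactly 1 survive
  post <- fit$posterior[rownames(study$counts), ]
  bot <- study$design$bottle[match(colnames(study$counts), study$design$replicate_id)]
  surviving <- strict > 0
  expect_true(all(post[, bot][surviving] >= 1))
})

test_that("decontamination removes injected contamination, not true detections", {
  study <- cached_study(7)   # fixture: p11 = 0.9, p10 = 0.02
  h <- detection_histories(study$counts, study$design)
  fit <- fit_occupancy(h)
  filt <- filter_by_posterior(study$counts, study$design, fit, threshold = 0.8)
  bot <- study$design$bottle[match(colnames(study$counts), study$design$replicate_id)]
  zc <- study$truth$z[rownames(study$counts), bot]
  fp_before <- sum(study$counts > 0 & !zc)
  fp_after <- sum(filt > 0 & !zc)
  tp_before <- sum(study$counts > 0 & zc)
  tp_after <- sum(filt > 0 & zc)
  expect_gte(1 - fp_after / fp_before, 0.9)
  expect_lt(1 - tp_after / tp_before, 0.05)
})

test_that("filtering then rarefying never exceeds the original counts", {
  study <- cached_study(7)
  h <- detection_histories(study$counts, study$design)
  fit <- fit_occupancy(h)
  filt <- filter_by_posterior(study$counts, study$design, fit, 0.8)
  expect_true(all(filt <= study$counts))
  rs <- rarefy_counts(filt, depth = min(colSums(filt)), n_draws = 2, seed = 1)
  for (d in rs$draws) expect_true(all(d <= filt[, colnames(d)]))
})
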