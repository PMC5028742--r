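test_that("identical config and seed give byte-identical studies", {
  cfg <- sim_config(pool_size = 150, richness_intercept = 40,
                    richness_slope = 1, depth_mean = 1500, family_count = 30)
  s1 <- simulate_study(cfg, seed = 3)
  s2 <- simulate_study(cfg, seed = 3)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$taxonomy, s2$taxonomy)
  expect_identical(s1$traits, s2$traits)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in c("counts.tsv", "design.tsv", "taxonomy.tsv", "traits.tsv",
              "truth_summary.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("emitted tables pass the io validations and match the truth", {
  study <- cached_study(7)
  expect_silent(as_count_matrix(study$counts))
  expect_s3_class(study$design, "edna_design")
  expect_silent(validate_traits(study$traits))
  expect_true(design_summary(study$design)$paired_ok)
  # every detection is a true presence or a logged contamination event
  tr <- study$truth
  bot <- study$design$bottle[match(colnames(study$counts),
                                   study$design$replicate_id)]
  zc <- tr$z[rownames(study$counts), bot]
  fp <- which((study$counts > 0) & !zc, arr.ind = TRUE)
  ev <- paste(tr$contam_events$replicate_id, tr$contam_events$otu_id)
  got <- paste(colnames(study$counts)[fp[, 2]], rownames(study$counts)[fp[, 1]])
  expect_true(all(got %in% ev))
})

test_that("degenerate detection settings give all-or-nothing histories", {
  # equal abundances + ample depth so every amplified taxon yields reads
  cfg <- sim_config(pool_size = 100, richness_intercept = 30,
                    richness_slope = 0.5, depth_mean = 5000,
                    abund_sdlog = 0, p11 = 1, p10 = 0)
  study <- simulate_study(cfg, seed = 2)
  h <- detection_histories(study$counts, study$design)
  present <- study$truth$z[rownames(study$counts), h$bottles]
  expect_true(all(h$y[present] == 4))
  expect_true(all(h$y[!present] == 0))
})

test_that("theta = 1 makes transects identical to the site pool (beta 0)", {
  cfg <- sim_config(pool_size = 100, richness_intercept = 30,
                    richness_slope = 0.5, depth_mean = 2000,
                    theta_intercept = 1, theta_slope = 0)
  study <- simulate_study(cfg, seed = 4)
  ts <- truth_summary(study$truth)
  expect_true(all(ts$beta == 0))
})

test_that("true diversity summaries match hand enumeration", {
  # three identical transects of 10 taxa
  taxa <- paste0("t", 1:10)
  truth <- list(communities = list(b1 = taxa, b2 = taxa, b3 = taxa),
                bottle_site = c(b1 = "S1", b2 = "S1", b3 = "S1"))
  ts <- truth_summary(truth)
  expect_equal(ts$alpha, 10)
  expect_equal(ts$beta, 0)
  expect_equal(ts$gamma, 10)
  # three disjoint transects of 10 taxa: gamma 30, beta = S/mean(alpha) - 1 = 2
  truth <- list(communities = list(b1 = paste0("a", 1:10), b2 = paste0("b", 1:10),
                                   b3 = paste0("c", 1:10)),
                bottle_site = c(b1 = "S1", b2 = "S1", b3 = "S1"))
  ts <- truth_summary(truth)
  expect_equal(ts$gamma, 30)
  expect_equal(ts$beta, 2)
  # empty site flagged
  truth <- list(communities = list(b1 = character(0), b2 = character(0)),
                bottle_site = c(b1 = "S1", b2 = "S1"))
  ts <- truth_summary(truth)
  expect_true(ts$empty)
  expect_equal(ts$alpha, 0)
})

test_that("emitted contamination rate converges to p10", {
  cfg <- sim_config(pool_size = 300, richness_intercept = 60,
                    richness_slope = 1, depth_mean = 50000,
                    p10 = 0.02, contam_weight = 0.05)
  study <- simulate_study(cfg, seed = 5)
  # realized_p10 is measured on emitted false detections over absent slots
  n_slots <- with(study$truth, length(psi) * ncol(study$counts) -
                    sum(z[, study$design$bottle[match(colnames(study$counts),
                                                      study$design$replicate_id)]]))
  se <- sqrt(0.02 * 0.98 / n_slots)
  expect_lt(abs(study$truth$realized_p10 - 0.02), 3 * se + 0.002)
})

test_that("richness slope increases expected true site richness monotonically", {
  lo <- simulate_study(sim_config(pool_size = 500, richness_intercept = 50,
                                  richness_slope = 1, depth_mean = 1000), seed = 6)
  hi <- simulate_study(sim_config(pool_size = 500, richness_intercept = 50,
                                  richness_slope = 5, depth_mean = 1000), seed = 6)
  expect_true(all(hi$truth$sites$pool_richness >= lo$truth$sites$pool_richness))
  expect_gt(mean(hi$truth$sites$pool_richness), mean(lo$truth$sites$pool_richness))
})

test_that("invalid detection probabilities are rejected", {
  expect_error(sim_config(p11 = 0.5, p10 = 0.5), "p10 < p11")
  expect_error(sim_config(p11 = 0.2, p10 = 0.4), "p10 < p11")
})
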