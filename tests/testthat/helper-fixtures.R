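# shared fixture builders; everything is generated in code at test time

# nested toy design: sites x transects x reps, one bottle per transect;
# returned pre-validated (odd site counts deliberately leave a pair
# incomplete, so that warning is muffled here)
make_toy_design <- function(n_sites = 2, n_transects = 2, n_reps = 2,
                            imperv = NULL) {
  if (is.null(imperv)) imperv <- seq(5, 50, length.out = n_sites)
  rows <- expand.grid(pcr_rep = seq_len(n_reps),
                      transect = paste0("T", seq_len(n_transects)),
                      site = paste0("S", seq_len(n_sites)),
                      stringsAsFactors = FALSE)
  rows$bottle <- paste(rows$site, rows$transect, sep = "_")
  rows$replicate_id <- paste(rows$bottle, rows$pcr_rep, sep = "_R")
  pair_of <- paste0("p", ceiling(seq_len(n_sites) / 2))
  rows$pair <- pair_of[match(rows$site, paste0("S", seq_len(n_sites)))]
  rows$urban <- rep(c("less", "more"), length.out = n_sites)[
    match(rows$site, paste0("S", seq_len(n_sites)))]
  rows$imperviousness <- imperv[match(rows$site, paste0("S", seq_len(n_sites)))]
  rows <- rows[, c("replicate_id", "site", "pair", "urban", "transect",
                   "bottle", "pcr_rep", "imperviousness")]
  suppressWarnings(validate_design(rows))
}

# incidence matrix from a named list of taxon vectors
inc_from_sets <- function(sets) {
  taxa <- sort(unique(unlist(sets)))
  out <- matrix(0L, length(sets), length(taxa),
                dimnames = list(names(sets), taxa))
  for (i in seq_along(sets)) out[i, sets[[i]]] <- 1L
  out
}

# memoized reduced-size synthetic studies / pipeline bundle shared by tests
.fixture_env <- new.env(parent = emptyenv())

cached_study <- function(seed = 7) {
  key <- paste0("study", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_study(fixture_config(), seed = seed)
  .fixture_env[[key]]
}

cached_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    study <- cached_study(7)
    cfg <- pipeline_config(study$counts, study$design, study$taxonomy,
                           study$traits, out_dir = tempfile("bundle_"),
                           n_draws = 5, n_perm = 199, n_null = 99,
                           n_boot = 100, seed = 11)
    .fixture_env$bundle <- run_pipeline(cfg)
  }
  .fixture_env$bundle
}

# brute-force nested SS partition from pairwise squared distances
brute_force_partition <- function(d, site, transect) {
  m <- as.matrix(d)
  n <- nrow(m)
  pairsum <- function(idx) {
    mm <- m[idx, idx, drop = FALSE]
    sum(mm[upper.tri(mm)]^2) / length(idx)
  }
  ss_total <- sum(m[upper.tri(m)]^2) / n
  within <- function(groups) sum(vapply(unique(groups), function(g)
    pairsum(which(groups == g)), numeric(1)))
  ws <- within(site)
  wt <- within(transect)
  c(site = ss_total - ws, transect = ws - wt, residual = wt, total = ss_total)
}
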