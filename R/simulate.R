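# synthetic_data: replicated eDNA count tables with the statistical
# structure the analysis assumes, plus ground truth for recovery tests.
#
# Generative model, top down:
#  * n_pairs site pairs; per pair one less-urban site with imperviousness
#    drawn U[1, 10]% and one more-urban site drawn U[25, 60]%;
#  * regional pool of pool_size OTUs with lognormal relative abundances;
#  * site species pool of size round(richness_intercept +
#    richness_slope * imperviousness), sampled from the regional pool with
#    probability proportional to abundance (common taxa recur across
#    sites);
#  * each transect (= one bottle) draws its true community by including
#    each site-pool member independently with probability theta, the
#    transect-inclusion parameter: theta = 1 makes the transects identical
#    to the site pool (within-site Whittaker beta 0), small theta makes
#    them sparse, heterogeneous subsets (beta near its maximum). theta =
#    clamp(theta_intercept + theta_slope * imperviousness, theta_bounds),
#    and a positive theta_slope therefore homogenizes urban sites;
#  * each PCR replicate amplifies each truly present OTU with probability
#    p11 and picks up each absent pool OTU as contamination with
#    probability p10 (events logged in the truth); reads are then drawn
#    multinomially at a lognormal per-replicate depth, present taxa
#    weighted by their lognormal abundances and contaminants by the small
#    uniform mass contam_weight.
#
# Everything is deterministic given (config, seed).

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the motivating field design: 4 site pairs x 3
#' transects x 4 PCR replicates, a ~2000-OTU regional pool, per-replicate
#' depths around 1.5e5 reads, and gradient effects (richness rising,
#' within-site beta falling with imperviousness) of the magnitude seen in
#' urbanized nearshore eDNA surveys.
#'
#' @param n_pairs number of more/less-urban site pairs.
#' @param transects_per_site transects (= water samples) per site.
#' @param pcr_reps K, PCR replicates per water sample.
#' @param pool_size regional OTU pool size.
#' @param imperv_less,imperv_more uniform ranges (%) for less-/more-urban
#'   imperviousness.
#' @param richness_intercept,richness_slope site-pool richness
#'   a + b * imperviousness.
#' @param theta_intercept,theta_slope,theta_bounds transect-inclusion
#'   probability theta = a + b * imperviousness, clamped to `theta_bounds`;
#'   theta = 1 means every transect carries the full site pool.
#' @param p11 per-replicate true-detection (amplification) probability.
#' @param p10 per-replicate false-positive (contamination) probability;
#'   must satisfy 0 <= p10 < p11 <= 1.
#' @param depth_mean,depth_sdlog lognormal read-depth distribution per
#'   replicate.
#' @param abund_meanlog,abund_sdlog lognormal OTU relative-abundance
#'   parameters.
#' @param contam_weight relative read mass of one contaminant OTU.
#' @param family_count,annotated_frac number of synthetic families and the
#'   fraction of OTUs annotated to family level.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 4, transects_per_site = 3, pcr_reps = 4,
                       pool_size = 2000,
                       imperv_less = c(1, 10), imperv_more = c(25, 60),
                       richness_intercept = 400, richness_slope = 8,
                       theta_intercept = 0.45, theta_slope = 0.005,
                       theta_bounds = c(0.05, 1),
                       p11 = 0.9, p10 = 0.02,
                       depth_mean = 150000, depth_sdlog = 0.1,
                       abund_meanlog = 0, abund_sdlog = 1.2,
                       contam_weight = 0.01,
                       family_count = 150, annotated_frac = 0.8) {
  cfg <- as.list(environment())
  if (!(p10 >= 0 && p10 < p11 && p11 <= 1))
    stop("need 0 <= p10 < p11 <= 1")
  if (n_pairs < 1 || transects_per_site < 1 || pcr_reps < 1 || pool_size < 1)
    stop("design dimensions must be positive")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  structure(cfg, class = "sim_config")
}

# hierarchical synthetic taxonomy: phylum > class > order > family
make_taxonomy <- function(otu_ids, family_count, annotated_frac) {
  n_phyla <- 8; n_classes <- 16; n_orders <- 40
  fam <- sprintf("Fam%03d", seq_len(family_count))
  ord_of_fam <- sprintf("Ord%02d", 1 + (seq_len(family_count) %% n_orders))
  cls_of_ord <- sprintf("Cls%02d", 1 + (seq_len(n_orders) %% n_classes))
  phy_of_cls <- sprintf("Phy%d", 1 + (seq_len(n_classes) %% n_phyla))
  fam_of_otu <- sample(fam, length(otu_ids), replace = TRUE)
  annotated <- runif(length(otu_ids)) < annotated_frac
  ord <- ord_of_fam[match(fam_of_otu, fam)]
  cls <- cls_of_ord[as.integer(sub("Ord", "", ord))]
  phy <- phy_of_cls[as.integer(sub("Cls", "", cls))]
  data.frame(otu_id = otu_ids, phylum = phy, class = cls, order = ord,
             family = ifelse(annotated, fam_of_otu, NA_character_),
             stringsAsFactors = FALSE)
}

make_traits <- function(families) {
  pick <- function(alphabet) {
    k <- sample(1:2, 1)
    paste(sort(sample(alphabet, k)), collapse = ";")
  }
  data.frame(
    family = families,
    category = vapply(families, function(f) pick(trait_alphabets$category), character(1)),
    habitat = vapply(families, function(f) pick(trait_alphabets$habitat), character(1)),
    mobility = vapply(families, function(f) pick(trait_alphabets$mobility), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Generate a synthetic paired-design eDNA study
#'
#' Produces an OTU x replicate count table, validated design, taxonomy,
#' family trait table, and a `sim_truth` object holding the latent states
#' (site pools, transect communities, contamination events, realized
#' detection rates) that parameter-recovery tests compare against.
#' Deterministic given `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with elements `counts`, `design`, `taxonomy`, `traits`,
#'   `truth`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cfg <- config

  otu_ids <- sprintf("OTU_%04d", seq_len(cfg$pool_size))
  abund <- rlnorm(cfg$pool_size, cfg$abund_meanlog, cfg$abund_sdlog)
  names(abund) <- otu_ids

  sites <- data.frame(
    site = paste0("P", rep(seq_len(cfg$n_pairs), each = 2), c("L", "M")),
    pair = paste0("pair", rep(seq_len(cfg$n_pairs), each = 2)),
    urban = rep(c("less", "more"), cfg$n_pairs),
    stringsAsFactors = FALSE
  )
  sites$imperviousness <- ifelse(
    sites$urban == "less",
    runif(nrow(sites), cfg$imperv_less[1], cfg$imperv_less[2]),
    runif(nrow(sites), cfg$imperv_more[1], cfg$imperv_more[2])
  )
  sites$imperviousness <- round(sites$imperviousness, 2)
  sites$theta <- clamp(cfg$theta_intercept + cfg$theta_slope * sites$imperviousness,
                       cfg$theta_bounds[1], cfg$theta_bounds[2])
  sites$pool_richness <- pmin(cfg$pool_size,
                              pmax(1L, round(cfg$richness_intercept +
                                             cfg$richness_slope * sites$imperviousness)))

  site_pools <- list()
  communities <- list()   # per bottle: character vector of truly present OTUs
  design_rows <- list()
  count_cols <- list()
  contam_events <- list()

  for (s in seq_len(nrow(sites))) {
    sp <- sample(otu_ids, sites$pool_richness[s], prob = abund)
    site_pools[[sites$site[s]]] <- sort(sp)
    for (t in seq_len(cfg$transects_per_site)) {
      bottle <- sprintf("%s_T%d", sites$site[s], t)
      present <- sp[runif(length(sp)) < sites$theta[s]]
      communities[[bottle]] <- sort(present)
      absent <- setdiff(otu_ids, present)
      for (r in seq_len(cfg$pcr_reps)) {
        rep_id <- sprintf("%s_R%d", bottle, r)
        design_rows[[rep_id]] <- data.frame(
          replicate_id = rep_id, site = sites$site[s], pair = sites$pair[s],
          urban = sites$urban[s], transect = sprintf("T%d", t),
          bottle = bottle, pcr_rep = r,
          imperviousness = sites$imperviousness[s], stringsAsFactors = FALSE
        )
        amplified <- present[runif(length(present)) < cfg$p11]
        contam <- absent[runif(length(absent)) < cfg$p10]
        if (length(contam))
          contam_events[[length(contam_events) + 1L]] <- data.frame(
            replicate_id = rep_id, bottle = bottle, otu_id = contam,
            stringsAsFactors = FALSE)
        active <- c(amplified, contam)
        wts <- c(abund[amplified], rep(cfg$contam_weight, length(contam)))
        depth <- max(1L, round(rlnorm(1, log(cfg$depth_mean), cfg$depth_sdlog)))
        col <- integer(cfg$pool_size)
        names(col) <- otu_ids
        if (length(active))
          col[active] <- drop(rmultinom(1, depth, wts))
        count_cols[[rep_id]] <- col
      }
    }
  }

  counts <- do.call(cbind, count_cols)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  counts <- as_count_matrix(counts)
  design <- validate_design(do.call(rbind, design_rows))
  rownames(design) <- NULL
  taxonomy <- make_taxonomy(rownames(counts), cfg$family_count, cfg$annotated_frac)
  traits <- make_traits(sort(unique(taxonomy$family[!is.na(taxonomy$family)])))

  contam_events <- if (length(contam_events)) {
    do.call(rbind, contam_events)
  } else {
    data.frame(replicate_id = character(0), bottle = character(0),
               otu_id = character(0), stringsAsFactors = FALSE)
  }

  bottles <- names(communities)
  z <- matrix(FALSE, cfg$pool_size, length(bottles),
              dimnames = list(otu_ids, bottles))
  for (b in bottles) z[communities[[b]], b] <- TRUE
  psi_true <- rowMeans(z)

  # realized per-replicate detection rates, measured on the emitted counts
  detected <- counts > 0
  bottle_of <- design$bottle[match(colnames(counts), design$replicate_id)]
  zc <- z[rownames(counts), bottle_of, drop = FALSE]  # presence per replicate
  realized_p11 <- sum(detected & zc) / sum(zc)
  false_detections <- sum(detected & !zc)
  total_absent_slots <- length(otu_ids) * ncol(counts) - sum(z[, bottle_of])
  realized_p10 <- false_detections / total_absent_slots

  truth <- structure(list(
    config = cfg, seed = as.integer(seed),
    sites = sites, site_pools = site_pools, communities = communities,
    bottle_site = setNames(sub("_T\\d+$", "", bottles), bottles),
    z = z, psi = psi_true, contam_events = contam_events,
    realized_p11 = realized_p11, realized_p10 = realized_p10,
    abundance = abund
  ), class = "sim_truth")

  list(counts = counts, design = design, taxonomy = taxonomy,
       traits = traits, truth = truth)
}

#' Per-site true diversity from the latent states
#'
#' Summaries computed directly from the simulated transect communities
#' (never from the observed counts): true mean transect richness (alpha),
#' within-site Whittaker beta, and pooled site richness (gamma). The
#' regional pooled richness over all sites is attached as attribute
#' `regional_gamma`.
#'
#' @param truth a `sim_truth`, or any list with `communities` (named list
#'   of per-bottle taxon vectors) and `bottle_site` (named site of each
#'   bottle).
#' @return data.frame `site`, `alpha`, `beta`, `gamma`, `empty` flag.
#' @export
truth_summary <- function(truth) {
  comm <- truth$communities
  bottle_site <- truth$bottle_site
  sites <- unique(unname(bottle_site))
  rows <- lapply(sites, function(s) {
    cs <- comm[names(bottle_site)[bottle_site == s]]
    alpha <- mean(lengths(cs))
    gamma <- length(unique(unlist(cs)))
    empty <- alpha == 0
    beta <- if (empty) 0 else gamma / alpha - 1
    data.frame(site = s, alpha = alpha, beta = beta, gamma = gamma,
               empty = empty, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "regional_gamma") <- length(unique(unlist(comm)))
  out
}

#' Write the five tables of a simulated study to a directory
#'
#' Writes `counts.tsv`, `design.tsv`, `taxonomy.tsv`, `traits.tsv`, the
#' true per-site diversity `truth_summary.tsv`, and `truth.json` (config,
#' seed, per-site latent parameters, contamination tally).
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(study$counts, file.path(dir, "counts.tsv"))
  write_design(study$design, file.path(dir, "design.tsv"))
  write_taxonomy(study$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_traits(study$traits, file.path(dir, "traits.tsv"))
  write_tsv(truth_summary(study$truth), file.path(dir, "truth_summary.tsv"))
  tr <- study$truth
  jsonlite::write_json(list(
    seed = tr$seed,
    config = tr$config[setdiff(names(tr$config), character(0))],
    sites = tr$sites,
    realized_p11 = tr$realized_p11,
    realized_p10 = tr$realized_p10,
    n_contamination_events = nrow(tr$contam_events)
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
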