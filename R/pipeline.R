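# pipeline_cli: orchestration of the full analysis with a single config,
# seeded reproducibility, a manifest, and a bundled synthetic fixture.
#
# Stage order is fixed: decontaminate -> rarefy -> collapse replicates ->
# diversity (alpha, beta, Raup-Crick, gamma, PERMANOVA) -> family collapse
# -> traits -> association.

#' Pipeline configuration
#'
#' Inputs may be in-memory objects (count matrix, design data.frame, ...)
#' or paths to their TSV representations; paths are loaded and validated at
#' run time, before any computation. Stage seeds are all derived from the
#' single `seed`, and recorded in the output manifest.
#'
#' @param counts count matrix or TSV path.
#' @param design design data.frame or TSV path.
#' @param taxonomy,traits taxonomy/trait tables or paths; both required
#'   for family- and niche-level analyses (`family_level = TRUE`).
#' @param out_dir output directory for the result bundle.
#' @param threshold posterior retention threshold for decontamination.
#' @param depth rarefaction depth: `"auto"` (smallest replicate total) or
#'   an integer.
#' @param n_draws rarefaction draws; `representative` selects the draw
#'   reported for single-dataset results.
#' @param n_perm PERMANOVA permutations.
#' @param n_null Raup-Crick null draws.
#' @param n_boot accumulation-curve bootstrap draws.
#' @param alpha significance threshold for per-OTU associations.
#' @param family_level run family/niche analyses (needs taxonomy+traits).
#' @param seed master integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, taxonomy = NULL, traits = NULL,
                            out_dir = tempfile("edna_run_"),
                            threshold = 0.8, depth = "auto",
                            n_draws = 100, representative = 1,
                            n_perm = 999, n_null = 999, n_boot = 1000,
                            alpha = 0.01,
                            family_level = !is.null(taxonomy) && !is.null(traits),
                            seed = 1) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (n_draws < 1 || representative < 1 || representative > n_draws)
    stop("invalid rarefaction draw settings")
  if (n_perm < 1 || n_null < 99 || n_boot < 1) stop("permutation/null counts out of bounds")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_input <- function(x, loader) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop(sprintf("input file not found: %s", x))
    loader(x)
  } else x
}

stage_seed <- function(seed, stage) {
  offsets <- c(rarefy = 101L, raupcrick = 211L, gamma = 307L,
               permanova = 401L, simulate = 503L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full decontamination-to-association pipeline
#'
#' Executes all stages in fixed order, writing a manifest first and every
#' stage result as TSV/JSON under `config$out_dir`. Result files are
#' deterministic given config and inputs; the manifest records their md5
#' hashes. A failing stage aborts with the stage name; the manifest of
#' completed stages is still on disk.
#'
#' @param config a [pipeline_config()].
#' @return object of class `edna_bundle`: list of all stage results plus
#'   `files` (paths) and `hashes`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] stage=%s %s\n", format(Sys.time(), "%H:%M:%S"), stage, msg),
        file = log_path, append = TRUE)
  }
  stage <- "preflight"
  res <- list()
  tryCatch({
    counts <- resolve_input(cfg$counts, load_count_table)
    counts <- as_count_matrix(counts)
    design <- resolve_input(cfg$design, load_design)
    design <- if (inherits(design, "edna_design")) design else validate_design(design)
    taxonomy <- traits <- NULL
    if (cfg$family_level) {
      if (is.null(cfg$taxonomy) || is.null(cfg$traits))
        stop("family-level metrics requested but taxonomy/traits missing")
      taxonomy <- resolve_input(cfg$taxonomy, load_taxonomy)
      traits <- validate_traits(resolve_input(cfg$traits, load_traits))
    }
    st <- site_table(design)

    manifest <- list(
      package = "ednadiv",
      version = as.character(utils::packageVersion("ednadiv")),
      seed = cfg$seed,
      stage_seeds = list(rarefy = stage_seed(cfg$seed, "rarefy"),
                         raupcrick = stage_seed(cfg$seed, "raupcrick"),
                         gamma = stage_seed(cfg$seed, "gamma"),
                         permanova = stage_seed(cfg$seed, "permanova")),
      settings = cfg[c("threshold", "depth", "n_draws", "representative",
                       "n_perm", "n_null", "n_boot", "alpha", "family_level")],
      design = design_summary(design)
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    log_line("preflight", sprintf("replicates=%d otus=%d", ncol(counts), nrow(counts)))

    stage <- "decontaminate"
    hist <- detection_histories(counts, design)
    fit <- fit_occupancy(hist)
    filtered <- filter_by_posterior(counts, design, fit, cfg$threshold)
    write_tsv(fit$estimates, file.path(out, "occupancy_estimates.tsv"))
    write_count_table(filtered, file.path(out, "filtered_counts.tsv"))
    res$occupancy <- fit
    res$filtered_counts <- filtered
    log_line(stage, sprintf("removed_detections=%d", sum(attr(filtered, "removed"))))

    stage <- "rarefy"
    rs <- rarefy_counts(filtered, depth = cfg$depth, n_draws = cfg$n_draws,
                        seed = stage_seed(cfg$seed, "rarefy"),
                        representative = cfg$representative)
    rep_draw <- representative_draw(rs)
    write_count_table(rep_draw, file.path(out, "rarefied_representative.tsv"))
    draw_richness <- vapply(rs$draws, function(d) sum(rowSums(d) > 0), numeric(1))
    write_tsv(data.frame(draw = seq_along(draw_richness),
                         total_richness = draw_richness),
              file.path(out, "rarefaction_draw_richness.tsv"))
    res$rarefied <- rs
    res$draw_richness <- draw_richness
    log_line(stage, sprintf("depth=%d draws=%d", rs$depth, cfg$n_draws))

    stage <- "collapse_replicates"
    coll <- collapse_replicates(rep_draw, design)
    res$bottle <- coll
    write_tsv(matrix_to_df(coll$incidence, "bottle"),
              file.path(out, "bottle_incidence.tsv"))
    log_line(stage, sprintf("bottles=%d", nrow(coll$incidence)))

    stage <- "diversity"
    alpha_tab <- site_alpha(coll$incidence, design)
    alpha_fit <- site_mean_regression(alpha_tab$richness, alpha_tab$imperviousness)

    # within-site beta per rarefaction draw (the across-draw analysis),
    # plus the representative draw on its own
    beta_draws <- lapply(rs$draws, function(d) {
      beta_by_site(collapse_replicates(d, design)$incidence, design)$beta
    })
    beta_mat <- do.call(cbind, beta_draws)
    beta_tab <- beta_by_site(coll$incidence, design)
    beta_tab$beta_mean_draws <- rowMeans(beta_mat)
    beta_fit <- site_mean_regression(beta_tab$beta_mean_draws,
                                     beta_tab$imperviousness)
    beta_fit_rep <- site_mean_regression(beta_tab$beta, beta_tab$imperviousness)

    rc_tab <- raup_crick_by_site(coll$incidence, design, n_null = cfg$n_null,
                                 seed = stage_seed(cfg$seed, "raupcrick"))

    sinc <- site_incidence(coll$incidence, design)
    acc <- list()
    gseed <- stage_seed(cfg$seed, "gamma")
    sets <- list(all = st$site,
                 less = st$site[st$urban == "less"],
                 more = st$site[st$urban == "more"])
    for (nm in names(sets)) {
      sub <- sinc[rownames(sinc) %in% sets[[nm]], , drop = FALSE]
      curve <- gamma_accumulation(sub, n_boot = cfg$n_boot, seed = gseed)
      acc[[nm]] <- list(curve = curve,
                        log_fit = if (nrow(curve) > 1) fit_log_curve(curve) else NULL,
                        gamma = sum(colSums(sub) > 0))
    }

    rep_inc <- as_incidence(t(rep_draw))
    dj <- jaccard_matrix(rep_inc)
    perm <- permanova_nested(dj, design, n_perm = cfg$n_perm,
                             seed = stage_seed(cfg$seed, "permanova"))

    res$alpha <- alpha_tab; res$alpha_fit <- alpha_fit
    res$beta <- beta_tab; res$beta_fit <- beta_fit; res$beta_fit_rep <- beta_fit_rep
    res$raup_crick <- rc_tab
    res$accumulation <- acc
    res$permanova <- perm
    write_tsv(alpha_tab, file.path(out, "alpha_site.tsv"))
    write_tsv(beta_tab, file.path(out, "beta_site.tsv"))
    write_tsv(rc_tab, file.path(out, "raup_crick_site.tsv"))
    write_tsv(as.data.frame(perm), file.path(out, "permanova.tsv"))
    for (nm in names(acc))
      write_tsv(acc[[nm]]$curve, file.path(out, sprintf("accumulation_%s.tsv", nm)))
    log_line(stage, sprintf("alpha_slope=%.4f beta_slope=%.4f",
                            alpha_fit$slope, beta_fit$slope))

    if (cfg$family_level) {
      stage <- "family_collapse"
      fam_inc <- collapse_to_family(coll$incidence, taxonomy)
      fam_site <- site_incidence(fam_inc, design)
      fam_alpha <- site_alpha(fam_inc, design)
      fam_fit <- site_mean_regression(fam_alpha$richness, fam_alpha$imperviousness)
      res$family_incidence <- fam_inc
      res$family_alpha <- fam_alpha; res$family_fit <- fam_fit
      write_tsv(fam_alpha, file.path(out, "alpha_family_site.tsv"))
      log_line(stage, sprintf("families=%d dropped_otus=%d",
                              ncol(fam_inc), attr(fam_inc, "n_dropped")))

      stage <- "traits"
      niches <- expand_niches(traits)
      nr <- niche_richness(fam_site, niches)
      npf <- suppressWarnings(niches_per_family(fam_site, niches))
      trait_tab <- st
      trait_tab$niche_richness <- nr$richness[match(st$site, nr$unit)]
      trait_tab$niches_per_family <-
        npf$niches_per_family[match(st$site, npf$unit)]
      niche_fit <- site_mean_regression(trait_tab$niche_richness,
                                        trait_tab$imperviousness)
      ord <- ordinate(niche_incidence(fam_site, niches))
      res$niches <- niches; res$trait_table <- trait_tab
      res$niche_fit <- niche_fit; res$ordination <- ord
      write_tsv(trait_tab, file.path(out, "niche_site.tsv"))
      log_line(stage, sprintf("niches=%d", length(unique(niches$niche))))
    }

    stage <- "association"
    assoc <- logistic_association(coll$incidence,
                                  design$imperviousness[match(rownames(coll$incidence),
                                                              design$bottle)])
    assoc_sig <- assoc[!is.na(assoc$p_value) & assoc$p_value < cfg$alpha, ]
    res$association <- assoc
    res$association_counts <- c(positive = sum(assoc_sig$direction > 0),
                                negative = sum(assoc_sig$direction < 0))
    write_tsv(assoc, file.path(out, "association_otu.tsv"))
    log_line(stage, sprintf("positive=%d negative=%d",
                            res$association_counts[["positive"]],
                            res$association_counts[["negative"]]))

    files <- list.files(out, full.names = TRUE)
    files <- setdiff(files, log_path)
    hashes <- tools::md5sum(sort(files))
    jsonlite::write_json(as.list(hashes), file.path(out, "hashes.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$config <- cfg
    res$design <- design
    res$site_table <- st
    res$files <- sort(files)
    res$hashes <- hashes
    class(res) <- "edna_bundle"
    res
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Human-readable summary of a pipeline bundle
#'
#' Per-site table (alpha at OTU and family level, within-site Whittaker
#' beta, niche richness, niches per family), variance partition, and
#' association counts at the configured significance threshold. Pure: the
#' same bundle always yields the same report.
#'
#' @param bundle an `edna_bundle` from [run_pipeline()].
#' @return character vector of report lines (also printed invisibly).
#' @export
pipeline_report <- function(bundle) {
  stopifnot(inherits(bundle, "edna_bundle"))
  st <- bundle$site_table
  lines <- c(
    "eDNA diversity pipeline report",
    sprintf("sites: %d in %d pairs; bottles: %d; replicates: %d",
            design_summary(bundle$design)$n_sites,
            design_summary(bundle$design)$n_pairs,
            design_summary(bundle$design)$n_bottles,
            design_summary(bundle$design)$n_replicates),
    ""
  )
  tab <- st
  tab$alpha_otu <- bundle$alpha$richness[match(st$site, bundle$alpha$site)]
  if (!is.null(bundle$family_alpha))
    tab$alpha_family <- bundle$family_alpha$richness[match(st$site, bundle$family_alpha$site)]
  tab$beta_w <- bundle$beta$beta[match(st$site, bundle$beta$site)]
  if (!is.null(bundle$trait_table)) {
    tab$niche_richness <- bundle$trait_table$niche_richness[match(st$site, bundle$trait_table$site)]
    tab$niches_per_family <- round(bundle$trait_table$niches_per_family[match(st$site, bundle$trait_table$site)], 3)
  }
  hdr <- paste(names(tab), collapse = "\t")
  body <- apply(tab, 1, function(r) paste(r, collapse = "\t"))
  lines <- c(lines, hdr, body, "")
  pv <- bundle$permanova
  lines <- c(lines, "variance partition (Jaccard, nested PERMANOVA):",
             sprintf("  among sites: %.1f%%; transects within sites: %.1f%%; PCR replicates: %.1f%%",
                     pv$pct[pv$stratum == "site"],
                     pv$pct[pv$stratum == "transect_within_site"],
                     pv$pct[pv$stratum == "residual"]))
  lines <- c(lines,
             sprintf("richness ~ imperviousness: slope %.3f (R2 %.2f, p %.3g)",
                     bundle$alpha_fit$slope, bundle$alpha_fit$r_squared,
                     bundle$alpha_fit$p_value),
             sprintf("within-site beta ~ imperviousness: slope %.4f (R2 %.2f, p %.3g)",
                     bundle$beta_fit$slope, bundle$beta_fit$r_squared,
                     bundle$beta_fit$p_value))
  ac <- bundle$association_counts
  if (sum(ac) == 0) {
    lines <- c(lines, sprintf("0 features at p<%g", bundle$config$alpha))
  } else {
    lines <- c(lines, sprintf("OTUs associated with imperviousness at p<%g: %d positive, %d negative",
                              bundle$config$alpha, ac[["positive"]], ac[["negative"]]))
  }
  lines
}

#' Reduced-size synthetic fixture configuration
#'
#' The bundled test fixture: the full paired design (4 pairs x 3 transects
#' x 4 PCR replicates) with a 300-OTU pool, site-pool richness
#' 80 + 2 x imperviousness, transect inclusion rising with imperviousness
#' (homogenization), detection probabilities p11 = 0.9 / p10 = 0.02, and
#' ~3000 reads per replicate - small enough for quick end-to-end runs while
#' keeping every gradient the full-scale generator produces.
#'
#' @return a [sim_config()].
#' @export
fixture_config <- function() {
  sim_config(pool_size = 300, richness_intercept = 80, richness_slope = 2,
             depth_mean = 3000, depth_sdlog = 0.1,
             family_count = 60, annotated_frac = 0.8)
}
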