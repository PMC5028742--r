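# Nested PERMANOVA: partition of the variance in an ecological distance
# matrix among sites, among transects within sites, and among PCR
# replicates (residual), with permutation tests restricted to respect the
# nesting.
#
# The decomposition is the Gower-centred inner-product form: with
# A = -d^2/2 and G = (I - 11'/n) A (I - 11'/n),
#   SS_total            = tr(G)
#   SS(site)            = tr(H_site G)
#   SS(transect | site) = tr(H_transect G) - tr(H_site G)
#   SS(residual)        = tr(G)  - tr(H_transect G)
# where H_f projects onto group means of factor f (transects are nested in
# sites so the spans are ordered). Because H_f averages within groups,
# tr(H_f G) = sum_g sum(G[g, g]) / n_g, which is what the code computes.
#
# Permutation scheme (restricted, one term at a time):
#  * site term: transects are the exchangeable units; whole transect blocks
#    (a bottle's replicates) are reassigned to sites, preserving each
#    site's transect count;
#  * transect term: PCR replicates are exchanged across transects within
#    their own site only.

# tr(H_f G) for a grouping factor
trace_hg <- function(G, groups) {
  groups <- as.character(groups)
  s <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- s + sum(G[idx, idx]) / length(idx)
  }
  s
}

gower_center <- function(d) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  A <- -0.5 * D2
  rm <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm, rm, "+") + gm
  G
}

#' Nested PERMANOVA variance partition
#'
#' Apportions the variance in a distance matrix over PCR replicates among
#' sites, among transects within sites, and among replicates (residual),
#' and tests the two structured terms by restricted permutations: the site
#' pseudo-F uses the transect-within-site mean square as its denominator
#' and permutes whole transect blocks across sites; the transect pseudo-F
#' uses the residual mean square and permutes replicates across transects
#' within each site. p-values are (1 + #\{F* >= F\}) / (1 + n_perm).
#'
#' @param d `dist` (or square matrix) whose labels are replicate ids.
#' @param design validated design covering those replicates.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return object of class `permanova_nested`: data.frame with one row per
#'   stratum (`site`, `transect_within_site`, `residual`, `total`):
#'   `df`, `ss`, `pct` (percent of total SS), `pseudo_f`, `p_value`, and
#'   an `n_perm` attribute.
#' @export
permanova_nested <- function(d, design, n_perm = 999, seed = 1) {
  design <- if (inherits(design, "edna_design")) design else validate_design(design)
  m <- as.matrix(d)
  ids <- rownames(m)
  if (is.null(ids)) stop("distance matrix must carry replicate ids as labels")
  row <- match(ids, design$replicate_id)
  if (anyNA(row))
    stop(sprintf("replicate(s) absent from design: %s",
                 paste(ids[is.na(row)], collapse = ", ")))
  site <- design$site[row]
  transect <- paste(design$site[row], design$transect[row], sep = "::")

  n <- nrow(m)
  G <- gower_center(m)
  ss_total <- sum(diag(G))
  tr_site <- trace_hg(G, site)
  tr_tran <- trace_hg(G, transect)
  ss_site <- tr_site
  ss_tran <- tr_tran - tr_site
  ss_res <- ss_total - tr_tran

  n_sites <- length(unique(site))
  n_tran <- length(unique(transect))
  df_site <- n_sites - 1L
  df_tran <- n_tran - n_sites
  df_res <- n - n_tran

  f_site <- f_tran <- NA_real_
  p_site <- p_tran <- NA_real_
  if (df_site < 1) warning("single site: site term dropped")
  if (df_tran < 1) warning("single transect per site: transect term dropped")
  if (df_res < 1) warning("single replicate per transect: residual term empty")

  test_site <- df_site >= 1 && df_tran >= 1
  test_tran <- df_tran >= 1 && df_res >= 1
  if (test_site) f_site <- (ss_site / df_site) / (ss_tran / df_tran)
  if (test_tran) f_tran <- (ss_tran / df_tran) / (ss_res / df_res)
  # a 0/0 pseudo-F (no variation in numerator or denominator stratum) is
  # untestable; drop the permutation test but keep the partition
  if (test_site && is.nan(f_site)) { test_site <- FALSE; f_site <- NA_real_ }
  if (test_tran && is.nan(f_tran)) { test_tran <- FALSE; f_tran <- NA_real_ }

  set.seed(seed)
  if (n_perm > 0 && (test_site || test_tran)) {
    # block bookkeeping for the site-term permutations
    blocks <- split(seq_len(n), transect)
    block_site <- vapply(blocks, function(i) site[i[1]], character(1))
    idx_by_site <- split(seq_len(n), site)
    ge_site <- 0L; ge_tran <- 0L
    for (p in seq_len(n_perm)) {
      if (test_site) {
        perm_site_of_block <- block_site[sample.int(length(blocks))]
        site_p <- character(n)
        for (bl in seq_along(blocks)) site_p[blocks[[bl]]] <- perm_site_of_block[bl]
        tr_site_p <- trace_hg(G, site_p)
        ss_site_p <- tr_site_p
        ss_tran_p <- tr_tran - tr_site_p
        fp <- (ss_site_p / df_site) / (ss_tran_p / df_tran)
        if (isTRUE(fp >= f_site - 1e-12)) ge_site <- ge_site + 1L
      }
      if (test_tran) {
        tran_p <- transect
        for (s in idx_by_site) tran_p[s] <- transect[s][sample.int(length(s))]
        tr_tran_p <- trace_hg(G, tran_p)
        ss_tran_p <- tr_tran_p - tr_site
        ss_res_p <- ss_total - tr_tran_p
        fp <- (ss_tran_p / df_tran) / (ss_res_p / df_res)
        if (isTRUE(fp >= f_tran - 1e-12)) ge_tran <- ge_tran + 1L
      }
    }
    if (test_site) p_site <- (1 + ge_site) / (1 + n_perm)
    if (test_tran) p_tran <- (1 + ge_tran) / (1 + n_perm)
  }

  out <- data.frame(
    stratum = c("site", "transect_within_site", "residual", "total"),
    df = c(df_site, df_tran, df_res, n - 1L),
    ss = c(ss_site, ss_tran, ss_res, ss_total),
    pct = 100 * c(ss_site, ss_tran, ss_res, ss_total) / ss_total,
    pseudo_f = c(f_site, f_tran, NA, NA),
    p_value = c(p_site, p_tran, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  class(out) <- c("permanova_nested", class(out))
  out
}
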