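# decontam_normalize, part 2: rarefaction to a common sequencing depth and
# collapse of PCR replicates to the bottle (water-sample) level.

#' Rarefy every replicate to a common read depth
#'
#' Each retained replicate column is subsampled to `depth` reads without
#' replacement (multivariate hypergeometric draw, via [vegan::rrarefy()]).
#' With `depth = "auto"` the depth is the smallest replicate total, the
#' usual "smallest sample" policy; replicates below an explicit depth are
#' dropped with a warning. The whole set of draws is deterministic given
#' `seed`.
#'
#' @param counts OTU x replicate count matrix.
#' @param depth `"auto"` (default) or a positive integer.
#' @param n_draws number of independent rarefaction draws.
#' @param seed integer seed for the draw sequence.
#' @param representative index of the draw reported as the representative
#'   dataset downstream (default 1).
#' @return object of class `rarefied_set`: list with `draws` (list of
#'   OTU x replicate matrices, every retained column summing to `depth`),
#'   `depth`, `representative`, and `dropped` (replicate ids below depth).
#' @export
rarefy_counts <- function(counts, depth = "auto", n_draws = 1, seed = 1,
                          representative = 1) {
  totals <- colSums(counts)
  if (identical(depth, "auto") || is.null(depth)) {
    depth <- min(totals[totals > 0])
  }
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0) stop("rarefaction depth must be a positive integer")
  if (representative < 1 || representative > n_draws)
    stop("representative draw index out of range")
  keep <- totals >= depth
  if (!any(keep)) stop("no replicate reaches the rarefaction depth")
  if (any(!keep))
    warning(sprintf("dropping %d replicate(s) below depth %d: %s", sum(!keep),
                    depth, paste(colnames(counts)[!keep], collapse = ", ")))
  x <- t(counts[, keep, drop = FALSE])  # samples as rows for vegan
  set.seed(seed)
  draws <- vector("list", n_draws)
  for (r in seq_len(n_draws)) {
    # rrarefy warns when a column has no singleton count (a heuristic for
    # non-count input); counts here are validated upstream
    d <- t(withCallingHandlers(
      vegan::rrarefy(x, depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }))
    storage.mode(d) <- "integer"
    draws[[r]] <- d
  }
  structure(list(draws = draws, depth = depth, representative = representative,
                 dropped = colnames(counts)[!keep]),
            class = "rarefied_set")
}

#' @rdname rarefy_counts
#' @param x a `rarefied_set`.
#' @return `representative_draw()`: the designated representative count
#'   matrix.
#' @export
representative_draw <- function(x) {
  stopifnot(inherits(x, "rarefied_set"))
  x$draws[[x$representative]]
}

#' Average PCR replicates to the bottle level
#'
#' Mean read count per OTU over each bottle's surviving PCR replicates;
#' presence is defined as mean > 0 (equivalently, at least one replicate
#' with reads). Output is invariant to replicate order.
#'
#' @param draw OTU x replicate count matrix (typically one rarefaction
#'   draw).
#' @param design validated design covering the draw's replicates.
#' @return list with `mean_counts` (bottle x OTU numeric matrix) and
#'   `incidence` (bottle x OTU 0/1 matrix).
#' @export
collapse_replicates <- function(draw, design) {
  design <- if (inherits(design, "edna_design")) design else validate_design(design)
  reps <- colnames(draw)
  missing <- setdiff(reps, design$replicate_id)
  if (length(missing))
    stop(sprintf("replicate(s) absent from design: %s",
                 paste(missing, collapse = ", ")))
  bottle_of <- design$bottle[match(reps, design$replicate_id)]
  bottles <- unique(design$bottle[design$replicate_id %in% reps])
  sums <- rowsum(t(draw), bottle_of, reorder = FALSE)      # bottle x OTU
  K <- as.integer(table(factor(bottle_of, levels = rownames(sums))))
  mean_counts <- sums / K
  mean_counts <- mean_counts[bottles, , drop = FALSE]
  list(mean_counts = mean_counts, incidence = as_incidence(mean_counts))
}

#' Closed-form expected rarefied richness of one replicate
#'
#' E\[S\] = sum_j (1 - choose(N - N_j, d) / choose(N, d)) for a column with
#' counts N_j summing to N, rarefied to depth d. Used as an analytic check
#' on the Monte-Carlo rarefaction.
#'
#' @param column non-negative integer vector of counts.
#' @param depth rarefaction depth.
#' @return expected number of OTUs with at least one read after
#'   rarefaction.
#' @export
expected_rarefied_richness <- function(column, depth) {
  N <- sum(column)
  if (depth > N) stop("depth exceeds the column total")
  sum(1 - exp(lchoose(N - column, depth) - lchoose(N, depth)))
}
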