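# traits_association, part 1: life-history niche expansion, redundancy
# metrics, and trait-space ordination.
#
# A life-history niche is a (category, habitat, mobility) attribute triple
# assigned at family level, e.g. "epifauna|intertidal|sessile". A family
# spanning several attribute values contributes every combination.

#' Expand family trait sets into life-history niches
#'
#' The niche set of a family is the Cartesian product of its category,
#' habitat and mobility attribute sets, so its cardinality is the product
#' of the three set sizes.
#'
#' @param traits validated trait table (see [load_traits()]).
#' @return data.frame with columns `family`, `category`, `habitat`,
#'   `mobility`, `niche` (the "cat|hab|mob" label), one row per
#'   family-niche combination.
#' @export
expand_niches <- function(traits) {
  traits <- validate_traits(traits)
  cats <- split_tokens(traits$category)
  habs <- split_tokens(traits$habitat)
  mobs <- split_tokens(traits$mobility)
  rows <- lapply(seq_len(nrow(traits)), function(i) {
    g <- expand.grid(category = cats[[i]], habitat = habs[[i]],
                     mobility = mobs[[i]], stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[order(g$category, g$habitat, g$mobility), , drop = FALSE]
    data.frame(family = traits$family[i], g, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$niche <- paste(out$category, out$habitat, out$mobility, sep = "|")
  rownames(out) <- NULL
  out
}

#' Site-by-niche incidence
#'
#' A niche is present at a site iff at least one family carrying it is
#' present. Families in the incidence matrix without a trait
#' classification are dropped; their count is stored in the `"n_dropped"`
#' attribute.
#'
#' @param fam_inc site x family incidence matrix.
#' @param niches niche table from [expand_niches()].
#' @return site x niche incidence with attribute `n_dropped`.
#' @export
niche_incidence <- function(fam_inc, niches) {
  fam_inc <- as_incidence(fam_inc)
  known <- colnames(fam_inc) %in% niches$family
  n_dropped <- sum(!known)
  sub <- fam_inc[, known, drop = FALSE]
  all_niches <- sort(unique(niches$niche))
  out <- matrix(0L, nrow(fam_inc), length(all_niches),
                dimnames = list(rownames(fam_inc), all_niches))
  for (f in colnames(sub)) {
    nf <- unique(niches$niche[niches$family == f])
    hit <- sub[, f] > 0
    out[hit, nf] <- 1L
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-site life-history niche richness
#'
#' Counts the unique niche triples contributed by the classified families
#' present at each site; shared niches collapse (redundancy).
#'
#' @inheritParams niche_incidence
#' @return data.frame `unit`, `richness`.
#' @export
niche_richness <- function(fam_inc, niches) {
  alpha_richness(niche_incidence(fam_inc, niches))
}

#' Life-history niches per classified family
#'
#' Niche richness divided by the number of classified families present: a
#' redundancy index, low values meaning many families packed into few
#' niches.
#'
#' @inheritParams niche_incidence
#' @return data.frame `unit`, `n_families`, `n_niches`, `niches_per_family`
#'   (`NA` with a flag when no classified family is present).
#' @export
niches_per_family <- function(fam_inc, niches) {
  fam_inc <- as_incidence(fam_inc)
  known <- colnames(fam_inc) %in% niches$family
  nfam <- rowSums(fam_inc[, known, drop = FALSE])
  nn <- niche_richness(fam_inc, niches)
  out <- data.frame(unit = nn$unit, n_families = unname(nfam),
                    n_niches = nn$richness,
                    niches_per_family = ifelse(nfam > 0, nn$richness / nfam, NA_real_),
                    stringsAsFactors = FALSE)
  if (any(nfam == 0))
    warning(sprintf("%d unit(s) with no classified family present", sum(nfam == 0)))
  out
}

#' Principal-components ordination of sites in niche (or OTU) space
#'
#' Column-centred PCA with axes ordered by non-increasing variance
#' explained and a fixed sign convention (the largest-magnitude loading on
#' each axis is positive), so results are reproducible across platforms.
#'
#' @param inc site x feature incidence (>= 2 sites).
#' @return list with `scores` (site x axis), `loadings`,
#'   `var_explained` (per axis), `total_variance`, and `degenerate` flag
#'   (TRUE when the input has zero variance, in which case all coordinates
#'   are 0).
#' @export
ordinate <- function(inc) {
  x <- as.matrix(inc)
  if (nrow(x) < 2) stop("need at least two sites")
  cx <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(cx) < 1e-12)) {
    warning("zero-variance input; all coordinates set to 0")
    k <- min(dim(x))
    return(list(scores = matrix(0, nrow(x), k,
                                dimnames = list(rownames(x), paste0("PC", seq_len(k)))),
                loadings = NULL, var_explained = rep(0, k),
                total_variance = 0, degenerate = TRUE))
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation, var_explained = pc$sdev^2,
       total_variance = sum(pc$sdev^2), degenerate = FALSE)
}
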