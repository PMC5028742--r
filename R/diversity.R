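# diversity: distance, alpha/beta/gamma diversity, Raup-Crick null model,
# and site-accumulation curves. Nested PERMANOVA lives in permanova.R.

#' Jaccard distance between units of an incidence matrix
#'
#' d(a, b) = 1 - |A n B| / |A u B| on presence/absence data (via
#' [vegan::vegdist()]). Two empty units are assigned distance 0 by
#' convention and their number flagged in the `"n_empty_pairs"` attribute,
#' so downstream ordinations and PERMANOVAs stay usable.
#'
#' @param inc unit x feature incidence matrix (>= 2 units).
#' @return `dist` object with attribute `metric = "jaccard"`.
#' @export
jaccard_matrix <- function(inc) {
  inc <- as_incidence(inc)
  if (nrow(inc) < 2) stop("need at least two units")
  d <- suppressWarnings(vegan::vegdist(inc, method = "jaccard", binary = TRUE))
  m <- as.matrix(d)
  empty <- rowSums(inc) == 0
  n_empty_pairs <- 0L
  if (any(empty)) {
    both <- outer(empty, empty, "&")
    n_empty_pairs <- sum(both[upper.tri(both)])
    m[both] <- 0
  }
  m[is.nan(m)] <- 0
  diag(m) <- 0
  out <- as.dist(m)
  attr(out, "metric") <- "jaccard"
  attr(out, "n_empty_pairs") <- n_empty_pairs
  out
}

#' Per-unit richness
#'
#' @param inc unit x feature incidence matrix.
#' @return data.frame with columns `unit`, `richness`.
#' @export
alpha_richness <- function(inc) {
  inc <- as_incidence(inc)
  data.frame(unit = rownames(inc), richness = unname(rowSums(inc)),
             stringsAsFactors = FALSE)
}

#' Site-mean transect richness
#'
#' Alpha diversity at the site level: the mean richness of the site's
#' transects (bottles), the unit used for site-level regressions to avoid
#' pseudoreplicating transects.
#'
#' @param inc bottle x feature incidence.
#' @param design validated design.
#' @return data.frame: `site`, `pair`, `urban`, `imperviousness`,
#'   `richness` (mean over transects).
#' @export
site_alpha <- function(inc, design) {
  design <- if (inherits(design, "edna_design")) design else validate_design(design)
  map <- unique(as.data.frame(design)[, c("bottle", "site")])
  site <- map$site[match(rownames(inc), map$bottle)]
  r <- rowSums(as_incidence(inc))
  st <- site_table(design)
  st$richness <- as.numeric(tapply(r, site, mean)[st$site])
  st
}

#' Whittaker's beta diversity of a set of transects
#'
#' beta_w = S / alpha-bar - 1, with S the pooled richness and alpha-bar the
#' mean per-transect richness, so identical transects give 0 and n fully
#' disjoint transects give n - 1. The classical ratio S / alpha-bar is
#' available via `variant = "ratio"`.
#'
#' @param inc transect x feature incidence (>= 2 transects).
#' @param variant `"turnover"` (S/alpha - 1, default) or `"ratio"` (S/alpha).
#' @return scalar; `NA` with a warning if all transects are empty.
#' @export
whittaker_beta <- function(inc, variant = c("turnover", "ratio")) {
  variant <- match.arg(variant)
  inc <- as_incidence(inc)
  if (nrow(inc) < 2) stop("need at least two transects")
  abar <- mean(rowSums(inc))
  if (abar == 0) {
    warning("all transects empty; beta undefined")
    return(NA_real_)
  }
  S <- sum(colSums(inc) > 0)
  if (variant == "ratio") S / abar else S / abar - 1
}

#' Within-site Whittaker beta for every site
#'
#' @param inc bottle x feature incidence (bottles = transects).
#' @param design validated design.
#' @inheritParams whittaker_beta
#' @return site table with a `beta` column.
#' @export
beta_by_site <- function(inc, design, variant = "turnover") {
  design <- if (inherits(design, "edna_design")) design else validate_design(design)
  map <- unique(as.data.frame(design)[, c("bottle", "site")])
  site <- map$site[match(rownames(inc), map$bottle)]
  st <- site_table(design)
  st$beta <- vapply(st$site, function(s) {
    sub <- inc[which(site == s), , drop = FALSE]
    if (nrow(sub) < 2) return(NA_real_)
    whittaker_beta(sub, variant = variant)
  }, numeric(1))
  st
}

#' Raup-Crick null-model dissimilarity
#'
#' For each pair of units, the observed number of shared taxa is compared
#' with draws from a null model that fixes each unit's richness and draws
#' taxa from the pool with probability proportional to their occupancy
#' frequency across the analysis set (Raup-Crick as reformulated for
#' incidence null models). The raw score
#' \deqn{[\#(SS_{null} > SS_{obs}) + 0.5\,\#(SS_{null} = SS_{obs})]/n_{null}}
#' is rescaled to \eqn{2(raw - 0.5) \in [-1, 1]}: negative values mean the
#' two units share more taxa than expected at their richnesses, positive
#' values fewer. Deterministic given `seed`.
#'
#' @param inc unit x feature incidence.
#' @param n_null number of null draws per pair (>= 99; default 999).
#' @param seed integer seed.
#' @param pool_freq optional named vector of pool occupancy frequencies;
#'   defaults to the column sums of `inc`.
#' @return `dist` object in \[-1, 1\] with attribute `metric = "raup_crick"`.
#' @export
raup_crick <- function(inc, n_null = 999, seed = 1, pool_freq = NULL) {
  inc <- as_incidence(inc) > 0
  if (n_null < 99) stop("n_null must be at least 99")
  if (is.null(pool_freq)) pool_freq <- colSums(inc)
  pool <- which(pool_freq > 0)
  w <- as.numeric(pool_freq[pool])
  P <- length(pool)
  rich <- rowSums(inc[, pool, drop = FALSE])
  if (any(rowSums(inc) > P)) stop("a unit is richer than the species pool")
  n <- nrow(inc)
  out <- matrix(0, n, n, dimnames = list(rownames(inc), rownames(inc)))
  set.seed(seed)
  memb <- matrix(FALSE, n, P)
  for (i in seq_len(n)) memb[i, ] <- inc[i, pool]
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      obs <- sum(memb[a, ] & memb[b, ])
      gt <- 0L; eq <- 0L
      for (r in seq_len(n_null)) {
        sa <- sample.int(P, rich[a], prob = w)
        flag <- logical(P); flag[sa] <- TRUE
        sb <- sample.int(P, rich[b], prob = w)
        ss <- sum(flag[sb])
        if (ss > obs) gt <- gt + 1L else if (ss == obs) eq <- eq + 1L
      }
      raw <- (gt + 0.5 * eq) / n_null
      out[a, b] <- out[b, a] <- 2 * (raw - 0.5)
    }
  }
  d <- as.dist(out)
  attr(d, "metric") <- "raup_crick"
  d
}

#' Mean within-site Raup-Crick dissimilarity
#'
#' Raup-Crick scores for all transect pairs within each site, against the
#' pool of all taxa observed across `inc`, averaged per site.
#'
#' @inheritParams raup_crick
#' @param design validated design (bottles = rownames of `inc`).
#' @return site table with a `raup_crick` column.
#' @export
raup_crick_by_site <- function(inc, design, n_null = 999, seed = 1) {
  design <- if (inherits(design, "edna_design")) design else validate_design(design)
  map <- unique(as.data.frame(design)[, c("bottle", "site")])
  site <- map$site[match(rownames(inc), map$bottle)]
  pool_freq <- colSums(as_incidence(inc))
  st <- site_table(design)
  st$raup_crick <- NA_real_
  for (k in seq_len(nrow(st))) {
    idx <- which(site == st$site[k])
    if (length(idx) < 2) next
    d <- raup_crick(inc[idx, , drop = FALSE], n_null = n_null,
                    seed = seed + k, pool_freq = pool_freq)
    st$raup_crick[k] <- mean(d)
  }
  st
}

#' Bootstrap accumulation curve of regional (gamma) diversity
#'
#' For m = 1..M, draws m sites with replacement from the set and pools
#' their features; repeated `n_boot` times to give the distribution of
#' cumulative richness at each step.
#'
#' @param site_inc site x feature incidence.
#' @param n_boot bootstrap draws per step (default 1000).
#' @param seed integer seed.
#' @return object of class `accumulation_curve`: data.frame `m`, `mean`,
#'   `sd`, `q025`, `q500`, `q975`.
#' @export
gamma_accumulation <- function(site_inc, n_boot = 1000, seed = 1) {
  inc <- as_incidence(site_inc)
  M <- nrow(inc)
  if (M < 1) stop("need at least one site")
  set.seed(seed)
  rows <- lapply(seq_len(M), function(m) {
    rich <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      pick <- sample.int(M, m, replace = TRUE)
      rich[b] <- sum(colSums(inc[pick, , drop = FALSE]) > 0)
    }
    data.frame(m = m, mean = mean(rich), sd = sd(rich),
               q025 = unname(quantile(rich, 0.025)),
               q500 = unname(quantile(rich, 0.5)),
               q975 = unname(quantile(rich, 0.975)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("accumulation_curve", class(out))
  out
}

#' Least-squares logarithmic curve fit
#'
#' Fits y = a + b log(m) to accumulation-curve means, the usual summary of
#' how fast regional richness accumulates with added sites.
#'
#' @param m site counts (>= 2 distinct values), or an
#'   `accumulation_curve`.
#' @param y mean richness at each `m` (ignored when `m` is a curve).
#' @return named vector `c(a, b)`.
#' @export
fit_log_curve <- function(m, y = NULL) {
  if (inherits(m, "accumulation_curve")) {
    y <- m$mean
    m <- m$m
  }
  if (length(unique(m)) < 2) stop("need at least two distinct site counts")
  fit <- lm(y ~ log(m))
  c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
}
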