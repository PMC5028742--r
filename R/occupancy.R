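# decontam_normalize, part 1: occupancy-model decontamination.
#
# Model: for OTU j, bottle (water sample) i with K_i PCR replicates, the
# number of replicates with reads y_ij follows the two-component binomial
# mixture
#
#   L_j = prod_i [ psi_j Bin(y_ij; K_i, p11_j) + (1 - psi_j) Bin(y_ij; K_i, p10_j) ]
#
# where psi is the probability the OTU truly occupies the bottle, p11 the
# per-replicate true-positive detection probability and p10 the
# per-replicate false-positive (contamination) probability. The fit is by
# EM on the complete-data likelihood with the latent occupancy state as the
# missing datum; "posterior" below is the empirical-Bayes probability of
# true presence given the point estimates,
#
#   Pr(z_i = 1 | y_i) = psi B(y_i; K_i, p11) / [psi B(.; p11) + (1-psi) B(.; p10)].

#' Detection histories across PCR replicates
#'
#' For every OTU and bottle, counts the number of that bottle's PCR
#' replicates with at least one read. The number of surviving replicates
#' `K_i` is taken from the columns actually present in `counts`, so bottles
#' that lost a replicate to QC get the smaller `K_i`.
#'
#' @param counts OTU x replicate count matrix.
#' @param design validated design covering every replicate column.
#' @return object of class `detection_history`: list with `y` (OTU x bottle
#'   integer matrix), `K` (replicates per bottle), `bottles`, `otu_ids`.
#' @export
detection_histories <- function(counts, design) {
  design <- if (inherits(design, "edna_design")) design else validate_design(design)
  reps <- colnames(counts)
  missing <- setdiff(reps, design$replicate_id)
  if (length(missing))
    stop(sprintf("replicate(s) absent from design: %s",
                 paste(missing, collapse = ", ")))
  bottle_of <- design$bottle[match(reps, design$replicate_id)]
  bottles <- unique(design$bottle[design$replicate_id %in% reps])
  pos <- counts > 0
  y <- t(rowsum(t(pos) * 1L, bottle_of, reorder = FALSE))
  y <- y[, bottles, drop = FALSE]
  K <- as.integer(table(factor(bottle_of, levels = bottles)))
  names(K) <- bottles
  structure(list(y = y, K = K, bottles = bottles, otu_ids = rownames(counts)),
            class = "detection_history")
}

# one EM run, vectorized over OTUs; y is J x N, Kmat same shape
em_occupancy <- function(y, Kmat, psi0, p110, p100, max_iter = 1000, tol = 1e-8) {
  J <- nrow(y)
  psi <- rep(psi0, J); p11 <- rep(p110, J); p10 <- rep(p100, J)
  eps <- 1e-7
  mix_ll <- function(psi, p11, p10) {
    B1 <- dbinom(y, Kmat, matrix(p11, J, ncol(y)))
    B0 <- dbinom(y, Kmat, matrix(p10, J, ncol(y)))
    den <- psi * B1 + (1 - psi) * B0
    list(ll = rowSums(log(pmax(den, 1e-300))), B1 = B1, B0 = B0, den = den)
  }
  cur <- mix_ll(psi, p11, p10)
  ll <- cur$ll
  converged <- rep(FALSE, J)
  iters <- rep(0L, J)
  for (it in seq_len(max_iter)) {
    w <- (psi * cur$B1) / pmax(cur$den, 1e-300)
    w[cur$den <= 1e-300] <- 0.5
    live <- !converged
    psi_new <- clamp(rowMeans(w), eps, 1 - eps)
    swK <- rowSums(w * Kmat); s0K <- rowSums((1 - w) * Kmat)
    p11_new <- clamp(ifelse(swK > 0, rowSums(w * y) / swK, p11), eps, 1 - eps)
    p10_new <- clamp(ifelse(s0K > 0, rowSums((1 - w) * y) / s0K, p10), eps, 1 - eps)
    psi[live] <- psi_new[live]; p11[live] <- p11_new[live]; p10[live] <- p10_new[live]
    cur <- mix_ll(psi, p11, p10)
    delta <- abs(cur$ll - ll)
    newly <- live & (delta < tol)
    iters[live] <- it
    converged <- converged | newly
    ll <- cur$ll
    if (all(converged)) break
  }
  list(psi = psi, p11 = p11, p10 = p10, ll = ll,
       converged = converged, iters = iters)
}

#' Fit the binomial-mixture occupancy model per OTU
#'
#' Maximizes the mixture likelihood by EM, independently for every OTU,
#' jointly across all bottles. Several fixed starting points are tried and
#' the best likelihood kept; identifiability is enforced by swapping the
#' mixture components (and replacing psi by 1 - psi) whenever the fit ends
#' with p10 > p11, so that p11 >= p10 always holds. When the two detection
#' probabilities tie the posterior reduces to psi (uninformative).
#'
#' @param hist `detection_history` from [detection_histories()], or a
#'   numeric vector of per-bottle detection counts for a single OTU.
#' @param K replicates per bottle; only used (and recycled) when `hist` is
#'   a bare vector.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return object of class `occupancy_fit`: list with `estimates` (one row
#'   per OTU: `otu`, `psi`, `p11`, `p10`, `loglik`, `converged`, `n_iter`)
#'   and `posterior` (OTU x bottle matrix of true-presence probabilities).
#' @export
fit_occupancy <- function(hist, K = NULL, max_iter = 1000, tol = 1e-8) {
  if (is.numeric(hist) && is.null(dim(hist))) {
    if (is.null(K)) stop("K is required when passing a bare detection vector")
    y <- matrix(as.integer(hist), nrow = 1,
                dimnames = list("otu", paste0("bottle", seq_along(hist))))
    K <- rep_len(as.integer(K), length(hist))
    hist <- structure(list(y = y, K = K, bottles = colnames(y), otu_ids = "otu"),
                      class = "detection_history")
  }
  stopifnot(inherits(hist, "detection_history"))
  y <- hist$y
  if (ncol(y) < 1) stop("need at least one bottle")
  if (any(y > rep(hist$K, each = nrow(y))))
    stop("detection count exceeds the number of replicates")
  Kmat <- matrix(hist$K, nrow(y), ncol(y), byrow = TRUE)
  storage.mode(y) <- "double"

  starts <- list(c(0.5, 0.7, 0.05), c(0.3, 0.9, 0.2), c(0.8, 0.5, 0.01))
  best <- NULL
  for (s in starts) {
    fit <- em_occupancy(y, Kmat, s[1], s[2], s[3], max_iter, tol)
    if (is.null(best)) {
      best <- fit
    } else {
      upd <- fit$ll > best$ll + 1e-10
      for (f in names(best)) best[[f]][upd] <- fit[[f]][upd]
    }
  }
  swap <- best$p10 > best$p11
  if (any(swap)) {
    tmp <- best$p11[swap]
    best$p11[swap] <- best$p10[swap]
    best$p10[swap] <- tmp
    best$psi[swap] <- 1 - best$psi[swap]
  }
  post <- occupancy_posterior(best$psi, best$p11, best$p10, y, Kmat)
  dimnames(post) <- list(hist$otu_ids, hist$bottles)
  est <- data.frame(otu = hist$otu_ids, psi = best$psi, p11 = best$p11,
                    p10 = best$p10, loglik = best$ll,
                    converged = best$converged, n_iter = best$iters,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(!est$converged))
    warning(sprintf("%d OTU(s) did not converge; they will be retained unfiltered",
                    sum(!est$converged)))
  structure(list(estimates = est, posterior = post, K = hist$K,
                 bottles = hist$bottles),
            class = "occupancy_fit")
}

#' Posterior probability of true presence
#'
#' @param psi,p11,p10 parameter vectors (recycled over rows of `y`).
#' @param y detections per bottle (vector or OTU x bottle matrix).
#' @param K replicates per bottle (scalar, vector, or matrix shaped like `y`).
#' @return posterior probabilities, shaped like `y`.
#' @export
occupancy_posterior <- function(psi, p11, p10, y, K) {
  if (is.null(dim(y))) {
    b1 <- dbinom(y, K, p11); b0 <- dbinom(y, K, p10)
    den <- psi * b1 + (1 - psi) * b0
    out <- ifelse(den > 0, psi * b1 / den, psi)
    return(out)
  }
  J <- nrow(y)
  if (is.null(dim(K))) K <- matrix(K, J, ncol(y), byrow = length(K) == ncol(y))
  B1 <- dbinom(y, K, matrix(p11, J, ncol(y)))
  B0 <- dbinom(y, K, matrix(p10, J, ncol(y)))
  den <- psi * B1 + (1 - psi) * B0
  out <- (psi * B1) / den
  out[den <= 0] <- rep(psi, ncol(y))[den <= 0]
  out
}

#' Zero out detections judged to be contamination
#'
#' Counts in every (OTU, bottle) cell whose posterior true-presence
#' probability falls below `threshold` are set to zero across all of that
#' bottle's PCR replicates. OTUs flagged as non-converged are retained
#' unfiltered. The per-OTU tally of removed detections (replicate cells
#' with reads that were zeroed) is recorded in the `"removed"` attribute.
#'
#' @param counts OTU x replicate count matrix.
#' @param design validated design.
#' @param fit `occupancy_fit` from [fit_occupancy()].
#' @param threshold posterior retention threshold in \[0, 1\] (default 0.8).
#' @return filtered count matrix with attribute `removed` (named integer
#'   vector per OTU).
#' @export
filter_by_posterior <- function(counts, design, fit, threshold = 0.8) {
  stopifnot(inherits(fit, "occupancy_fit"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  design <- if (inherits(design, "edna_design")) design else validate_design(design)
  post <- fit$posterior
  if (!all(rownames(counts) %in% rownames(post)))
    stop("counts contain OTUs absent from the occupancy fit")
  post <- post[rownames(counts), , drop = FALSE]
  keep_otu <- fit$estimates$converged[match(rownames(counts), fit$estimates$otu)]
  bottle_of <- design$bottle[match(colnames(counts), design$replicate_id)]
  drop_cell <- post < threshold          # OTU x bottle
  drop_cell[!keep_otu, ] <- FALSE        # non-converged: retained unfiltered
  drop_rep <- drop_cell[, bottle_of, drop = FALSE]  # OTU x replicate
  removed <- rowSums(drop_rep & counts > 0)
  out <- counts
  out[drop_rep] <- 0L
  attr(out, "removed") <- removed
  out
}
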