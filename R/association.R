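# traits_association, part 2: per-feature association tests against the
# urbanization gradient (imperviousness).

# deterministic ridge-penalized logistic fit, used as a fallback when the
# unpenalized ML fit separates (slope diverging to +/- Inf); the penalty is
# on the slope only, never the intercept
penalized_logit <- function(y, x, lambda = 0.5, max_iter = 200) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  P <- diag(c(0, lambda))
  Hm <- NULL
  for (it in seq_len(max_iter)) {
    mu <- plogis(drop(X %*% beta))
    wv <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X, y - mu)) - drop(P %*% beta)
    Hm <- crossprod(X, X * wv) + P
    step <- solve(Hm, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(Hm)))
  z <- beta[2] / se[2]
  list(slope = unname(beta[2]), p = 2 * pnorm(-abs(z)))
}

logistic_one <- function(y, x) {
  if (length(unique(y)) < 2)
    return(list(slope = NA_real_, p = NA_real_, flag = "degenerate"))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) sep <- TRUE
  if (!sep && abs(coef(fit)[2]) < 15) {
    sm <- summary(fit)$coefficients
    return(list(slope = unname(coef(fit)[2]), p = unname(sm[2, 4]), flag = "ok"))
  }
  pen <- penalized_logit(y, x)
  list(slope = pen$slope, p = pen$p, flag = "separation")
}

#' Per-feature logistic regression of presence on imperviousness
#'
#' Fits presence ~ imperviousness by maximum-likelihood logistic regression
#' for every feature (OTU, family, or niche) and reports the slope and the
#' Wald p-value. Complete or quasi-complete separation — e.g. an OTU
#' present only at the most urban sites — is detected and flagged, and a
#' deterministic ridge-penalized fit supplies a finite slope so those
#' (often the most interesting) features still get a usable effect
#' estimate.
#'
#' @param presence unit x feature 0/1 matrix (units are transects by
#'   default in the pipeline; any unit with an imperviousness value works).
#' @param imperv imperviousness per unit (needs >= 2 distinct values).
#' @param p_adjust `"none"` (default, raw p-values) or any method of
#'   [stats::p.adjust()], e.g. `"BH"`.
#' @return data.frame, one row per feature: `feature`, `model`, `slope`,
#'   `p_value`, `direction` (+1/-1/0 by slope sign), `flag`
#'   (`ok`/`separation`/`degenerate`).
#' @export
logistic_association <- function(presence, imperv, p_adjust = "none") {
  presence <- as_incidence(presence)
  if (length(imperv) != nrow(presence))
    stop("imperv must have one value per unit (row)")
  if (length(unique(imperv)) < 2)
    stop("need at least two distinct imperviousness values")
  res <- lapply(seq_len(ncol(presence)), function(j)
    logistic_one(presence[, j], imperv))
  out <- data.frame(
    feature = colnames(presence),
    model = "logistic",
    slope = vapply(res, `[[`, numeric(1), "slope"),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    flag = vapply(res, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE
  )
  if (!identical(p_adjust, "none"))
    out$p_value <- p.adjust(out$p_value, method = p_adjust)
  out$direction <- ifelse(is.na(out$slope), 0, sign(out$slope))
  out[, c("feature", "model", "slope", "p_value", "direction", "flag")]
}

#' Poisson trend of a richness response along imperviousness
#'
#' Log-link Poisson GLM of a non-negative integer response (e.g. per-site
#' family richness) on imperviousness.
#'
#' @param y non-negative integer response (one per unit).
#' @param imperv imperviousness per unit.
#' @return one-row data.frame shaped like [logistic_association()] output
#'   with `model = "poisson"`.
#' @export
poisson_trend <- function(y, imperv) {
  if (length(y) < 2) stop("need at least two units (insufficient df)")
  if (length(y) != length(imperv)) stop("y and imperv must be the same length")
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (all(y == 0))
    return(data.frame(feature = NA_character_, model = "poisson",
                      slope = NA_real_, p_value = NA_real_, direction = 0,
                      flag = "degenerate", stringsAsFactors = FALSE))
  fit <- glm(y ~ imperv, family = poisson())
  sm <- summary(fit)$coefficients
  slope <- unname(coef(fit)[2])
  data.frame(feature = NA_character_, model = "poisson", slope = slope,
             p_value = unname(sm[2, 4]),
             direction = sign(slope), flag = "ok", stringsAsFactors = FALSE)
}

#' Exact two-sided binomial test
#'
#' Probability, under success probability `p0`, of an outcome at least as
#' extreme (in likelihood) as `k` successes in `n` trials; the standard
#' minimum-likelihood two-sided exact test.
#'
#' @param k observed successes.
#' @param n number of trials (> 0).
#' @param p0 null success probability.
#' @return p-value.
#' @export
binomial_presence_test <- function(k, n, p0 = 0.5) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  binom.test(k, n, p = p0)$p.value
}

#' Ordinary least squares on site means
#'
#' Site-level regression of a diversity metric on imperviousness, using one
#' mean value per site to avoid pseudoreplicating transects.
#'
#' @param y metric per site (>= 3 sites).
#' @param imperv imperviousness per site (non-constant).
#' @return list `slope`, `intercept`, `r_squared`, `p_value`, `conf_low`,
#'   `conf_high` (95% CI of the slope), `n`.
#' @export
site_mean_regression <- function(y, imperv) {
  ok <- !is.na(y) & !is.na(imperv)
  y <- y[ok]; imperv <- imperv[ok]
  if (length(y) < 3) stop("need at least three sites")
  if (length(unique(imperv)) < 2) stop("imperviousness is constant across sites")
  fit <- lm(y ~ imperv)
  sm <- summary(fit)
  ci <- suppressWarnings(confint(fit, "imperv", level = 0.95))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       conf_low = unname(ci[1]), conf_high = unname(ci[2]),
       n = length(y))
}
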