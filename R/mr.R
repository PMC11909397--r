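# Causal-effect estimation from harmonized instrument pairs.
#
# The workhorse is the random-effects inverse-variance-weighted (IVW)
# estimator: weighted least squares of outcome on exposure effects through
# the origin with weights 1/se_y^2, with a multiplicative overdispersion
# scale phi = Q/(n-1) floored at 1 so the random-effects SE never shrinks
# below the fixed-effects SE.  Sensitivity: Cochran's Q for heterogeneity
# and the MR-Egger intercept for directional pleiotropy.

#' Construct an MR result
#'
#' @param method `"wald_ratio"`, `"ivw_random_effects"` or `"egger_slope"`.
#' @param beta_hat Causal estimate on the log-odds scale.
#' @param se_hat Its standard error.
#' @param pval Two-sided P value.
#' @param n_snps Number of instruments used.
#' @return An object of class `mr_result` carrying in addition `or_hat`
#'   (exp(beta_hat)), the 95% Wald interval on the OR scale (`ci_low`,
#'   `ci_high`) and the association `strength` tier.
#' @export
mr_result <- function(method, beta_hat, se_hat, pval, n_snps) {
  stopifnot(n_snps >= 1, se_hat > 0)
  z95 <- stats::qnorm(0.975)
  structure(
    list(method = method, beta_hat = beta_hat, se_hat = se_hat,
         or_hat = exp(beta_hat),
         ci_low = exp(beta_hat - z95 * se_hat),
         ci_high = exp(beta_hat + z95 * se_hat),
         pval = pval, n_snps = as.integer(n_snps),
         strength = classify_strength(pval)),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: OR = %.3f (95%% CI %.3f-%.3f), P = %.3g, n_snps = %d [%s]\n",
              x$method, x$or_hat, x$ci_low, x$ci_high, x$pval, x$n_snps,
              x$strength))
  invisible(x)
}

#' Classify the strength of an MR association from its P value
#'
#' Tiers: strong (P <= 0.01), moderate (P <= 0.05), weak (P <= 0.1), none
#' otherwise.  Boundaries are inclusive.
#'
#' @param pval P value in \[0, 1\].
#' @return One of `"strong"`, `"moderate"`, `"weak"`, `"none"`; vectorized.
#' @export
classify_strength <- function(pval) {
  if (any(!is.finite(pval)) || any(pval < 0) || any(pval > 1)) {
    stop("pval must lie in [0, 1]")
  }
  ifelse(pval <= 0.01, "strong",
         ifelse(pval <= 0.05, "moderate",
                ifelse(pval <= 0.1, "weak", "none")))
}

#' Star annotation matching the strength tier
#'
#' `"***"` strong, `"**"` moderate, `"*"` weak, `""` none — the heatmap
#' annotation convention.
#' @param strength Strength tier string(s) from [classify_strength()].
#' @export
strength_stars <- function(strength) {
  unname(c(strong = "***", moderate = "**", weak = "*", none = "")[strength])
}

pairs_of <- function(x) {
  if (inherits(x, "harmonized_set")) x$pairs else as.data.frame(x)
}

#' Wald ratio causal estimate from a single instrument
#'
#' `beta_hat = beta_y / beta_x`, first-order `se_hat = se_y / |beta_x|`,
#' two-sided P from the standard normal.
#'
#' @param pair A one-row data.frame (or list) with `beta_x`, `beta_y`, `se_y`.
#' @return An `mr_result` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(pair) {
  if (pair$beta_x == 0) stop("degenerate instrument: beta_x = 0")
  beta_hat <- pair$beta_y / pair$beta_x
  se_hat <- pair$se_y / abs(pair$beta_x)
  pval <- 2 * stats::pnorm(-abs(beta_hat / se_hat))
  mr_result("wald_ratio", beta_hat, se_hat, pval, 1L)
}

#' Random-effects IVW causal estimate
#'
#' Weighted least squares of `beta_y` on `beta_x` through the origin with
#' weights `1/se_y^2`.  The fixed-effects SE is inflated by
#' `sqrt(max(Q/(n-1), 1))` (multiplicative random effects, floored at no
#' shrinkage).  With a single pair this reduces to [wald_ratio()].
#'
#' @param hset A `harmonized_set` (or a data.frame of pairs).
#' @return An `mr_result`.
#' @export
mr_ivw <- function(hset) {
  p <- pairs_of(hset)
  n <- nrow(p)
  if (n == 0) stop("no harmonized pairs: insufficient instruments for IVW")
  if (n == 1) return(wald_ratio(p[1, ]))
  w <- 1 / p$se_y^2
  sxx <- sum(p$beta_x^2 * w)
  beta_hat <- sum(p$beta_x * p$beta_y * w) / sxx
  se_fixed <- 1 / sqrt(sxx)
  q <- sum(w * (p$beta_y - beta_hat * p$beta_x)^2)
  phi <- q / (n - 1)
  se_hat <- se_fixed * sqrt(max(phi, 1))
  pval <- 2 * stats::pnorm(-abs(beta_hat / se_hat))
  mr_result("ivw_random_effects", beta_hat, se_hat, pval, n)
}

#' Cochran's Q heterogeneity test across per-instrument Wald ratios
#'
#' `Q = sum_j w_j (r_j - beta_hat)^2` with `r_j = beta_y/beta_x` and
#' first-order weights `w_j = (beta_x/se_y)^2`; `Q ~ chi-square(n-1)` under
#' homogeneity.  P > 0.05 is read as absence of heterogeneity.
#'
#' @param hset A `harmonized_set` (or pair data.frame) with `n >= 2`.
#' @param beta_hat The IVW estimate; computed here if omitted.
#' @return List with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(hset, beta_hat = NULL) {
  p <- pairs_of(hset)
  n <- nrow(p)
  if (n < 2) stop("Cochran's Q requires at least 2 instruments")
  if (is.null(beta_hat)) beta_hat <- mr_ivw(p)$beta_hat
  r <- p$beta_y / p$beta_x
  w <- (p$beta_x / p$se_y)^2
  q <- sum(w * (r - beta_hat)^2)
  list(q_stat = q, q_df = n - 1L,
       q_pval = stats::pchisq(q, df = n - 1, lower.tail = FALSE))
}

#' MR-Egger regression: intercept test for directional pleiotropy and slope
#'
#' Each pair is first oriented so the exposure effect is nonnegative (both
#' betas negated where `beta_x < 0`; stored pairs are never altered).  Then
#' weighted least squares of `beta_y` on `beta_x` with intercept, weights
#' `1/se_y^2`.  Standard errors use a multiplicative dispersion floored at 1;
#' P values use the t distribution with n - 2 df.  A nonzero intercept
#' indicates directional pleiotropy; P > 0.05 is read as its absence.
#'
#' @param hset A `harmonized_set` (or pair data.frame) with `n >= 3`.
#' @return List of class `mr_egger` with `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_pval`, `egger_slope` (an
#'   `mr_result` with t-based P), `n_snps`.
#' @export
mr_egger <- function(hset) {
  p <- pairs_of(hset)
  n <- nrow(p)
  if (n < 3) stop("MR-Egger requires at least 3 instruments")
  s <- ifelse(p$beta_x < 0, -1, 1)
  bx <- s * p$beta_x
  by <- s * p$beta_y
  w <- 1 / p$se_y^2
  # Weighted normal equations for y = a + b x.
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= .Machine$double.eps * sw * swxx) {
    stop("degenerate Egger fit: exposure effects are collinear with the intercept")
  }
  b <- (sw * swxy - swx * swy) / det
  a <- (swy - b * swx) / sw
  rss <- sum(w * (by - a - b * bx)^2)
  sigma2 <- rss / (n - 2)
  disp <- max(sigma2, 1)   # multiplicative random effects, floored
  se_a <- sqrt(disp * swxx / det)
  se_b <- sqrt(disp * sw / det)
  p_a <- 2 * stats::pt(-abs(a / se_a), df = n - 2)
  p_b <- 2 * stats::pt(-abs(b / se_b), df = n - 2)
  slope <- mr_result("egger_slope", b, se_b, p_b, n)
  structure(list(egger_intercept = a, egger_intercept_se = se_a,
                 egger_intercept_pval = p_a, egger_slope = slope,
                 n_snps = as.integer(n)),
            class = "mr_egger")
}

#' Full sensitivity analysis: Cochran's Q plus MR-Egger intercept
#'
#' @param hset A `harmonized_set`.
#' @param ivw Optional precomputed IVW result (avoids refitting).
#' @return List of class `mr_sensitivity` combining [cochran_q()] and
#'   [mr_egger()] fields; Egger entries are `NA` when `n < 3`.
#' @export
mr_sensitivity <- function(hset, ivw = NULL) {
  p <- pairs_of(hset)
  n <- nrow(p)
  if (n < 2) stop("sensitivity analysis requires at least 2 instruments")
  if (is.null(ivw)) ivw <- mr_ivw(hset)
  q <- cochran_q(p, ivw$beta_hat)
  eg <- if (n >= 3) mr_egger(p) else NULL
  structure(list(
    q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval,
    egger_intercept = if (is.null(eg)) NA_real_ else eg$egger_intercept,
    egger_intercept_se = if (is.null(eg)) NA_real_ else eg$egger_intercept_se,
    egger_intercept_pval = if (is.null(eg)) NA_real_ else eg$egger_intercept_pval,
    egger_slope = if (is.null(eg)) NULL else eg$egger_slope,
    n_snps = n
  ), class = "mr_sensitivity")
}
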