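# Two-sample MR causal estimators.
#
# All estimators consume a "harmonized" data.frame (see harmonize()) whose
# rows carry per-SNP exposure effects gamma (beta_exp, se_exp) and outcome
# effects Gamma (beta_out, se_out) aligned to the same effect allele, and
# return a one-row mr_result data.frame: method, n_snp, beta, se, ci_low,
# ci_high, pvalue.  Confidence intervals are the normal approximation
# beta +/- 1.96 * se throughout.

.Z95 <- 1.96

.mr_result <- function(method, beta, se, pvalue, n_snp) {
  out <- data.frame(method = method, n_snp = as.integer(n_snp),
                    beta = beta, se = se,
                    ci_low = beta - .Z95 * se, ci_high = beta + .Z95 * se,
                    pvalue = pvalue, stringsAsFactors = FALSE)
  class(out) <- c("mr_result", "data.frame")
  out
}

.check_usable <- function(instruments, min_n, caller) {
  h <- instruments[is.na(instruments$excluded_reason), , drop = FALSE]
  if (nrow(h) < min_n)
    stop(caller, ": at least ", min_n, " usable instrument(s) required, got ",
         nrow(h))
  h
}

.ratios <- function(h) h$beta_out / h$beta_exp
# first-order variance of the per-SNP Wald ratio
.ratio_var <- function(h) h$se_out^2 / h$beta_exp^2

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate Gamma/gamma.  The default standard error is
#' the first-order delta approximation `se_out / |beta_exp|`; the
#' second-order form adds the exposure-uncertainty term
#' `beta_out^2 * se_exp^2 / beta_exp^4`.
#'
#' @param h A one-row harmonized instrument (or a harmonized data.frame,
#'   first usable row taken).
#' @param se_order `"first"` (default) or `"second"`.
#' @return An `mr_result` row with method `"wald"`.
#' @export
wald_ratio <- function(h, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  h <- .check_usable(h, 1, "wald_ratio")[1, ]
  if (h$beta_exp == 0) stop("wald_ratio: beta_exp must be nonzero")
  beta <- h$beta_out / h$beta_exp
  se <- if (se_order == "first") h$se_out / abs(h$beta_exp) else
    sqrt(h$se_out^2 / h$beta_exp^2 + h$beta_out^2 * h$se_exp^2 / h$beta_exp^4)
  p <- 2 * stats::pnorm(-abs(beta / se))
  .mr_result("wald", beta, se, p, 1L)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with weights `1/se_out^2`:
#' `beta = sum(w * gamma * Gamma) / sum(w * gamma^2)`.  The fixed-effect
#' standard error is `1/sqrt(sum(gamma^2/se_out^2))`; under multiplicative
#' random effects it is inflated by `max(1, sqrt(Q/(n-1)))` where Q is the
#' Cochran heterogeneity statistic.  P-values are two-sided normal.
#'
#' @param instruments A harmonized data.frame with >= 1 usable instrument.
#' @param re_mode `"multiplicative_random"` (default, the headline flavor
#'   for more than one SNP) or `"fixed"`.  A single instrument always uses
#'   the fixed-effect SE (identical to the Wald ratio).
#' @return An `mr_result` row with method `"ivw_mre"` or `"ivw_fixed"`.
#' @export
ivw <- function(instruments,
                re_mode = c("multiplicative_random", "fixed")) {
  re_mode <- match.arg(re_mode)
  h <- .check_usable(instruments, 1, "ivw")
  n <- nrow(h)
  w <- 1 / h$se_out^2
  beta <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  se <- 1 / sqrt(sum(h$beta_exp^2 / h$se_out^2))
  method <- "ivw_fixed"
  if (re_mode == "multiplicative_random") {
    if (n == 1) {
      message("ivw: single instrument; multiplicative random effects needs df, using fixed-effect SE")
    } else {
      q <- sum(w * (h$beta_out - beta * h$beta_exp)^2)
      se <- se * max(1, sqrt(q / (n - 1)))
      method <- "ivw_mre"
    }
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  .mr_result(method, beta, se, p, n)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects *with* an
#' intercept (weights `1/se_out^2`), after orienting every instrument so
#' that its exposure effect is positive.  The slope estimates the causal
#' effect; a nonzero intercept indicates directional horizontal pleiotropy.
#' Standard errors use multiplicative random-effects scaling (residual SD
#' floored at 1) and p-values are two-sided t with `n - 2` df.
#'
#' @param instruments A harmonized data.frame with >= 3 usable instruments.
#' @return A list with `slope` and `intercept`, each an `mr_result` row
#'   (methods `"egger_slope"`, `"egger_intercept"`).
#' @export
mr_egger <- function(instruments) {
  h <- .check_usable(instruments, 3, "mr_egger")
  n <- nrow(h)
  # orient to positive exposure effects (InSIDE parameterization)
  sgn <- sign(h$beta_exp)
  sgn[sgn == 0] <- 1
  x <- h$beta_exp * sgn
  y <- h$beta_out * sgn
  w <- 1 / h$se_out^2
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  scale <- max(1, sm$sigma) / sm$sigma
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"] * scale
  pv <- 2 * stats::pt(-abs(est / se), df = n - 2)
  list(slope = .mr_result("egger_slope", est["x"], se["x"], pv["x"], n),
       intercept = .mr_result("egger_intercept", est["(Intercept)"],
                              se["(Intercept)"], pv["(Intercept)"], n))
}

.boot_se <- function(h, estimator, n_boot, seed) {
  withr::with_seed(seed, {
    n <- nrow(h)
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(n, h$beta_exp, h$se_exp)
      by <- stats::rnorm(n, h$beta_out, h$se_out)
      hb <- h
      hb$beta_exp <- bx
      hb$beta_out <- by
      estimator(hb)
    }, numeric(1))
    stats::sd(est)
  })
}

.weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The weighted median of the per-SNP Wald ratios, with weights proportional
#' to the inverse first-order ratio variance.  The estimate is the linear
#' interpolation of the weighted empirical CDF at 0.5, using standardized
#' cumulative weights `s_j = (cum_j - w_j/2) / sum(w)`.  It is consistent
#' when instruments carrying at least half the weight are valid.  The SE is
#' a seeded parametric bootstrap (per-SNP effects resampled from normal
#' distributions centred on the observed effects).
#'
#' @param instruments A harmonized data.frame with >= 3 usable instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return An `mr_result` row with method `"weighted_median"`.
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed = 1L) {
  h <- .check_usable(instruments, 3, "weighted_median")
  point <- function(hh) {
    .weighted_median_point(.ratios(hh), 1 / (hh$se_out^2 / hh$beta_exp^2))
  }
  beta <- point(h)
  se <- .boot_se(h, point, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(beta / se))
  .mr_result("weighted_median", beta, se, p, nrow(h))
}

.mode_point <- function(ratios, weights, phi, grid_n = 512L) {
  s <- stats::sd(ratios)
  iqr <- stats::IQR(ratios)
  bw <- phi * 0.9 * min(s, iqr / 1.349) * length(ratios)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(list(beta = ratios[1], bw = 0))
  grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw, length.out = grid_n)
  w <- weights / sum(weights)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm((g - ratios) / bw)) / bw, numeric(1))
  list(beta = grid[which.max(dens)], bw = bw)
}

#' Mode-based estimators (simple and weighted)
#'
#' The mode of the smoothed empirical density of per-SNP Wald ratios: valid
#' when the largest group of instruments sharing a ratio is valid (ZEMPA).
#' Bandwidth is `phi * 0.9 * min(sd, IQR/1.349) * n^(-1/5)` over the ratios;
#' the density (Gaussian kernels; unweighted for `"simple"`,
#' inverse-variance weighted for `"weighted"`) is maximized over a fixed
#' grid of 512 points spanning the ratios plus/minus 3 bandwidths.  If all
#' ratios coincide the common ratio is returned.  SE by the same parametric
#' bootstrap as [weighted_median()].
#'
#' @param instruments A harmonized data.frame with >= 3 usable instruments.
#' @param variant `"simple"` or `"weighted"`.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot,seed Bootstrap settings.
#' @return An `mr_result` row with method `"simple_mode"` or
#'   `"weighted_mode"`; the bandwidth used is attached as attribute
#'   `"bandwidth"`.
#' @export
mode_estimate <- function(instruments, variant = c("simple", "weighted"),
                          phi = 1, n_boot = 1000, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(phi > 0)
  h <- .check_usable(instruments, 3, "mode_estimate")
  wts <- function(hh) {
    if (variant == "simple") rep(1, nrow(hh)) else hh$beta_exp^2 / hh$se_out^2
  }
  pt0 <- .mode_point(.ratios(h), wts(h), phi)
  point <- function(hh) .mode_point(.ratios(hh), wts(hh), phi)$beta
  se <- .boot_se(h, point, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(pt0$beta / se))
  out <- .mr_result(paste0(variant, "_mode"), pt0$beta, se, p, nrow(h))
  attr(out, "bandwidth") <- pt0$bw
  out
}

#' Multivariable IVW
#'
#' Weighted least squares of the per-SNP outcome effects on K columns of
#' exposure effects, without intercept, weights `1/se_out^2`.  In the
#' two-step mediation design the columns are (exposure, mediator) and the
#' mediator's coefficient is its effect on the outcome adjusted for the
#' exposure (beta2); the exposure's coefficient is the direct effect.
#' Standard errors use multiplicative random-effects scaling (residual SD
#' floored at 1); p-values two-sided normal.
#'
#' @param beta_exp Numeric matrix (n_snp x K) of per-SNP effects on the K
#'   exposures; column names label the estimates.
#' @param beta_out,se_out Per-SNP outcome effects and SEs (aligned alleles).
#' @param cond_tol Maximum acceptable condition number of the weighted
#'   design (default 1e8); beyond it the exposures are declared collinear.
#' @return An `mr_result` data.frame with one row per exposure (method
#'   `"mvmr_ivw"`, `exposure` column prepended).
#' @export
mvmr_ivw <- function(beta_exp, beta_out, se_out, cond_tol = 1e8) {
  X <- as.matrix(beta_exp)
  k <- ncol(X)
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(k))
  if (n <= k) stop("mvmr_ivw: need more SNPs (", n, ") than exposures (", k, ")")
  if (any(se_out <= 0)) stop("mvmr_ivw: se_out must be positive")
  Xw <- X / se_out
  if (kappa(Xw) > cond_tol)
    stop("mvmr_ivw: exposure effect columns are collinear (condition number > ",
         format(cond_tol), ")")
  fit <- stats::lm(beta_out ~ 0 + X, weights = 1 / se_out^2)
  sm <- summary(fit)
  scale <- max(1, sm$sigma) / sm$sigma
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"] * scale
  p <- 2 * stats::pnorm(-abs(est / se))
  out <- .mr_result("mvmr_ivw", unname(est), unname(se), unname(p), n)
  out <- cbind(exposure = colnames(X), out, stringsAsFactors = FALSE)
  class(out) <- c("mr_result", "data.frame")
  out
}

#' Run the univariable estimator battery
#'
#' Convenience wrapper running the Wald ratio / IVW headline plus MR-Egger,
#' weighted median and the two mode estimators where the instrument count
#' permits (Egger, median and modes need >= 3 SNPs).
#'
#' @param instruments A harmonized data.frame.
#' @param re_mode IVW flavor, see [ivw()].
#' @param phi,n_boot,seed Pass-throughs for the median/mode bootstrap.
#' @return An `mr_result` data.frame, one row per method; the IVW row is
#'   the headline estimate.
#' @export
mr_all_methods <- function(instruments, re_mode = "multiplicative_random",
                           phi = 1, n_boot = 1000, seed = 1L) {
  h <- .check_usable(instruments, 1, "mr_all_methods")
  n <- nrow(h)
  rows <- list(ivw(h, re_mode = re_mode))
  if (n >= 3) {
    eg <- mr_egger(h)
    rows <- c(rows, list(eg$slope, eg$intercept),
              list(weighted_median(h, n_boot = n_boot, seed = seed),
                   mode_estimate(h, "simple", phi, n_boot, seed),
                   mode_estimate(h, "weighted", phi, n_boot, seed)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
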