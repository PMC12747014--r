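# Heterogeneity, pleiotropy and influence diagnostics.

#' Cochran Q heterogeneity statistic
#'
#' `Q = sum(w_j * (r_j - pooled_beta)^2)` over the per-SNP Wald ratios
#' `r_j`, with `w_j` the inverse first-order ratio variance
#' (`beta_exp^2 / se_out^2`), matching the IVW weighting.  P-value from the
#' chi-square distribution with `n - 1` df; `I2 = max(0, (Q - df)/Q)`.
#'
#' @param instruments A harmonized data.frame with >= 2 usable instruments.
#' @param pooled_beta The pooled causal estimate the ratios are compared
#'   against; defaults to the headline IVW beta on the same instruments.
#' @return A list with `q`, `df`, `pvalue`, `i2`.
#' @export
cochran_q <- function(instruments, pooled_beta = NULL) {
  h <- .check_usable(instruments, 2, "cochran_q")
  if (is.null(pooled_beta)) pooled_beta <- ivw(h)$beta
  r <- .ratios(h)
  w <- 1 / .ratio_var(h)
  q <- sum(w * (r - pooled_beta)^2)
  df <- nrow(h) - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  list(q = q, df = df, pvalue = stats::pchisq(q, df, lower.tail = FALSE),
       i2 = i2)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate omitting each instrument in turn, to flag
#' results driven by a single SNP.
#'
#' @param instruments A harmonized data.frame with >= 2 usable instruments.
#' @param re_mode IVW flavor passed to [ivw()].
#' @return A data.frame with one row per left-out SNP: `snp_left_out`,
#'   `n_snp`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`.
#' @export
leave_one_out <- function(instruments, re_mode = "multiplicative_random") {
  h <- .check_usable(instruments, 2, "leave_one_out")
  rows <- lapply(seq_len(nrow(h)), function(i) {
    est <- ivw(h[-i, , drop = FALSE], re_mode = re_mode)
    cbind(snp_left_out = h$snp_id[i],
          est[, c("n_snp", "beta", "se", "ci_low", "ci_high", "pvalue")],
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Egger-intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression with its SE and two-sided t
#' p-value (`n - 2` df); an intercept distinguishable from zero indicates
#' directional horizontal pleiotropy.
#'
#' @param instruments A harmonized data.frame with >= 3 usable instruments.
#' @return A list with `intercept`, `se`, `pvalue`.
#' @export
pleiotropy_test <- function(instruments) {
  eg <- mr_egger(instruments)$intercept
  list(intercept = eg$beta, se = eg$se, pvalue = eg$pvalue)
}

#' Full sensitivity report
#'
#' Bundles Cochran Q (against the supplied or headline IVW beta), the
#' Egger-intercept pleiotropy test (>= 3 SNPs) and the leave-one-out table.
#'
#' @param instruments A harmonized data.frame with >= 2 usable instruments.
#' @param pooled_beta Optional pooled beta for Q, see [cochran_q()].
#' @return A list of class `"sensitivity_report"`: `q`, `q_df`, `q_pvalue`,
#'   `i2`, `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`
#'   (NA below 3 SNPs), `loo`.
#' @export
sensitivity_report <- function(instruments, pooled_beta = NULL) {
  h <- .check_usable(instruments, 2, "sensitivity_report")
  qq <- cochran_q(h, pooled_beta)
  eg <- if (nrow(h) >= 3) pleiotropy_test(h) else
    list(intercept = NA_real_, se = NA_real_, pvalue = NA_real_)
  structure(list(q = qq$q, q_df = qq$df, q_pvalue = qq$pvalue, i2 = qq$i2,
                 egger_intercept = eg$intercept,
                 egger_intercept_se = eg$se,
                 egger_intercept_p = eg$pvalue,
                 loo = leave_one_out(h)),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Cochran Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
              x$q, x$q_df, x$q_pvalue, 100 * x$i2))
  if (!is.na(x$egger_intercept))
    cat(sprintf("Egger intercept = %.4f (SE %.4f, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  cat(sprintf("Leave-one-out: %d refits\n", nrow(x$loo)))
  invisible(x)
}
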