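# Two-step mediation decomposition and the mediated-proportion report.

#' Two-step MR mediation decomposition
#'
#' Decomposes a total causal effect into the path through a mediator and
#' the remainder.  With beta1 the exposure->mediator effect, beta2 the
#' mediator->outcome effect adjusted for the exposure, and beta0 the total
#' exposure->outcome effect:
#' indirect = beta1 * beta2, direct = beta0 - indirect, and the proportion
#' mediated = indirect / beta0.
#'
#' The indirect-effect SE uses the product delta method
#' (`indirect_se^2 = beta1^2 se2^2 + beta2^2 se1^2`).  The proportion SE
#' uses the full three-term delta method
#' `|proportion| * sqrt((se1/beta1)^2 + (se2/beta2)^2 + (se0/beta0)^2)`,
#' assuming the three estimates come from non-overlapping samples and are
#' independent; its 95% CI is `proportion +/- 1.96 * proportion_se`.  When
#' the indirect and total effects have opposite signs the estimate is
#' flagged `sign_inconsistent` (reported, not suppressed).
#'
#' @param beta1,se1 Exposure->mediator effect and SE (step 1).
#' @param beta2,se2 Mediator->outcome effect adjusted for exposure and SE
#'   (step 2, multivariable).
#' @param beta0,se0 Total exposure->outcome effect and SE (must have
#'   `beta0 != 0`).
#' @return A list of class `"mediation_estimate"` with fields `beta1`,
#'   `se1`, `beta2`, `se2`, `beta0`, `se0`, `indirect`, `indirect_se`,
#'   `direct`, `proportion`, `proportion_se`, `prop_ci_low`,
#'   `prop_ci_high`, `sign_inconsistent`.
#' @export
two_step_mediation <- function(beta1, se1, beta2, se2, beta0, se0) {
  stopifnot(se1 > 0, se2 > 0, se0 > 0)
  if (beta0 == 0) stop("two_step_mediation: beta0 must be nonzero")
  indirect <- beta1 * beta2
  indirect_se <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  direct <- beta0 - indirect
  proportion <- indirect / beta0
  if (beta1 == 0 || beta2 == 0) {
    # ratio delta method degenerates; only the product term contributes
    proportion_se <- indirect_se / abs(beta0)
  } else {
    proportion_se <- abs(proportion) *
      sqrt((se1 / beta1)^2 + (se2 / beta2)^2 + (se0 / beta0)^2)
  }
  structure(list(
    beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
    beta0 = beta0, se0 = se0,
    indirect = indirect, indirect_se = indirect_se,
    direct = direct,
    proportion = proportion, proportion_se = proportion_se,
    prop_ci_low = proportion - .Z95 * proportion_se,
    prop_ci_high = proportion + .Z95 * proportion_se,
    sign_inconsistent = indirect * beta0 < 0),
    class = "mediation_estimate")
}

#' @export
print.mediation_estimate <- function(x, ...) {
  cat(sprintf("indirect = %.4f (SE %.4f), direct = %.4f, total = %.4f\n",
              x$indirect, x$indirect_se, x$direct, x$beta0))
  cat(sprintf("proportion mediated = %.2f%% (95%% CI %.2f%%, %.2f%%)%s\n",
              100 * x$proportion, 100 * x$prop_ci_low, 100 * x$prop_ci_high,
              if (x$sign_inconsistent) "  [sign-inconsistent]" else ""))
  invisible(x)
}

#' Mediated-proportion report table
#'
#' Applies [two_step_mediation()] to each row of step estimates and returns
#' a report in the conventional layout (exposure, beta1(SE), mediator,
#' beta2(SE), outcome, beta0(SE), proportion with 95% CI), sorted by
#' descending proportion within each outcome.  Malformed rows are recorded
#' with an error message and the remainder processed.
#'
#' @param rows A data.frame with columns `exposure`, `mediator`, `outcome`,
#'   `beta1`, `se1`, `beta2`, `se2`, `beta0`, `se0`.
#' @return A data.frame of class `"mediation_table"` with the input
#'   columns plus `indirect`, `indirect_se`, `direct`, `proportion`,
#'   `proportion_se`, `prop_ci_low`, `prop_ci_high`, `sign_inconsistent`,
#'   `error` (NA for clean rows).
#' @export
mediation_table <- function(rows) {
  rows <- as.data.frame(rows)
  need <- c("exposure", "mediator", "outcome",
            "beta1", "se1", "beta2", "se2", "beta0", "se0")
  missing <- setdiff(need, names(rows))
  if (length(missing))
    stop("mediation_table: missing column(s): ", paste(missing, collapse = ", "))
  extra <- data.frame(indirect = NA_real_, indirect_se = NA_real_,
                      direct = NA_real_, proportion = NA_real_,
                      proportion_se = NA_real_, prop_ci_low = NA_real_,
                      prop_ci_high = NA_real_, sign_inconsistent = NA,
                      error = NA_character_)
  out <- cbind(rows, extra[rep(1, nrow(rows)), , drop = FALSE])
  for (i in seq_len(nrow(out))) {
    m <- tryCatch(
      two_step_mediation(out$beta1[i], out$se1[i], out$beta2[i],
                         out$se2[i], out$beta0[i], out$se0[i]),
      error = function(e) e)
    if (inherits(m, "error")) {
      out$error[i] <- conditionMessage(m)
      next
    }
    out$indirect[i] <- m$indirect
    out$indirect_se[i] <- m$indirect_se
    out$direct[i] <- m$direct
    out$proportion[i] <- m$proportion
    out$proportion_se[i] <- m$proportion_se
    out$prop_ci_low[i] <- m$prop_ci_low
    out$prop_ci_high[i] <- m$prop_ci_high
    out$sign_inconsistent[i] <- m$sign_inconsistent
    if (isTRUE(m$sign_inconsistent))
      warning("mediation_table: sign-inconsistent mediation for mediator '",
              out$mediator[i], "' on outcome '", out$outcome[i], "'",
              call. = FALSE)
  }
  ord <- order(out$outcome, -ifelse(is.na(out$proportion), -Inf, out$proportion),
               out$mediator)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mediation_table", "data.frame")
  out
}

#' Format a mediation table for display
#'
#' @param x A [mediation_table()] result.
#' @return A character data.frame mirroring the conventional published
#'   layout, proportions as percentages with 95% CIs.
#' @export
format_mediation_table <- function(x) {
  data.frame(
    Exposure = x$exposure,
    `beta1(SE)` = sprintf("%.3f (%.3f)", x$beta1, x$se1),
    Mediator = x$mediator,
    `beta2(SE)` = sprintf("%.3f (%.3f)", x$beta2, x$se2),
    Outcome = x$outcome,
    `beta0(SE)` = sprintf("%.3f (%.3f)", x$beta0, x$se0),
    `Mediation proportion` = sprintf("%.2f%% (%.2f%%, %.2f%%)",
                                     100 * x$proportion,
                                     100 * x$prop_ci_low,
                                     100 * x$prop_ci_high),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Worked mediation examples: birth weight, gut microbiota and lung function
#'
#' Step estimates (beta1: birth weight -> microbial trait; beta2: microbial
#' trait -> lung-function measure adjusted for birth weight; beta0: total
#' birth weight -> lung-function effect) for five gut-microbiota mediators
#' and three spirometric outcomes, transcribed from a published two-step MR
#' mediation study of birth weight and adult lung function.  The
#' `reported_proportion` column holds the published mediated proportions
#' (percent) for comparison against [two_step_mediation()] output.
#'
#' @return A data.frame with columns `exposure`, `mediator`, `outcome`,
#'   `beta1`, `se1`, `beta2`, `se2`, `beta0`, `se0`,
#'   `reported_proportion`, `reported_ci_low`, `reported_ci_high`.
#' @export
lung_mediation_examples <- function() {
  path <- system.file("extdata", "birthweight_lung_mediation.tsv",
                      package = "mrmediate", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
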