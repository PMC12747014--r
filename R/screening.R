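# Orchestration of the full two-step MR mediation study:
# exposure -> outcome total effects, exposure -> mediator screen with a
# reverse-MR guard, multivariable mediator -> outcome effects adjusted for
# the exposure, and the mediated-proportion report.

#' Screening-pipeline configuration
#'
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param fallback_p Relaxed threshold used when fewer than `min_snps`
#'   variants reach `p_threshold` (default 1e-5).
#' @param clump_r2,clump_kb LD-clumping parameters (defaults 0.01, 10000).
#' @param f_min Minimum instrument F statistic (default 10).
#' @param min_snps Minimum instrument count before the fallback threshold
#'   triggers (default 3).
#' @param alpha Significance level for qualification (default 0.05).
#' @param mtc Multiple-testing correction across mediators: `"none"`
#'   (default) or `"bh_fdr"` (Benjamini-Hochberg, recommended for large
#'   panels).
#' @param seed RNG seed for bootstrap standard errors.
#' @param re_mode IVW flavor, see [ivw()].
#' @param phi Mode-estimator bandwidth multiplier.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @return A validated list of class `"screen_config"`.
#' @export
screen_config <- function(p_threshold = 5e-8, fallback_p = 1e-5,
                          clump_r2 = 0.01, clump_kb = 10000, f_min = 10,
                          min_snps = 3, alpha = 0.05,
                          mtc = c("none", "bh_fdr"), seed = 1L,
                          re_mode = "multiplicative_random", phi = 1,
                          n_boot = 1000) {
  mtc <- match.arg(mtc)
  stopifnot(p_threshold > 0, p_threshold < 1, fallback_p > 0, fallback_p < 1,
            p_threshold <= fallback_p, clump_r2 > 0, clump_r2 <= 1,
            clump_kb > 0, f_min >= 0, min_snps >= 1,
            alpha > 0, alpha < 1, phi > 0, n_boot >= 1)
  structure(list(p_threshold = p_threshold, fallback_p = fallback_p,
                 clump_r2 = clump_r2, clump_kb = clump_kb, f_min = f_min,
                 min_snps = min_snps, alpha = alpha, mtc = mtc,
                 seed = as.integer(seed), re_mode = re_mode, phi = phi,
                 n_boot = as.integer(n_boot)),
            class = "screen_config")
}

.trait_id <- function(x, default) attr(x, "trait_id") %||% default

# Align mediator and outcome effects to the exposure table's effect alleles
# for a set of SNP ids; returns NULL when fewer than min_n SNPs survive.
.align_joint <- function(snp_ids, exposure, mediator, outcome, min_n = 1L) {
  ex <- as.data.frame(exposure)
  ref <- ex[match(snp_ids, ex$SNP), , drop = FALSE]
  ref <- ref[!is.na(ref$SNP), , drop = FALSE]
  if (nrow(ref) < min_n) return(NULL)
  hm <- usable_instruments(harmonize(ref, mediator))
  ho <- usable_instruments(harmonize(ref, outcome))
  ids <- intersect(hm$snp_id, ho$snp_id)
  if (length(ids) < min_n) return(NULL)
  hm <- hm[match(ids, hm$snp_id), ]
  ho <- ho[match(ids, ho$snp_id), ]
  ref <- ref[match(ids, ref$SNP), ]
  list(snp = ids,
       beta_exp = ref$BETA, se_exp = ref$SE,
       beta_med = hm$beta_out, se_med = hm$se_out,
       beta_out = ho$beta_out, se_out = ho$se_out)
}

#' Total-effect MR of an exposure on an outcome
#'
#' Selects instruments from the exposure table (significance threshold with
#' fallback, LD clumping, F filter), harmonizes them with the outcome, and
#' runs the full estimator battery plus sensitivity diagnostics.  The IVW
#' row is the headline (total-effect) estimate.
#'
#' @param exposure,outcome [sumstats] tables.
#' @param ld An [ld_matrix()].
#' @param cfg A [screen_config()].
#' @return A list with `estimates` (`mr_result` rows; `NULL` when no
#'   instruments survive), `headline` (the IVW row), `diagnostics`
#'   ([sensitivity_report()] or `NULL`), `instruments` (the selection
#'   ledger), `harmonized`, and `no_instruments`.
#' @export
run_total_effect <- function(exposure, outcome, ld, cfg = screen_config()) {
  sel <- select_instruments(exposure, ld, cfg)
  if (sel$no_instruments)
    return(list(estimates = NULL, headline = NULL, diagnostics = NULL,
                instruments = sel, harmonized = NULL, no_instruments = TRUE))
  h <- usable_instruments(harmonize(sel$kept, outcome))
  if (nrow(h) == 0)
    return(list(estimates = NULL, headline = NULL, diagnostics = NULL,
                instruments = sel, harmonized = NULL, no_instruments = TRUE))
  est <- mr_all_methods(h, re_mode = cfg$re_mode, phi = cfg$phi,
                        n_boot = cfg$n_boot, seed = cfg$seed)
  diag <- if (nrow(h) >= 2)
    sensitivity_report(h, pooled_beta = est$beta[est$method %in%
                                                   c("ivw_mre", "ivw_fixed")][1])
  else NULL
  list(estimates = est,
       headline = est[grep("^ivw", est$method), , drop = FALSE][1, ],
       diagnostics = diag, instruments = sel, harmonized = h,
       no_instruments = FALSE)
}

.ivw_step <- function(instr_rows, target_table, cfg) {
  h <- usable_instruments(harmonize(instr_rows, target_table))
  if (nrow(h) == 0) return(NULL)
  ivw(h, re_mode = cfg$re_mode)
}

#' Screen a panel of candidate mediators
#'
#' Runs the full two-step design over one exposure, a panel of candidate
#' mediators and one or more outcomes:
#' \enumerate{
#'   \item total effects: exposure -> each outcome (beta0, headline IVW);
#'   \item step 1: exposure -> each mediator (beta1, IVW over the
#'     exposure's instruments);
#'   \item reverse guard: mediator -> exposure MR over the mediator's own
#'     instruments; a significant reverse IVW disqualifies the mediator;
#'   \item step 2: multivariable IVW of each outcome on (exposure,
#'     mediator) over the clumped union of both instrument sets; the
#'     mediator coefficient is beta2, adjusted for the exposure;
#'   \item qualification: step-1 and step-2 IVW p below `alpha` (after the
#'     configured multiple-testing correction across mediators) and a
#'     non-significant reverse estimate;
#'   \item mediation report: [mediation_table()] rows for qualified
#'     (mediator, outcome) pairs whose outcome shows a significant total
#'     effect.
#' }
#' Per-mediator failures (no instruments, harmonization losses) are
#' recorded and never abort the screen.  Deterministic given `cfg`.
#'
#' @param exposure A [sumstats] table.
#' @param mediators Named list of [sumstats] tables.
#' @param outcomes Named list of [sumstats] tables.
#' @param ld An [ld_matrix()] covering all traits' SNPs.
#' @param cfg A [screen_config()].
#' @return A list of class `"screen_result"`: `total` (per-outcome
#'   [run_total_effect()] results), `step1`, `reverse`, `step2` (per
#'   mediator / pair estimate tables), `qualified` (data.frame mediator x
#'   outcome with the qualification verdict and reasons),
#'   `qualified_mediators`, `mediation_report`, `counts`, `cfg`.
#' @export
screen_mediators <- function(exposure, mediators, outcomes, ld,
                             cfg = screen_config()) {
  stopifnot(length(mediators) >= 1, length(outcomes) >= 1)
  if (is.null(names(mediators)))
    names(mediators) <- paste0("mediator_", seq_along(mediators))
  if (is.null(names(outcomes)))
    names(outcomes) <- paste0("outcome_", seq_along(outcomes))
  exposure_id <- .trait_id(exposure, "exposure")

  # exposure -> outcome total effects (beta0)
  total <- lapply(outcomes, function(o) run_total_effect(exposure, o, ld, cfg))

  # exposure instruments, selected once
  exp_sel <- select_instruments(exposure, ld, cfg)

  step1 <- list(); reverse <- list(); step2 <- list()
  med_sel <- list()
  for (m in names(mediators)) {
    step1[[m]] <- tryCatch(
      if (exp_sel$no_instruments) NULL else
        .ivw_step(exp_sel$kept, mediators[[m]], cfg),
      error = function(e) NULL)
    med_sel[[m]] <- select_instruments(mediators[[m]], ld, cfg)
    reverse[[m]] <- tryCatch(
      if (med_sel[[m]]$no_instruments) NULL else
        .ivw_step(med_sel[[m]]$kept, exposure, cfg),
      error = function(e) NULL)
  }

  # step 2: MVMR of outcome on (exposure, mediator) over the clumped union
  for (m in names(mediators)) {
    step2[[m]] <- list()
    for (o in names(outcomes)) {
      step2[[m]][[o]] <- tryCatch({
        un <- rbind(exp_sel$kept, med_sel[[m]]$kept)
        un <- un[order(un$P), , drop = FALSE]
        un <- un[!duplicated(un$SNP), , drop = FALSE]
        un <- ld_clump(un, ld, cfg$clump_r2, cfg$clump_kb)$kept
        al <- .align_joint(un$SNP, exposure, mediators[[m]], outcomes[[o]],
                           min_n = 3L)
        if (is.null(al)) NULL else {
          X <- cbind(exposure = al$beta_exp, mediator = al$beta_med)
          est <- mvmr_ivw(X, al$beta_out, al$se_out)
          est[est$exposure == "mediator", , drop = FALSE]
        }
      }, error = function(e) NULL)
    }
  }

  # qualification
  p1 <- vapply(step1, function(x) if (is.null(x)) NA_real_ else x$pvalue,
               numeric(1))
  if (cfg$mtc == "bh_fdr") p1 <- stats::p.adjust(p1, method = "BH")
  verdict <- expand.grid(mediator = names(mediators),
                         outcome = names(outcomes),
                         stringsAsFactors = FALSE)
  verdict$step1_p <- p1[verdict$mediator]
  verdict$reverse_p <- vapply(reverse[verdict$mediator], function(x)
    if (is.null(x)) NA_real_ else x$pvalue, numeric(1))
  verdict$step2_p <- vapply(seq_len(nrow(verdict)), function(i) {
    x <- step2[[verdict$mediator[i]]][[verdict$outcome[i]]]
    if (is.null(x)) NA_real_ else x$pvalue
  }, numeric(1))
  if (cfg$mtc == "bh_fdr")
    verdict$step2_p <- stats::p.adjust(verdict$step2_p, method = "BH")
  sig1 <- !is.na(verdict$step1_p) & verdict$step1_p < cfg$alpha
  sig2 <- !is.na(verdict$step2_p) & verdict$step2_p < cfg$alpha
  # a mediator with no reverse-direction instruments passes the guard
  rev_ok <- is.na(verdict$reverse_p) | verdict$reverse_p >= cfg$alpha
  verdict$qualified <- sig1 & sig2 & rev_ok
  verdict$reason <- ifelse(verdict$qualified, "qualified",
                    ifelse(!sig1, "step1_not_significant",
                    ifelse(!rev_ok, "reverse_causation",
                           "step2_not_significant")))

  # mediation report for qualified pairs whose outcome beta0 is significant
  rows <- list()
  for (i in which(verdict$qualified)) {
    m <- verdict$mediator[i]; o <- verdict$outcome[i]
    tot <- total[[o]]$headline
    if (is.null(tot) || tot$pvalue >= cfg$alpha) next
    s1 <- step1[[m]]; s2 <- step2[[m]][[o]]
    rows[[length(rows) + 1]] <- data.frame(
      exposure = exposure_id, mediator = m, outcome = o,
      beta1 = s1$beta, se1 = s1$se, beta2 = s2$beta, se2 = s2$se,
      beta0 = tot$beta, se0 = tot$se, stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) mediation_table(do.call(rbind, rows)) else NULL

  counts <- list(
    n_mediators = length(mediators), n_outcomes = length(outcomes),
    exposure_instruments = nrow(exp_sel$kept),
    exposure_candidates = nrow(exp_sel$kept) + length(exp_sel$dropped),
    mediator_instruments = vapply(med_sel, function(s) nrow(s$kept),
                                  integer(1)),
    n_qualified_pairs = sum(verdict$qualified),
    n_mediation_rows = if (is.null(report)) 0L else nrow(report))

  structure(list(total = total, step1 = step1, reverse = reverse,
                 step2 = step2, qualified = verdict,
                 qualified_mediators = sort(unique(
                   verdict$mediator[verdict$qualified])),
                 mediation_report = report, counts = counts,
                 exposure_selection = exp_sel, mediator_selection = med_sel,
                 cfg = cfg),
            class = "screen_result")
}

.tidy_estimates <- function(result) {
  rows <- list()
  add <- function(exposure, outcome, est) {
    if (is.null(est)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      exposure = exposure, outcome = outcome, method = est$method,
      nsnp = est$n_snp, b = est$beta, se = est$se,
      ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pvalue,
      stringsAsFactors = FALSE)
  }
  for (o in names(result$total)) add("exposure", o, result$total[[o]]$estimates)
  for (m in names(result$step1)) add("exposure", m, result$step1[[m]])
  for (m in names(result$reverse)) add(m, "exposure", result$reverse[[m]])
  for (m in names(result$step2)) {
    for (o in names(result$step2[[m]])) {
      est <- result$step2[[m]][[o]]
      if (!is.null(est))
        add(m, o, est[, setdiff(names(est), "exposure"), drop = FALSE])
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a screen result to disk
#'
#' Writes tidy tab-delimited outputs: `estimates.tsv` (all MR estimates),
#' `mediation.tsv` (the mediated-proportion report; header-only when no
#' pair qualified), `qualification.tsv` (the per-pair verdict),
#' `leave_one_out.tsv` (per-outcome influence refits) and `manifest.json`
#' (configuration, seed, package version and filter counts).
#'
#' @param result A [screen_mediators()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
summarize_screen <- function(result, out_dir) {
  stopifnot(inherits(result, "screen_result"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("summarize_screen: cannot create output directory ", out_dir)
  wt <- function(d, f) {
    p <- file.path(out_dir, f)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    p
  }
  files <- character(0)
  est <- .tidy_estimates(result)
  if (is.null(est))
    est <- data.frame(exposure = character(0), outcome = character(0),
                      method = character(0), nsnp = integer(0),
                      b = numeric(0), se = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), pval = numeric(0))
  files <- c(files, wt(est, "estimates.tsv"))
  med <- result$mediation_report
  if (is.null(med))
    med <- data.frame(exposure = character(0), mediator = character(0),
                      outcome = character(0), beta1 = numeric(0),
                      se1 = numeric(0), beta2 = numeric(0), se2 = numeric(0),
                      beta0 = numeric(0), se0 = numeric(0),
                      indirect = numeric(0), indirect_se = numeric(0),
                      direct = numeric(0), proportion = numeric(0),
                      proportion_se = numeric(0), prop_ci_low = numeric(0),
                      prop_ci_high = numeric(0), sign_inconsistent = logical(0),
                      error = character(0))
  files <- c(files, wt(as.data.frame(med), "mediation.tsv"))
  files <- c(files, wt(result$qualified, "qualification.tsv"))
  loo <- do.call(rbind, lapply(names(result$total), function(o) {
    d <- result$total[[o]]$diagnostics
    if (is.null(d)) return(NULL)
    cbind(outcome = o, d$loo, stringsAsFactors = FALSE)
  }))
  if (is.null(loo))
    loo <- data.frame(outcome = character(0), snp_left_out = character(0),
                      n_snp = integer(0), beta = numeric(0), se = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      pval = numeric(0))
  files <- c(files, wt(loo, "leave_one_out.tsv"))
  manifest <- list(
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    config = unclass(result$cfg),
    counts = result$counts,
    qualified_mediators = result$qualified_mediators)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mp)
  invisible(files)
}
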