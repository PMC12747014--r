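# Instrument selection: significance thresholding with a documented
# fallback, greedy LD clumping, and weak-instrument F filtering.

#' Construct an LD matrix object
#'
#' @param r2 Square symmetric matrix of squared correlations in \[0, 1\]
#'   with unit diagonal; dimnames give the SNP ids.
#' @param pos Optional data.frame with columns `SNP`, `CHR`, `POS` used for
#'   the physical clumping window; SNPs on different chromosomes are never
#'   mutually exclusive.
#'
#' @return A list of class `"ld_matrix"` with elements `snp_ids`, `r2`,
#'   `pos`.
#' @export
ld_matrix <- function(r2, pos = NULL) {
  r2 <- as.matrix(r2)
  ids <- rownames(r2) %||% colnames(r2)
  if (is.null(ids)) stop("ld_matrix: r2 must carry SNP ids as dimnames")
  stopifnot(nrow(r2) == ncol(r2))
  if (max(abs(r2 - t(r2))) > 1e-8) stop("ld_matrix: r2 must be symmetric")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop("ld_matrix: entries outside [0,1]")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("ld_matrix: diagonal must be 1")
  dimnames(r2) <- list(ids, ids)
  structure(list(snp_ids = ids, r2 = r2, pos = pos), class = "ld_matrix")
}

#' Read a tab-delimited LD (r-squared) matrix
#'
#' Expects a square matrix with SNP ids as header row and first column.
#'
#' @param path File path.
#' @param pos Optional position data.frame, see [ld_matrix()].
#' @return An [ld_matrix()] object.
#' @export
read_ld_matrix <- function(path, pos = NULL) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  ld_matrix(as.matrix(d), pos = pos)
}

#' Write an LD matrix to a tab-delimited file
#'
#' @param ld An [ld_matrix()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ld_matrix <- function(ld, path) {
  m <- as.data.frame(ld$r2)
  utils::write.table(cbind(SNP = rownames(m), m), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select variants by association p-value with a fallback threshold
#'
#' Applies the genome-wide significance threshold (default 5e-8); if fewer
#' than `min_snps` variants pass, relaxes to the fallback threshold
#' (default 1e-5), the conventional remedy when a trait — e.g. a microbial
#' abundance with a small GWAS — yields too few genome-wide-significant hits.
#'
#' @param table A [sumstats] table.
#' @param primary_threshold,fallback_threshold P-value cutoffs in (0, 1),
#'   primary <= fallback; selection is strict (`p < threshold`).
#' @param min_snps Minimum instrument count before falling back (default 3,
#'   the minimum for MR-Egger).
#'
#' @return A list with `snps` (subset of `table` rows), `fallback_used`,
#'   `p_threshold_used`, and `no_instruments` (TRUE when both thresholds
#'   yield an empty selection).
#' @export
select_by_pvalue <- function(table, primary_threshold = 5e-8,
                             fallback_threshold = 1e-5, min_snps = 3) {
  stopifnot(primary_threshold > 0, primary_threshold < 1,
            fallback_threshold > 0, fallback_threshold < 1,
            primary_threshold <= fallback_threshold)
  d <- as.data.frame(table)
  hit <- d[d$P < primary_threshold, , drop = FALSE]
  fallback_used <- FALSE
  thr <- primary_threshold
  if (nrow(hit) < min_snps) {
    fb <- d[d$P < fallback_threshold, , drop = FALSE]
    if (nrow(fb) > nrow(hit)) {
      hit <- fb
      fallback_used <- TRUE
      thr <- fallback_threshold
    }
  }
  rownames(hit) <- NULL
  list(snps = hit, fallback_used = fallback_used, p_threshold_used = thr,
       no_instruments = nrow(hit) == 0)
}

#' Greedy LD clumping
#'
#' Orders candidates by ascending p-value (ties broken by chromosome,
#' position, then SNP id) and accepts each variant only if its r-squared
#' with every already-accepted variant within the physical window is below
#' `r2_max`.  Variants on different chromosomes never exclude each other;
#' when positions are unavailable all pairs are treated as within the
#' window (conservative).
#'
#' @param candidates A [sumstats] table (or data.frame with `SNP`, `P`, and
#'   optionally `CHR`, `POS`).
#' @param ld An [ld_matrix()]; candidates absent from it are dropped with
#'   reason `"no_ld_info"`.
#' @param r2_max LD threshold (default 0.01).
#' @param window_kb Physical window in kb (default 10000).
#'
#' @return A list with `kept` (rows in acceptance order) and `dropped`
#'   (named character vector snp -> reason, `"clumped"` or `"no_ld_info"`).
#' @export
ld_clump <- function(candidates, ld, r2_max = 0.01, window_kb = 10000) {
  d <- as.data.frame(candidates)
  if (nrow(d) == 0) return(list(kept = d, dropped = character(0)))
  dropped <- character(0)
  in_ld <- d$SNP %in% ld$snp_ids
  if (any(!in_ld)) {
    dropped[d$SNP[!in_ld]] <- "no_ld_info"
    d <- d[in_ld, , drop = FALSE]
  }
  if (nrow(d) == 0) return(list(kept = d, dropped = dropped))

  chr <- if ("CHR" %in% names(d)) as.character(d$CHR) else rep(NA_character_, nrow(d))
  pos <- if ("POS" %in% names(d)) as.numeric(d$POS) else rep(NA_real_, nrow(d))
  ord <- order(d$P, chr, pos, d$SNP)
  d <- d[ord, , drop = FALSE]
  chr <- chr[ord]; pos <- pos[ord]

  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    acc <- which(keep)
    ok <- TRUE
    for (k in acc) {
      same_chr <- is.na(chr[i]) || is.na(chr[k]) || chr[i] == chr[k]
      if (!same_chr) next
      within <- is.na(pos[i]) || is.na(pos[k]) ||
        abs(pos[i] - pos[k]) <= window_kb * 1000
      if (!within) next
      if (ld$r2[d$SNP[i], d$SNP[k]] >= r2_max) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  if (any(!keep)) dropped[d$SNP[!keep]] <- "clumped"
  kept <- d[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, dropped = dropped)
}

#' Instrument-strength F statistic
#'
#' The default form is `(beta/se)^2`, which needs no sample size.  When `n`
#' and the effect-allele frequency are available, the variance-explained
#' form `F = (n - 2) * R2 / (1 - R2)` with
#' `R2 = 2 * eaf * (1 - eaf) * beta^2` (standardized trait) is available as
#' `method = "r2"`.
#'
#' @param beta,se Effect and standard error (se > 0).
#' @param method `"ratio"` (default) or `"r2"`.
#' @param n,eaf Sample size and effect-allele frequency, required for
#'   `method = "r2"`.
#' @return The F statistic (vectorized).
#' @export
f_statistic <- function(beta, se, method = c("ratio", "r2"),
                        n = NULL, eaf = NULL) {
  method <- match.arg(method)
  if (method == "ratio") {
    if (any(se <= 0)) stop("f_statistic: se must be positive")
    return((beta / se)^2)
  }
  if (is.null(n) || is.null(eaf))
    stop("f_statistic: method 'r2' requires n and eaf")
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  (n - 2) * r2 / (1 - r2)
}

#' Filter weak instruments by F statistic
#'
#' @param candidates A [sumstats] table.
#' @param f_min Minimum F (default 10).
#' @param method F-statistic form, see [f_statistic()].
#' @return A list with `kept`, `dropped` (snp -> `"weak_instrument"`), and
#'   `f_statistics` (named vector over all candidates).
#' @export
filter_weak <- function(candidates, f_min = 10, method = "ratio") {
  stopifnot(f_min >= 0)
  d <- as.data.frame(candidates)
  if (nrow(d) == 0)
    return(list(kept = d, dropped = character(0),
                f_statistics = stats::setNames(numeric(0), character(0))))
  f <- f_statistic(d$BETA, d$SE, method = method, n = d$N, eaf = d$EAF)
  names(f) <- d$SNP
  keep <- f >= f_min
  dropped <- character(0)
  if (any(!keep)) dropped[d$SNP[!keep]] <- "weak_instrument"
  kept <- d[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, dropped = dropped, f_statistics = f)
}

#' Full instrument-selection ladder
#'
#' Significance selection (with fallback), greedy LD clumping, then
#' weak-instrument filtering, returning the kept set together with the
#' partition of everything dropped and the per-SNP F statistics.
#'
#' @param table A [sumstats] table for the trait whose instruments are
#'   sought.
#' @param ld An [ld_matrix()].
#' @param cfg A [screen_config()] supplying `p_threshold`, `fallback_p`,
#'   `min_snps`, `clump_r2`, `clump_kb`, `f_min`.
#'
#' @return A list with `kept`, `p_threshold_used`, `fallback_used`,
#'   `f_statistics`, `dropped` (named reasons over all non-kept candidates,
#'   including `"p_above_threshold"`), and `no_instruments`.
#' @export
select_instruments <- function(table, ld, cfg = screen_config()) {
  d <- as.data.frame(table)
  sel <- select_by_pvalue(d, cfg$p_threshold, cfg$fallback_p, cfg$min_snps)
  dropped <- character(0)
  not_sel <- setdiff(d$SNP, sel$snps$SNP)
  if (length(not_sel)) dropped[not_sel] <- "p_above_threshold"
  cl <- ld_clump(sel$snps, ld, cfg$clump_r2, cfg$clump_kb)
  dropped <- c(dropped, cl$dropped)
  fw <- filter_weak(cl$kept, cfg$f_min)
  dropped <- c(dropped, fw$dropped)
  list(kept = fw$kept,
       p_threshold_used = sel$p_threshold_used,
       fallback_used = sel$fallback_used,
       f_statistics = fw$f_statistics,
       dropped = dropped,
       no_instruments = nrow(fw$kept) == 0)
}
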