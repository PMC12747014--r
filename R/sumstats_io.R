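# Reading, validation and harmonization of GWAS summary statistics.
#
# A summary-statistics table is a data.frame with (at least) the canonical
# columns SNP, EA, OA, EAF, BETA, SE, P, N and optionally CHR, POS, carrying
# attributes trait_id / trait_label / sample_size.  All betas are per-allele
# effects in trait SD units.

.canonical_cols <- c(snp = "SNP", ea = "EA", oa = "OA", eaf = "EAF",
                     beta = "BETA", se = "SE", p = "P", n = "N",
                     chr = "CHR", pos = "POS")

.valid_allele <- function(a) {
  !is.na(a) & grepl("^[ACGT]+$", a)
}

#' Construct a summary-statistics table
#'
#' Builds a validated GWAS summary-statistics table from per-variant vectors.
#' Rows violating the record invariants (non-positive SE, p outside (0, 1],
#' allele frequency outside (0, 1), identical or malformed alleles, duplicate
#' SNP ids) are dropped with a message.
#'
#' @param snp Character vector of variant identifiers (unique).
#' @param ea,oa Effect and other allele, uppercase strings over A/C/G/T
#'   (multi-base strings denote indels).
#' @param beta Per-allele effect on the trait, in trait SD units.
#' @param se Standard error of `beta`, strictly positive.
#' @param p Association p-value in (0, 1].
#' @param eaf Optional effect-allele frequency in (0, 1); `NA` permitted.
#' @param n Optional per-variant sample size.
#' @param chr,pos Optional chromosome and 1-based base-pair position.
#' @param trait_id,trait_label Identifiers attached as attributes.
#' @param sample_size Optional study sample size attribute.
#'
#' @return A `data.frame` of class `"sumstats"` with canonical columns
#'   `SNP, EA, OA, EAF, BETA, SE, P, N` (plus `CHR`, `POS` when given).
#' @export
sumstats <- function(snp, ea, oa, beta, se, p, eaf = NA_real_, n = NA_real_,
                     chr = NA_character_, pos = NA_real_,
                     trait_id = "trait", trait_label = trait_id,
                     sample_size = NA_integer_) {
  d <- data.frame(SNP = as.character(snp),
                  EA = toupper(as.character(ea)),
                  OA = toupper(as.character(oa)),
                  EAF = as.numeric(eaf),
                  BETA = as.numeric(beta),
                  SE = as.numeric(se),
                  P = as.numeric(p),
                  N = as.numeric(n),
                  CHR = as.character(chr),
                  POS = as.numeric(pos),
                  stringsAsFactors = FALSE)
  ok <- !is.na(d$SNP) & nzchar(d$SNP) &
    .valid_allele(d$EA) & .valid_allele(d$OA) & d$EA != d$OA &
    !is.na(d$BETA) & is.finite(d$BETA) &
    !is.na(d$SE) & d$SE > 0 &
    !is.na(d$P) & d$P > 0 & d$P <= 1 &
    (is.na(d$EAF) | (d$EAF > 0 & d$EAF < 1))
  ok[ok] <- !duplicated(d$SNP[ok])
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(sprintf("sumstats: dropped %d invalid row(s) for trait '%s'",
                    n_drop, trait_id))
  d <- d[ok, , drop = FALSE]
  rownames(d) <- NULL
  if (nrow(d) == 0 && n_drop > 0)
    stop("sumstats: no valid rows remain for trait '", trait_id, "'")
  structure(d, class = c("sumstats", "data.frame"),
            trait_id = trait_id, trait_label = trait_label,
            sample_size = sample_size)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_label"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Column-mapping dialect for summary-statistics files
#'
#' Maps canonical fields to the column names used in a particular file.
#' Either `beta` + `se`, or `or` + `or_lci` + `or_uci` (odds ratio with 95%
#' confidence limits, converted as beta = log(OR),
#' se = (log(UCI) - log(LCI)) / (2 * 1.96)) must be supplied.
#'
#' @param snp,ea,oa,p Required column names.
#' @param beta,se Effect and standard-error columns (beta scale).
#' @param or,or_lci,or_uci Odds-ratio columns, alternative to `beta`/`se`.
#' @param eaf,n,chr,pos Optional column names (`NULL` to omit).
#'
#' @return A named list usable as the `dialect` argument of [read_sumstats()].
#' @export
sumstats_dialect <- function(snp = "SNP", ea = "EA", oa = "OA",
                             beta = "BETA", se = "SE", p = "P",
                             or = NULL, or_lci = NULL, or_uci = NULL,
                             eaf = "EAF", n = "N", chr = "CHR", pos = "POS") {
  list(snp = snp, ea = ea, oa = oa, beta = beta, se = se, p = p,
       or = or, or_lci = or_lci, or_uci = or_uci,
       eaf = eaf, n = n, chr = chr, pos = pos)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab-delimited summary-statistics table with a header row,
#' remapping columns through a dialect mapping.  Odds-ratio dialects are
#' converted to the log scale.  Invalid rows are dropped with a message.
#'
#' @param path Path to a tab-delimited file with header; `NA` is the missing
#'   sentinel.
#' @param dialect A [sumstats_dialect()] mapping; the default matches the
#'   canonical column names.
#' @param trait_id,trait_label Trait identifiers for the returned table.
#'
#' @return A [sumstats] table.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_id = basename(path), trait_label = trait_id) {
  if (!file.exists(path)) stop("read_sumstats: file not found: ", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA",
                         check.names = FALSE)
  need <- function(field) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(d))
      stop("read_sumstats: missing required column '", field,
           "' (looked for '", col %||% "<unmapped>", "')")
    d[[col]]
  }
  opt <- function(field, default = NA) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(d)) default else d[[col]]
  }
  if (nrow(d) == 0)
    stop("read_sumstats: empty table in ", path)
  has_or <- !is.null(dialect$or) && dialect$or %in% names(d)
  if (has_or) {
    or <- as.numeric(need("or"))
    lci <- as.numeric(need("or_lci"))
    uci <- as.numeric(need("or_uci"))
    beta <- log(or)
    se <- (log(uci) - log(lci)) / (2 * 1.96)
  } else {
    beta <- as.numeric(need("beta"))
    se <- as.numeric(need("se"))
  }
  sumstats(snp = need("snp"), ea = need("ea"), oa = need("oa"),
           beta = beta, se = se, p = as.numeric(need("p")),
           eaf = as.numeric(opt("eaf")), n = as.numeric(opt("n")),
           chr = as.character(opt("chr")), pos = as.numeric(opt("pos")),
           trait_id = trait_id, trait_label = trait_label)
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-delimited layout (`NA` sentinel for missing
#' values).  Numeric fields survive a read/write round trip to better than
#' 1e-12 relative error.
#'
#' @param table A [sumstats] table.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats") || is.data.frame(table))
  d <- as.data.frame(table)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.17g", x))
  })
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

.is_palindromic <- function(ea, oa) {
  nchar(ea) == 1 & nchar(oa) == 1 & .complement(ea) == oa
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome associations to the exposure's effect allele so that the
#' per-SNP exposure effect (gamma) and outcome effect (Gamma) refer to the
#' same allele.  The resolution ladder is: direct allele match; allele swap
#' (outcome beta sign flipped, EAF complemented); strand complement; strand
#' complement plus swap.  Palindromic variants (A/T or C/G) cannot be
#' resolved by strand, so they are excluded when the effect-allele frequency
#' is missing on either trait or lies within `palindrome_eaf_window` of 0.5
#' on either trait; otherwise frequencies on opposite sides of 0.5 imply a
#' flip.
#'
#' @param exposure_snps A [sumstats] table (or compatible data.frame) of
#'   selected exposure instruments.
#' @param outcome_table A [sumstats] table for the outcome trait.
#' @param palindrome_eaf_window Half-width of the ambiguity window around an
#'   EAF of 0.5 (default 0.08: exclude when either EAF is in [0.42, 0.58]).
#'
#' @return A `data.frame` of class `"harmonized"` with columns `snp_id`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf`, `flipped`,
#'   `palindromic`, `excluded_reason` (`NA` for usable instruments).  Rows
#'   with a non-`NA` `excluded_reason` (`"missing_in_outcome"`,
#'   `"ambiguous_palindrome"`, `"allele_mismatch"`) must not feed estimators;
#'   [usable_instruments()] subsets them away.
#' @export
harmonize <- function(exposure_snps, outcome_table,
                      palindrome_eaf_window = 0.08) {
  ex <- as.data.frame(exposure_snps)
  ou <- as.data.frame(outcome_table)
  idx <- match(ex$SNP, ou$SNP)

  n <- nrow(ex)
  res <- data.frame(
    snp_id = ex$SNP,
    beta_exp = ex$BETA, se_exp = ex$SE,
    beta_out = NA_real_, se_out = NA_real_,
    eaf = if ("EAF" %in% names(ex)) ex$EAF else NA_real_,
    flipped = FALSE,
    palindromic = .is_palindromic(ex$EA, ex$OA),
    excluded_reason = NA_character_,
    stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) {
      res$excluded_reason[i] <- "missing_in_outcome"
      next
    }
    ea <- ex$EA[i]; oa <- ex$OA[i]
    oea <- ou$EA[j]; ooa <- ou$OA[j]
    b <- ou$BETA[j]; s <- ou$SE[j]
    oeaf <- if ("EAF" %in% names(ou)) ou$EAF[j] else NA_real_
    flip <- NA  # NA = unresolvable

    if (oea == ea && ooa == oa) {
      flip <- FALSE
    } else if (oea == oa && ooa == ea) {
      flip <- TRUE
    } else if (!res$palindromic[i]) {
      # palindromic pairs are their own strand complement; only attempt
      # complement resolution for non-palindromic alleles
      cea <- .complement(oea); coa <- .complement(ooa)
      if (cea == ea && coa == oa) flip <- FALSE
      else if (cea == oa && coa == ea) flip <- TRUE
    }

    if (is.na(flip)) {
      res$excluded_reason[i] <- "allele_mismatch"
      next
    }

    if (res$palindromic[i]) {
      eeaf <- res$eaf[i]
      ambiguous <- is.na(eeaf) || is.na(oeaf) ||
        abs(eeaf - 0.5) <= palindrome_eaf_window ||
        abs(oeaf - 0.5) <= palindrome_eaf_window
      if (ambiguous) {
        res$excluded_reason[i] <- "ambiguous_palindrome"
        next
      }
      # allele labels carry no strand information for palindromes: infer the
      # orientation from the frequencies instead of the allele match above
      flip <- (eeaf - 0.5) * (oeaf - 0.5) < 0
    }

    res$beta_out[i] <- if (flip) -b else b
    res$se_out[i] <- s
    res$flipped[i] <- flip
  }
  class(res) <- c("harmonized", "data.frame")
  res
}

#' Keep only usable harmonized instruments
#'
#' @param h A [harmonize()] result.
#' @return The subset of rows with no exclusion reason.
#' @export
usable_instruments <- function(h) {
  out <- h[is.na(h$excluded_reason), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct harmonized instruments directly
#'
#' Convenience constructor for analyses that already hold aligned per-SNP
#' exposure/outcome effects (simulation studies, worked examples).
#'
#' @param snp_id Variant identifiers.
#' @param beta_exp,se_exp SNP-exposure effect and SE (SE > 0).
#' @param beta_out,se_out SNP-outcome effect and SE (SE > 0), aligned to the
#'   exposure effect allele.
#' @param eaf Optional effect-allele frequency.
#' @return A `"harmonized"` data.frame as returned by [harmonize()].
#' @export
harmonized_instruments <- function(snp_id, beta_exp, se_exp, beta_out, se_out,
                                   eaf = NA_real_) {
  stopifnot(all(se_exp > 0), all(se_out > 0))
  res <- data.frame(snp_id = as.character(snp_id),
                    beta_exp = beta_exp, se_exp = se_exp,
                    beta_out = beta_out, se_out = se_out,
                    eaf = eaf, flipped = FALSE, palindromic = FALSE,
                    excluded_reason = NA_character_,
                    stringsAsFactors = FALSE)
  class(res) <- c("harmonized", "data.frame")
  res
}
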