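# Seeded generator of GWAS summary statistics for an
# exposure -> mediator -> outcome causal system with known truth.
#
# Summary statistics are simulated directly (no individual-level
# genotypes): two-sample MR consumes only summary data, and direct
# simulation keeps desk-scale runtime.  All traits are in SD units; the
# standard error of a per-allele effect in a GWAS of n individuals is
# approximated by se = 1/sqrt(2 * n * eaf * (1 - eaf)).

#' Scenario configuration for the summary-statistics generator
#'
#' Parameterizes the causal system.  A set of `n_causal_exp` SNPs carries
#' exposure effects `gamma_j ~ N(0, gamma_sd^2)`; a disjoint set of
#' `n_causal_med` SNPs carries mediator-specific effects
#' `delta_j ~ N(0, gamma_sd^2)` (the mediator's own instruments, without
#' which its adjusted effect on the outcome is not identifiable by
#' multivariable MR).  True effects:
#' mediator `= beta1 * gamma + delta`; outcome
#' `= direct * gamma + beta2 * (beta1 * gamma + delta) + pleiotropy`, so the
#' total exposure->outcome effect is `direct + beta1 * beta2` and the
#' mediated proportion `beta1 * beta2 / total`.  With
#' `reverse_mediation = TRUE` the mediator instead causes the exposure:
#' exposure `= gamma + beta1 * delta`, mediator `= delta`.
#'
#' @param n_snps Total SNPs simulated (default 200).
#' @param n_causal_exp SNPs with direct exposure effects (default 50).
#' @param n_causal_med SNPs with mediator-specific effects (default 50;
#'   requires `n_causal_exp + n_causal_med <= n_snps`).
#' @param eaf_range Effect-allele-frequency range (default c(0.1, 0.9)).
#' @param gamma_sd SD of per-SNP causal effects in trait SD units
#'   (default 0.05).
#' @param beta1 True exposure->mediator effect (default 0.3).
#' @param beta2 True mediator->outcome effect (default 0.4).
#' @param direct True direct exposure->outcome effect (default 0.2).
#' @param pleiotropy_sd SD of balanced per-SNP direct-to-outcome
#'   (pleiotropic) effects on exposure SNPs; 0 = none.
#' @param directional_pleiotropy Constant offset added to the outcome
#'   effects of exposure SNPs (default 0).
#' @param reverse_mediation If TRUE, the mediator causes the exposure.
#' @param n_exp,n_med,n_out GWAS sample sizes (default 50000 each).
#' @param ld_block_size SNPs per exchangeable LD block (default 10).
#' @param ld_r2_within r-squared between distinct SNPs of a block
#'   (default 0.3, above the conventional 0.01 clumping threshold so that
#'   clumping is exercised).
#' @param seed RNG seed (required; the triplet is a pure function of the
#'   config).
#' @return A validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_snps = 200L, n_causal_exp = 50L,
                            n_causal_med = 50L,
                            eaf_range = c(0.1, 0.9), gamma_sd = 0.05,
                            beta1 = 0.3, beta2 = 0.4, direct = 0.2,
                            pleiotropy_sd = 0, directional_pleiotropy = 0,
                            reverse_mediation = FALSE,
                            n_exp = 50000L, n_med = 50000L, n_out = 50000L,
                            ld_block_size = 10L, ld_r2_within = 0.3,
                            seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps),
              n_causal_exp = as.integer(n_causal_exp),
              n_causal_med = as.integer(n_causal_med),
              eaf_range = as.numeric(eaf_range), gamma_sd = gamma_sd,
              beta1 = beta1, beta2 = beta2, direct = direct,
              pleiotropy_sd = pleiotropy_sd,
              directional_pleiotropy = directional_pleiotropy,
              reverse_mediation = isTRUE(reverse_mediation),
              n_exp = as.integer(n_exp), n_med = as.integer(n_med),
              n_out = as.integer(n_out),
              ld_block_size = as.integer(ld_block_size),
              ld_r2_within = ld_r2_within, seed = as.integer(seed))
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_snps >= 1, "n_snps must be >= 1")
  chk(cfg$n_causal_exp >= 0 && cfg$n_causal_exp <= cfg$n_snps,
      "n_causal_exp must be in [0, n_snps]")
  chk(cfg$n_causal_med >= 0 &&
        cfg$n_causal_exp + cfg$n_causal_med <= cfg$n_snps,
      "n_causal_exp + n_causal_med must be <= n_snps")
  chk(length(cfg$eaf_range) == 2 && all(cfg$eaf_range > 0) &&
        all(cfg$eaf_range < 1) && cfg$eaf_range[1] <= cfg$eaf_range[2],
      "eaf_range must be inside (0,1)")
  chk(cfg$gamma_sd >= 0, "gamma_sd must be >= 0")
  chk(cfg$pleiotropy_sd >= 0, "pleiotropy_sd must be >= 0")
  chk(all(c(cfg$n_exp, cfg$n_med, cfg$n_out) >= 2),
      "sample sizes must be >= 2")
  chk(cfg$ld_block_size >= 1, "ld_block_size must be >= 1")
  chk(cfg$ld_r2_within >= 0 && cfg$ld_r2_within < 1,
      "ld_r2_within must be in [0,1)")
  if (length(problems))
    stop("scenario_config: invalid configuration:\n  ",
         paste(problems, collapse = "\n  "))
  structure(cfg, class = "scenario_config")
}

.obs_table <- function(snp, ea, oa, eaf, chr, pos, true_beta, n,
                       trait_id, trait_label) {
  se <- 1 / sqrt(2 * n * eaf * (1 - eaf))
  beta <- true_beta + stats::rnorm(length(se), 0, se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  p[p == 0] <- .Machine$double.xmin   # keep p in (0, 1]
  sumstats(snp = snp, ea = ea, oa = oa, beta = beta, se = se, p = p,
           eaf = eaf, n = n, chr = chr, pos = pos,
           trait_id = trait_id, trait_label = trait_label, sample_size = n)
}

.scenario_map <- function(cfg) {
  n <- cfg$n_snps
  snp <- sprintf("rs%05d", seq_len(n))
  block <- (seq_len(n) - 1) %/% cfg$ld_block_size
  chr <- as.character(block %% 22 + 1)
  # blocks 20 Mb apart (outside any conventional clumping window);
  # SNPs 1 kb apart within a block
  pos <- (block %/% 22 + 1) * 2e7 + ((seq_len(n) - 1) %% cfg$ld_block_size) * 1e3
  # non-palindromic allele pairs so harmonization never has to drop
  # simulated variants; palindrome handling is exercised by unit fixtures
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  pick <- sample.int(4, n, replace = TRUE)
  list(snp = snp, block = block, chr = chr, pos = pos,
       ea = pairs[pick, 1], oa = pairs[pick, 2])
}

.block_ld <- function(map, cfg) {
  n <- length(map$snp)
  r2 <- diag(n)
  for (b in unique(map$block)) {
    i <- which(map$block == b)
    r2[i, i] <- cfg$ld_r2_within
    diag(r2)[i] <- 1
  }
  dimnames(r2) <- list(map$snp, map$snp)
  ld_matrix(r2, pos = data.frame(SNP = map$snp, CHR = map$chr,
                                 POS = map$pos, stringsAsFactors = FALSE))
}

#' Simulate an exposure/mediator/outcome summary-statistics triplet
#'
#' Draws the causal system of a [scenario_config()] and returns observed
#' (noisy) GWAS summary tables for the three traits, a block-diagonal LD
#' matrix, and the ground truth.  Deterministic given the config (the seed
#' is part of the config).
#'
#' @param cfg A [scenario_config()].
#' @return A list with `exposure`, `mediator`, `outcome` ([sumstats]
#'   tables), `ld` ([ld_matrix()]), and `truth` (per-SNP true effects plus
#'   `beta1`, `beta2`, `direct`, `total = direct + beta1*beta2`,
#'   `proportion = beta1*beta2/total`).
#' @export
simulate_triplet <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$seed, .simulate_triplet_impl(cfg))
}

.simulate_triplet_impl <- function(cfg) {
  map <- .scenario_map(cfg)
  n <- cfg$n_snps
  eaf <- stats::runif(n, cfg$eaf_range[1], cfg$eaf_range[2])

  # scatter causal SNPs over the genome so they are not confined to a few
  # LD blocks (which would collapse under clumping)
  causal <- sample.int(n, cfg$n_causal_exp + cfg$n_causal_med)
  exp_set <- causal[seq_len(cfg$n_causal_exp)]
  med_set <- causal[cfg$n_causal_exp + seq_len(cfg$n_causal_med)]
  gamma <- numeric(n)
  gamma[exp_set] <- stats::rnorm(cfg$n_causal_exp, 0, cfg$gamma_sd)
  delta <- numeric(n)
  if (cfg$n_causal_med > 0)
    delta[med_set] <- stats::rnorm(cfg$n_causal_med, 0, cfg$gamma_sd)

  if (!cfg$reverse_mediation) {
    true_exp <- gamma
    true_med <- cfg$beta1 * gamma + delta
  } else {
    true_med <- delta
    true_exp <- gamma + cfg$beta1 * delta
  }
  pleio <- numeric(n)
  if (cfg$pleiotropy_sd > 0)
    pleio[exp_set] <- stats::rnorm(cfg$n_causal_exp, 0, cfg$pleiotropy_sd)
  pleio[exp_set] <- pleio[exp_set] + cfg$directional_pleiotropy
  true_out <- cfg$direct * true_exp + cfg$beta2 * true_med + pleio

  mk <- function(true_beta, nn, id, lab)
    .obs_table(map$snp, map$ea, map$oa, eaf, map$chr, map$pos,
               true_beta, nn, id, lab)
  list(exposure = mk(true_exp, cfg$n_exp, "exposure", "simulated exposure"),
       mediator = mk(true_med, cfg$n_med, "mediator", "simulated mediator"),
       outcome = mk(true_out, cfg$n_out, "outcome", "simulated outcome"),
       ld = .block_ld(map, cfg),
       truth = list(gamma = stats::setNames(gamma, map$snp),
                    delta = stats::setNames(delta, map$snp),
                    pleiotropy = stats::setNames(pleio, map$snp),
                    beta1 = cfg$beta1, beta2 = cfg$beta2,
                    direct = cfg$direct,
                    total = cfg$direct + cfg$beta1 * cfg$beta2,
                    proportion = cfg$beta1 * cfg$beta2 /
                      (cfg$direct + cfg$beta1 * cfg$beta2),
                    reverse_mediation = cfg$reverse_mediation))
}

#' Simulate a panel of candidate mediators
#'
#' One causal-path mediator (per the config) plus `n_null_mediators` traits
#' with no causal connection to exposure or outcome (pure noise around zero
#' effects), all sharing the SNP set, LD and exposure/outcome tables: a
#' desk-scale stand-in for screening a large panel of microbial traits.
#'
#' @param cfg A [scenario_config()].
#' @param n_null_mediators Number of null mediators (default 4).
#' @return As [simulate_triplet()], but with `mediators`, a named list of
#'   tables (`causal_mediator`, `null_1`, ...); `truth$causal_mediator`
#'   names the causal one.
#' @export
simulate_mediator_panel <- function(cfg, n_null_mediators = 4L) {
  stopifnot(inherits(cfg, "scenario_config"), n_null_mediators >= 0)
  withr::with_seed(cfg$seed, {
    tri <- .simulate_triplet_impl(cfg)
    map_snp <- tri$exposure$SNP
    meds <- list(causal_mediator = tri$mediator)
    for (k in seq_len(n_null_mediators)) {
      id <- sprintf("null_%d", k)
      meds[[id]] <- .obs_table(tri$mediator$SNP, tri$mediator$EA,
                               tri$mediator$OA, tri$mediator$EAF,
                               tri$mediator$CHR, tri$mediator$POS,
                               numeric(length(map_snp)), cfg$n_med,
                               id, sprintf("null mediator %d", k))
    }
    tri$mediator <- NULL
    tri$mediators <- meds
    tri$truth$causal_mediator <- "causal_mediator"
    tri
  })
}
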