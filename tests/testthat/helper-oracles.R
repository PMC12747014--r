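# Fixture builders and independently coded oracles.  The oracles are
# deliberately naive re-derivations (enumeration, direct CDF interpolation,
# explicit kernel sums, Monte-Carlo propagation) kept separate from the
# package's implementation paths.

make_sumstats <- function(snp = paste0("rs", seq_along(beta)),
                          beta, se, p = 2 * pnorm(-abs(beta / se)),
                          ea = "A", oa = "G", eaf = 0.3, n = 50000,
                          chr = "1", pos = seq_along(beta) * 1e6,
                          trait_id = "trait") {
  sumstats(snp = snp, ea = ea, oa = oa, beta = beta, se = se, p = p,
           eaf = eaf, n = n, chr = chr, pos = pos, trait_id = trait_id)
}

make_h <- function(beta_exp, se_exp, beta_out, se_out,
                   snp = paste0("rs", seq_along(beta_exp))) {
  harmonized_instruments(snp, beta_exp, se_exp, beta_out, se_out)
}

# dense LD matrix over ids with given off-diagonal r2 entries
make_ld <- function(ids, r2_pairs = NULL, pos = NULL) {
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  if (!is.null(r2_pairs)) {
    for (k in seq_len(nrow(r2_pairs))) {
      i <- r2_pairs$a[k]; j <- r2_pairs$b[k]
      m[i, j] <- m[j, i] <- r2_pairs$r2[k]
    }
  }
  ld_matrix(m, pos = pos)
}

# Brute-force greedy clumping oracle: walks the p-sorted candidate list and
# checks every accepted pair explicitly.
oracle_clump <- function(d, r2, r2_max, window_kb) {
  ord <- order(d$P, d$CHR, d$POS, d$SNP)
  d <- d[ord, , drop = FALSE]
  accepted <- character(0)
  for (i in seq_len(nrow(d))) {
    ok <- TRUE
    for (a in accepted) {
      k <- which(d$SNP == a)
      if (!is.na(d$CHR[i]) && !is.na(d$CHR[k]) && d$CHR[i] != d$CHR[k]) next
      if (!is.na(d$POS[i]) && !is.na(d$POS[k]) &&
          abs(d$POS[i] - d$POS[k]) > window_kb * 1000) next
      if (r2[d$SNP[i], a] >= r2_max) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, d$SNP[i])
  }
  accepted
}

# Weighted-median oracle: explicit weighted empirical CDF interpolation at
# one half, standardized cumulative weights s_j = (cum_j - w_j/2)/total.
oracle_weighted_median <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]; w <- weights[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  n <- length(r)
  if (0.5 >= s[n]) return(r[n])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

# KDE-argmax oracle: explicit Gaussian kernel sum maximized over the same
# 512-point grid convention (ratios +/- 3 bandwidths).
oracle_mode <- function(ratios, weights, phi) {
  n <- length(ratios)
  bw <- phi * 0.9 * min(sd(ratios), IQR(ratios) / 1.349) * n^(-1 / 5)
  grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw, length.out = 512)
  w <- weights / sum(weights)
  dens <- sapply(grid, function(g) sum(w * dnorm(g, mean = ratios, sd = bw)))
  grid[which.max(dens)]
}

# Monte-Carlo propagation oracle for the mediated-proportion SE.
oracle_proportion_se_mc <- function(beta1, se1, beta2, se2, beta0, se0,
                                    n_draw = 1e6, seed = 123) {
  withr::with_seed(seed, {
    b1 <- rnorm(n_draw, beta1, se1)
    b2 <- rnorm(n_draw, beta2, se2)
    b0 <- rnorm(n_draw, beta0, se0)
    sd(b1 * b2 / b0)
  })
}
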