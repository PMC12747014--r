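---
title: "Two-step Mendelian randomization mediation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step Mendelian randomization mediation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The causal model

Two-sample Mendelian randomization treats SNPs as instrumental variables
for a heritable exposure. For SNP $j$, a GWAS of the exposure supplies
$\hat\gamma_j$ (SE $\sigma_{xj}$) and an independent GWAS of the outcome
supplies $\hat\Gamma_j$ (SE $\sigma_{yj}$). If the instrument assumptions
hold — relevance (the SNP affects the exposure), independence (no
confounding of the SNP–outcome relation), and exclusion (the SNP affects
the outcome only through the exposure) — then every valid instrument's
Wald ratio $\hat\Gamma_j/\hat\gamma_j$ estimates the same causal effect,
and pooling over instruments buys precision and robustness diagnostics.

The two-step mediation design asks, in addition, how much of a total
causal effect $\beta_0$ (exposure $\to$ outcome) passes through a mediator
trait: step 1 estimates $\beta_1$ (exposure $\to$ mediator) by
univariable MR; step 2 estimates $\beta_2$ (mediator $\to$ outcome,
*adjusted for the exposure*) by multivariable MR. The indirect effect is
the product $\beta_1\beta_2$, the direct effect is the remainder
$\beta_0 - \beta_1\beta_2$, and the proportion mediated is
$\beta_1\beta_2/\beta_0$.

# Instrument selection

Three filters, applied in order by `select_instruments()`:

1. **Significance.** Genome-wide significance $p < 5\times10^{-8}$
   (`p_threshold`). Traits measured in small GWAS — microbial abundances
   especially — often yield fewer than the three SNPs MR-Egger needs, so
   when fewer than `min_snps = 3` pass, the threshold relaxes to
   `fallback_p` $= 1\times10^{-5}$ and the result is flagged
   `fallback_used`. Selection is strict (`p < t`, not `\le`).
2. **LD clumping.** Greedy: candidates are sorted by ascending $p$ (ties
   broken by chromosome, position, then SNP id, purely for determinism —
   the data never provide exactly tied p-values in practice) and a SNP is
   accepted only if its $r^2$ with every already-accepted SNP within
   `clump_kb` $= 10{,}000$ kb is below `clump_r2` $= 0.01$. SNPs on
   different chromosomes never exclude one another regardless of what the
   supplied $r^2$ matrix contains; when positions are unavailable all
   pairs are treated as within the window, which only ever prunes more.
3. **Instrument strength.** $F = (\hat\gamma/\sigma_x)^2 \ge 10$. The
   squared-z form is the default because per-SNP sample sizes are
   frequently absent from public summary statistics; when $n$ and the
   effect-allele frequency are available the variance-explained form
   $F = (n-2)R^2/(1-R^2)$ with $R^2 = 2f(1-f)\hat\gamma^2$ is offered as
   a documented variant (`f_statistic(..., method = "r2")`). Which form a
   given published analysis used is rarely stated; results with strong
   instruments are insensitive to the choice.

Every discarded candidate carries a reason (`p_above_threshold`,
`clumped`, `no_ld_info`, `weak_instrument`), and kept plus dropped always
partition the candidates — the run manifest asserts these counts.

# Harmonization

`harmonize()` aligns outcome effects to the exposure's effect allele
through the standard ladder: direct match, allele swap (sign flip, EAF
complement), strand complement, complement plus swap. Unresolvable pairs
are excluded as `allele_mismatch`, never silently kept. Palindromic
variants (A/T, C/G) carry no strand information in their allele labels;
they are oriented by comparing effect-allele frequencies, and excluded as
`ambiguous_palindrome` whenever the frequency is missing on either trait
or lies within `palindrome_eaf_window = 0.08` of 0.5 on either side
(i.e. EAF in [0.42, 0.58]). The window matches prevailing two-sample-MR
practice; published analyses rarely state their policy, so this default
is an explicit package decision rather than an inference about any one
study.

# Estimators

All estimators report a normal-approximation 95% interval
$\hat\beta \pm 1.96\,\mathrm{SE}$ (the constant 1.96 is used literally
throughout, including the odds-ratio-to-log conversion
$\mathrm{SE} = (\ln \mathrm{UCI} - \ln \mathrm{LCI})/(2\cdot 1.96)$).

**IVW.** Weighted least squares of $\hat\Gamma$ on $\hat\gamma$ through
the origin with weights $1/\sigma_y^2$; closed form
$\hat\beta = \sum w_j\hat\gamma_j\hat\Gamma_j / \sum w_j\hat\gamma_j^2$.
The fixed-effect SE is $1/\sqrt{\sum \hat\gamma_j^2/\sigma_{yj}^2}$; the
default multiplicative random-effects flavor inflates it by
$\max(1, \sqrt{Q/(n-1)})$, so heterogeneity widens intervals but can
never shrink them below the fixed-effect width. A single instrument falls
back to the fixed form (the Wald ratio) with a logged note.

**MR-Egger.** The same regression with an intercept, after orienting all
instruments to positive exposure effects. The slope is the causal
estimate under the InSIDE assumption; the intercept estimates directional
pleiotropy. SEs are scaled by $\max(1, \hat\sigma)$ (residual SD floored
at one, the multiplicative random-effects convention) and p-values use
Student's t with $n-2$ df. All other estimators use two-sided normal
p-values.

**Weighted median.** Per-SNP ratios ordered, weighted by the inverse
first-order ratio variance $\hat\gamma_j^2/\sigma_{yj}^2$; the estimate
interpolates the weighted empirical CDF at one half through the
standardized cumulative weights $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum w$.
Consistent when valid instruments carry a weight majority.

**Mode estimators.** The argmax of a Gaussian kernel density over the
ratios, bandwidth $\varphi \cdot 0.9\min(\mathrm{sd},
\mathrm{IQR}/1.349)\,n^{-1/5}$ with $\varphi = 1$ by default, evaluated
on a fixed 512-point grid spanning the ratios $\pm 3$ bandwidths. The
simple variant weights instruments equally, the weighted variant by
inverse ratio variance. If every ratio coincides the bandwidth is zero
and the common ratio is returned directly.

Median and mode SEs come from a parametric bootstrap: each
$(\hat\gamma_j, \hat\Gamma_j)$ is resampled from normal distributions
centred on the observed values with the reported SEs, the estimator is
recomputed, and the SD over `n_boot = 1000` replicates (seeded; results
are bit-for-bit reproducible under a fixed seed) is the SE.

**Multivariable IVW.** For step 2, the outcome effects are regressed
without intercept on $K$ columns of exposure effects (here: exposure and
mediator) with weights $1/\sigma_y^2$, over the clumped union of both
traits' instruments. The mediator's coefficient is $\beta_2$; the
exposure's coefficient is the direct effect. Designs with
$n_{\mathrm{snp}} \le K$ or a weighted condition number above $10^8$ are
rejected (rank / collinearity errors) rather than silently regularized.

# Sensitivity diagnostics

Cochran $Q = \sum w_j(r_j - \hat\beta)^2$ over the Wald ratios $r_j$ with
first-order weights, $\chi^2_{n-1}$ p-value and
$I^2 = \max(0, (Q - \mathrm{df})/Q)$; the pooled beta defaults to the
headline IVW estimate (whether a published Q used the fixed or
random-effects pooled value is typically unstated — the two coincide in
the point estimate, so the choice is moot here). The Egger intercept test
and a leave-one-out IVW table complete the report.

# Mediation arithmetic

`two_step_mediation()` enforces the decomposition identities exactly:
indirect $= \beta_1\beta_2$, direct $+$ indirect $= \beta_0$,
proportion $\times\ \beta_0 =$ indirect. The indirect-effect SE is the
product delta method,
$\sqrt{\beta_1^2 s_2^2 + \beta_2^2 s_1^2}$. For the proportion the
package uses the **full three-term delta method**

$$\mathrm{SE}\!\left(\frac{\beta_1\beta_2}{\beta_0}\right) =
\left|\frac{\beta_1\beta_2}{\beta_0}\right|
\sqrt{\left(\frac{s_1}{\beta_1}\right)^2 +
      \left(\frac{s_2}{\beta_2}\right)^2 +
      \left(\frac{s_0}{\beta_0}\right)^2},$$

including the total-effect variance term: on the bundled worked examples
the two-term version gives visibly narrower intervals than the published
ones, while the three-term version reproduces them to within rounding of
the printed inputs. The three estimates are treated as independent
(separate GWAS samples); with overlapping samples the CI is
anti-conservative. The first-order delta approximation tracks a
Monte-Carlo propagation of the input normals to within a few percent when
each $|\beta/\mathrm{SE}|$ is above roughly 3, and degrades below that —
the test suite verifies agreement within 5% in that regime. Mediation
rows whose indirect and total effects disagree in sign are flagged
`sign_inconsistent` and reported with a warning, never suppressed.

# The screening pipeline

`screen_mediators()` composes the study end to end: per-outcome total
effects; step-1 MR for every mediator over the exposure's instruments; a
**reverse-MR guard** (mediator $\to$ exposure MR over the mediator's own
instruments — a significant reverse IVW at level $\alpha$ disqualifies
the mediator as likely reverse causation); step-2 multivariable MR; and
qualification requiring significant step-1 and step-2 estimates plus a
clean reverse test. Mediation rows are produced only for outcomes whose
total effect is itself significant: an outcome with no demonstrated total
effect has nothing to decompose.

Two properties of this design are worth stating plainly. First, the
reverse guard is a nominal-level test on instruments that are null for
the reverse direction when the mediator is genuinely downstream, so it
disqualifies a *true* mediator in about $\alpha = 5\%$ of datasets — the
price of protection against reverse causation. Second, multiple testing
across a large panel is configurable: `mtc = "none"` mirrors the common
practice of screening at nominal significance, while `mtc = "bh_fdr"`
(recommended for panels of hundreds of traits) applies
Benjamini–Hochberg within each step. Per-mediator failures (no
instruments, harmonization losses) are isolated and recorded; one bad
trait never aborts a screen.

# The synthetic-data generator

`simulate_triplet()` draws summary statistics directly — no
individual-level genotypes — because two-sample MR consumes nothing else
and direct simulation keeps runs desk-scale. The causal system:

- `n_causal_exp` SNPs (default 50 of `n_snps = 200`) carry exposure
  effects $\gamma_j \sim N(0, \texttt{gamma\_sd}^2)$,
  `gamma_sd` $= 0.05$ SD units;
- a disjoint set of `n_causal_med` SNPs (default 50) carries
  mediator-specific effects $\delta_j$ with the same SD. These are the
  mediator's own instruments; without them the mediator's true effects
  would be exactly proportional to the exposure's
  ($\beta_1\gamma_j$) and the step-2 multivariable regression would be
  unidentifiable — a mediator with no independent genetic basis cannot
  be studied by this design at all, so the generator gives it one;
- true effects: mediator $= \beta_1\gamma + \delta$, outcome
  $= \mathrm{direct}\cdot\gamma + \beta_2(\beta_1\gamma + \delta) +$
  pleiotropy (balanced `pleiotropy_sd` noise and/or a constant
  `directional_pleiotropy` offset on exposure SNPs). Defaults
  $\beta_1 = 0.3$, $\beta_2 = 0.4$, direct $= 0.2$, hence total $= 0.32$
  and true proportion mediated $= 0.375$;
- `reverse_mediation = TRUE` swaps the roles: the mediator has its own
  effects and causes the exposure with coefficient $\beta_1$, for
  testing the reverse-MR guard;
- observed effects add noise with
  $\mathrm{SE} = 1/\sqrt{2 n f(1-f)}$ (standardized-trait
  approximation), $f \sim U(0.1, 0.9)$, GWAS sizes
  `n_exp = n_med = n_out` $= 50{,}000$ — large enough that instrument
  sets are well powered yet small enough that estimation error is
  visible; p-values are two-sided normal, floored at the smallest
  positive double so they stay in $(0,1]$;
- LD is block-exchangeable: blocks of `ld_block_size = 10` SNPs with
  within-block $r^2 = 0.3$ (above the 0.01 clumping threshold, so
  clumping is genuinely exercised), blocks placed 20 Mb apart across 22
  chromosomes so between-block pairs fall outside any conventional
  window. Causal SNPs are scattered uniformly over the genome rather
  than packed into adjacent blocks, so clumping does not collapse the
  instrument set;
- allele pairs are drawn from the non-palindromic set (A/G, A/C, T/G,
  T/C); palindrome handling is exercised by dedicated unit fixtures
  rather than by randomly losing simulated instruments.

What the generator does **not** emulate: realistic LD structure, allele
frequency spectra, winner's curse in instrument discovery, sample overlap
between GWAS, population stratification, or the heritability profile of
real microbial traits (microbiome GWAS in particular are far smaller and
noisier than the defaults here). Passing recovery tests therefore
demonstrates the pipeline's statistical correctness under its own
assumptions, not robustness to everything real data can do.

# Validation problem sizes

The test suite validates calibration and recovery at sizes chosen to give
tight Monte-Carlo error while keeping the default run in the minutes
range: 500 null replicates with 50 independent instruments for the size
of the IVW test and the Egger intercept test (expected rejection within
$5\% \pm 2\%$; the $\max(1,\cdot)$ SE floors make both very slightly
conservative, which the band accommodates); 200 replicates of the default
scenario for mediated-proportion recovery (mean within 0.03 of 0.375,
delta-CI coverage in [0.90, 0.98]); and 60 replicates of a five-mediator
panel (one causal, four null) for the screen, asserting the causal
mediator qualifies in at least 90% of replicates (the expected rate is
$\approx 95\%$ given the reverse guard's nominal type-I error) and null
mediators qualify at no more than the nominal rate.

# Known limitations

- Normal-approximation CIs everywhere; no bootstrap or profile intervals
  for IVW/Egger, and no simulation-based mediation CIs.
- The proportion-mediated delta CI assumes independent, well-separated
  step estimates; it is unreliable when $\beta_0$ is near zero (the
  pipeline therefore refuses to decompose non-significant total effects).
- No MR-PRESSO outlier removal, Steiger directionality filtering, or
  contamination-mixture models; the sensitivity toolkit is Q, Egger
  intercept and leave-one-out.
- LD is always supplied, never computed from a reference panel; there is
  no proxy-SNP lookup, liftover, or GWAS-VCF ingestion.
- Real microbiome applications should treat single-study mediation
  proportions as indicative: published intervals in this literature are
  wide, and the generator's clean architecture understates real-world
  uncertainty.
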