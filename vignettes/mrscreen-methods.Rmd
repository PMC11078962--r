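---
title: "Methods: two-sample MR screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

# The problem

Serum metabolite levels are heritable, and large metabolomics GWAS provide
per-SNP association estimates for hundreds of metabolites.  Given a disease
GWAS (here the motivating application is iridocyclitis, the most common
form of uveitis, with thousands of cases and hundreds of thousands of
controls), two-sample Mendelian randomization (MR) asks whether genetically
predicted metabolite levels causally affect disease risk, using SNPs as
instrumental variables.  `mrscreen` implements the complete screening
pipeline — instrument selection, harmonization, estimation, sensitivity
analysis, LD score regression (LDSC), reverse MR, and a three-criterion
decision rule — on GWAS summary statistics alone, plus a synthetic-data
generator with known ground truth so that every stage can be exercised and
calibrated without external downloads.

# Model and estimators

For metabolite $X$ and disease $Y$, each instrument $j$ contributes an
estimated SNP-exposure effect $\hat\beta_{Xj}$ (s.e. $\sigma_{Xj}$) and a
SNP-outcome log-odds effect $\hat\beta_{Yj}$ (s.e. $\sigma_{Yj}$).  Under
the instrumental-variable assumptions the Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal slope
$\theta$, with first-order standard error
$\sigma_{Yj}/|\hat\beta_{Xj}|$ (a second-order form that includes the
exposure-side variance is available via `wald_ratios(..., se_order = 2)`;
the first-order convention is the default because it matches dominant
practice, and the choice is surfaced so replication mismatches are
diagnosable).

**IVW (primary).** The inverse-variance-weighted estimate is the
zero-intercept weighted regression of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with weights $w_j = 1/\sigma_{Yj}^2$,
$$\hat\theta_{\mathrm{IVW}} =
  \frac{\sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj}}
       {\sum_j w_j \hat\beta_{Xj}^2},$$
equivalent to the inverse-variance meta-analysis of the Wald ratios.  The
*multiplicative random-effects* variant inflates the fixed-effect variance
by the overdispersion implied by Cochran's $Q$:
$\phi = \max\{1, Q/(J-1)\}$ and
$\mathrm{se} = \sqrt{\phi / \sum_j w_j \hat\beta_{Xj}^2}$, with a normal
p-value.  The truncation at 1 (never deflating below the fixed-effect
variance) makes the test mildly conservative under the exact null — the
analytic type-I error at $\alpha = 0.05$ is about 0.043 at $J = 50$ —
which is the standard construction and is measured, not hidden, by the
calibration tests.

**MR-Egger.** Weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ *with* a free intercept, after jointly sign-flipping each
SNP pair so all $\hat\beta_{Xj} \ge 0$ (the exposure-increasing
orientation).  The slope is the pleiotropy-adjusted causal estimate and
keeps the truncated overdispersion rule with $J - 2$ degrees of freedom.
The intercept estimates the average directional pleiotropy; its standard
error deliberately uses the *untruncated* residual variance
$\mathrm{RSS}/(J-2)$, so the intercept test is exactly
$t_{J-2}$-calibrated under the no-pleiotropy null.  (With the truncated
variance the intercept test's type-I error would be 0.028–0.038 over
$J \in [20, 50]$ — a silently conservative pleiotropy detector is the
wrong default for a gatekeeping test.)

**Weighted median.** Order the Wald ratios; with normalized weights
$w_j' = (\hat\beta_{Xj}^2/\sigma_{Yj}^2) / \sum_k(\cdot)$ the estimate
linearly interpolates the ratios where the cumulative weight
$s_j = \sum_{k \le j} w_k' - w_j'/2$ crosses one half.  It is consistent
when instruments carrying at least 50% of the weight are valid.  The
standard error comes from a parametric bootstrap (default 1000 replicates)
that resamples $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ from normal
distributions with their reported standard errors; the seed is a mandatory
argument so results are reproducible.

**Simple and weighted mode.** The mode of a normal-kernel-smoothed density
of the Wald ratios — unweighted, or inverse-variance weighted.  The
bandwidth is `bandwidth_factor` (default 1) times the
median-absolute-deviation plug-in rule
$0.9 \min(\mathrm{sd}, \mathrm{mad}) J^{-1/5}$; degenerate clouds (all
ratios equal, or zero spread) return the common ratio directly.  Standard
errors use the same parametric bootstrap.

Before the bootstrap, the median and mode estimators re-orient every SNP
pair to $\hat\beta_{Xj} \ge 0$.  The Wald ratios are unchanged, and this
makes the seeded bootstrap — not just the point estimate — invariant to
how instruments happen to be oriented on input.

All estimates are reported on the log-odds scale (`beta`) and the
odds-ratio scale (`or_ = exp(beta)`) with 95% intervals
$\exp(\beta \pm 1.96\,\mathrm{se})$.

# Sensitivity battery

* **Cochran's Q** over the Wald ratios with first-order weights,
  $\chi^2_{J-1}$ reference; exactly calibrated under the homogeneous null.
* **Egger intercept test** as above.
* **Radial MR**: the IVW fit re-expressed with response
  $\hat\theta_j\sqrt{w_j}$ and predictor $\sqrt{w_j}$,
  $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, exposing per-SNP contributions
  $Q_j = w_j(\hat\theta_j - \hat\theta)^2$ that sum to Cochran's $Q$ (an
  identity the tests assert to 1e-8).  A SNP is an outlier when $Q_j$
  exceeds the $\chi^2_1$ quantile at `radial_alpha` (default 0.05, no
  multiplicity correction — the cited method's common default).
* **MR-PRESSO**: observed residual sum of squares
  $\mathrm{RSS} = \sum_j w_j(\hat\beta_{Yj} -
  \hat\theta_{(-j)}\hat\beta_{Xj})^2$ with leave-one-out IVW slopes
  $\hat\theta_{(-j)}$; the null distribution is built from `presso_nsim`
  (default 10000) parametric draws of both effect vectors, the global p is
  the rank of the observed RSS floored at `1/n_sim`, per-SNP outlier
  p-values are Bonferroni-corrected, and the distortion test compares the
  estimate shift after outlier removal against removing equally many
  random SNPs.  SNPs are processed in canonical rsID order so the seeded
  p-values do not depend on row order.
* **Leave-one-out**: stability requires every leave-one-out IVW estimate
  to keep the full estimate's sign and, when the full estimate is
  significant, to stay nominally significant.  This is an explicit
  operationalization of "no single SNP drives the finding"; no consensus
  numeric rule exists, so the definition is documented rather than
  implicit.

For the decision rule, *heterogeneity* means Cochran's Q **or** the PRESSO
global test rejects at $\alpha$; *pleiotropy* means the Egger intercept
rejects.  The three tools are named together by the screening procedure
without combination logic, so the disjunction — the more cautious
reading — is the package's choice.

# Instrument selection and harmonization

Per metabolite: (1) keep SNPs with exposure $p < 10^{-5}$; (2) greedy LD
clumping by ascending p-value (ties broken by rsID for determinism) within
a 500 kb window at $r^2 < 0.01$; (3) require per-SNP strength
$F = (\hat\beta/\hat\sigma)^2 > 10$, reporting the variance explained
$R^2 = F/(F + n - 2)$; (4) drop instruments associated with the outcome
($p < 10^{-5}$) or absent from it; (5) analyze only metabolites with at
least `min_ivs = 4` surviving instruments (the screening convention reports
metabolites with as few as 4 instruments, so the boundary is $\ge 4$ and
configurable).

No reference panel ships with the package: clumping accepts an explicit
pairwise $r^2$ table (`snp_a`, `snp_b`, `r2`), and in its absence is
distance-only — one SNP per window, the conservative reading.  SNP pairs
absent from a supplied table are treated as independent.  Replication runs
against real data should supply a 1000-Genomes-derived table.

Harmonization aligns outcome records onto the exposure's effect-allele
frame: identical allele pairs pass through, swapped pairs have the outcome
effect negated and frequency complemented, incompatible pairs (e.g. A/G
vs A/C) are dropped, and palindromic pairs (A/T, C/G) are dropped when
either side's effect-allele frequency lies in the ambiguity band
`maf_band` (default [0.40, 0.60]) or is missing; outside the band they are
oriented by matching frequency sides.  "Middle allele frequency" is not
quantified anywhere authoritative; the 0.40–0.60 default is configurable
and a `strict_palindromes` switch drops all palindromes.  One consequence:
harmonizing a dataset against itself is the identity *on retained SNPs*,
while frequency-ambiguous palindromes fall regardless of the source — the
drop is a property of the SNP, not of the comparison.

# LD score regression

Per-SNP $\chi^2_j = z_j^2$ is regressed on the LD score $\ell_j$ under
$E[\chi^2_j] = 1 + \text{intercept offset} + n_j h^2 \ell_j / M$: an OLS
pass gives a provisional $h^2$, then the fit is repeated with the standard
heteroskedasticity weights $1/[\max(\ell_j,1)(1 + n_j \hat h^2 \ell_j /
M)^2]$.  Heritability is `slope * M / mean(n)`.  Standard errors come from
a delete-one-block jackknife over `n_blocks = 200` contiguous blocks
(auto-shrunk to $\lfloor J/2\rfloor$ for small inputs, so desk-scale
simulations with $M \approx 2000$ work).  Estimates are *unreliable* — and
serialize as literal `NA`, mirroring how screening reports present
unestimable heritabilities — when the jackknife fails or $\hat h^2 \notin
[-0.5, 1.5]$.

Genetic correlation regresses $z_{1j} z_{2j}$ on $\ell_j$, scales the
slope by $M/\sqrt{\bar n_1 \bar n_2}$ to a genetic covariance, and
normalizes by the per-trait heritabilities estimated on the SNP
intersection.  The regression intercept (which absorbs sample overlap) is
estimated, not constrained, even though the motivating cohorts are
non-overlapping.  $r_g$ is computed whenever both heritabilities are
positive; the reliability flag additionally requires both heritability
jackknifes to succeed and $|r_g| \le 1.25$ (a soft bound).  The whole
$r_g$ pipeline is jackknifed per block for its standard error, and
$r_g(a,b) = r_g(b,a)$ to numerical precision.

LD scores are consumed as input (`snp`, `l2` columns); computing them from
genotypes is out of scope, and the generator produces model-consistent
scores.

# The screen and the decision rule

`run_forward_screen()` applies the per-metabolite pipeline, then the
three-criterion rule, evaluated in order:

1. IVW $p < 0.05$ (raw; **no** multiple-testing correction across
   metabolites, faithful to standard screening practice — an informational
   Benjamini–Hochberg column `ivw_p_fdr` is emitted for users, and the run
   manifest records that it does not feed the verdicts);
2. no heterogeneity and no pleiotropy per the sensitivity flags;
3. leave-one-out stability;

plus an exclusion: a significant Egger intercept in the *reverse* analysis
(disease instruments against the metabolite) marks the metabolite
`excluded_reverse_pleiotropy`.  The first failing criterion names the
verdict; metabolites with fewer than `min_ivs` instruments are
`insufficient_ivs`.

In the default `paper_faithful` mode the secondary estimators (weighted
median, Egger, modes) are computed only for IVW-significant metabolites,
matching the screening workflow this package re-implements; `mode =
"full"` computes them for everything.  Likewise LDSC annotation defaults
to validated metabolites only (`ldsc_scope = "validated"`).  Whether one
should re-estimate the secondary methods after PRESSO outlier removal is
genuinely open; the PRESSO component therefore reports both the raw and
the outlier-corrected IVW estimate.

Every stochastic component (bootstraps, PRESSO simulations) takes its seed
from the screen configuration; per-exposure seeds are derived
deterministically from the master seed, so a complete run is a pure
function of (inputs, config, seed) — the suite asserts byte-identical
output files across repeated runs.

# The synthetic-data generator

`simulate_pair()` draws, per instrument $j$:
$\gamma_j \sim N(0, \texttt{gamma\_sd}^2)$ (truth),
$\alpha_j \sim N(\texttt{pleio\_mean}, \texttt{pleio\_sd}^2)$
(pleiotropy), observed
$\hat\beta_{Xj} = \gamma_j + \varepsilon_{Xj}$ and
$\hat\beta_{Yj} = \theta\gamma_j + \alpha_j + \varepsilon_{Yj}$ with
normal errors of scale `se_x`, `se_y`; p-values are the exact two-sided
normal p of $\hat\beta/\sigma$ (floored at $10^{-300}$ so noiseless
configurations still satisfy the $p > 0$ record invariant).  A
`round(outlier_frac * J)`-sized subset receives an extra pleiotropy offset
of magnitude `outlier_scale * se_y` with random sign — "an outlier with
pleiotropy 10 standard errors" is `outlier_scale = 10`.  Background SNPs
(default 50 per instrument) are drawn under the global null so the
significance filter and clumping have realistic work; allele assignment
plants palindromic pairs (`palindrome_frac`, half with in-band
frequencies so both palindrome branches are exercised), incompatible
outcome pairs (`mismatch_frac`), and swapped-orientation outcome records
(`swap_frac`).  The truth record keeps $\gamma$, $\alpha$, the noise
draws and the outlier identities, so dataset and truth are exactly
mutually consistent.

Default scales are chosen once to emulate the motivating data: exposure
GWAS of $n = 7824$ with per-allele standard errors around 0.012 (a
standardized metabolite at typical allele frequencies), outcome GWAS of
$n \approx 365{,}000$ with log-odds standard errors around 0.03, and
instrument effects `gamma_sd = 0.08` giving F statistics broadly in the
10–100 range with per-SNP variance explained of a few tenths of a percent
— the regime the screening application reports.  Two switches matter for
method experiments: `orient_gamma` takes $|\gamma_j|$ (the
exposure-increasing orientation; with sign-symmetric instruments the
*apparent* direction of pleiotropy cancels when estimators re-orient
pairs, so directional-pleiotropy recovery experiments enable it), and
`gamma_min_z` rejection-samples $\gamma$ to a minimum true z so
genome-wide-strength instrument sets can be produced by construction.  The
InSIDE assumption holds by construction; `inside_violation = TRUE`
correlates $\alpha$ with $\gamma$ to probe MR-Egger's failure mode.

`simulate_ldsc_inputs()` draws LD scores from a shifted gamma
($\ell = 1 + \Gamma(2, 10)$) and bivariate-normal z-scores with variances
$1 + n_t h^2_t \ell/M$ and covariance
$\sqrt{n_1 n_2}\, r_g \sqrt{h^2_1 h^2_2}\, \ell/M$ — the LDSC model with
unit intercepts.

What the generator does **not** emulate: real LD block structure (pairwise
$r^2$ for clumping tests is supplied directly as a table), linkage between
instruments and background SNPs, allele-frequency-dependent effect sizes,
case-control ascertainment, and sample overlap between the two GWAS.
Passing tests therefore demonstrate correctness of the statistical
machinery under the model it assumes, not robustness to every property of
real GWAS data.

# Numerical choices and experiment sizes

* Weighted regressions are solved from sufficient statistics (sums), and
  the block jackknife reuses per-block sums, so LDSC with $M = 5000$ and
  200 blocks costs a few milliseconds per fit.
* Clumping ties are broken lexicographically by rsID; PRESSO canonicalizes
  SNP order; both make seeded results order-invariant.
* The p-vs-z consistency check on input flags records where
  $|p - 2(1-\Phi(|\beta/\sigma|))| > 0.01$ but never alters them.
* The test suite's experiment sizes — 2000 replicates for null
  calibration at $J = 50$, 500 for slope recovery, 300 for the
  median-robustness comparison, 200 each for outlier recovery and LDSC
  coverage, PRESSO at 1000 simulations inside replicated experiments —
  were fixed once as the package's standard desk-scale study and give
  Monte-Carlo error comfortably inside the asserted bands.

# Known limitations

* Exact numerical agreement with other MR software is not promised: the
  Wald-ratio SE order, the overdispersion truncation, bootstrap designs
  and mode bandwidth rules all vary across implementations; this package
  documents its conventions precisely instead.
* LDSC here is single-component (no partitioned heritability, no
  liability-scale conversion) and consumes LD scores as input.
* Real-data replication of any published metabolite screen additionally
  depends on the LD reference panel and munging choices, which published
  reports typically leave unstated; heritability values in particular are
  sensitive to them.
* Proxy-SNP lookup for instruments missing in the outcome and Steiger
  direction filtering are deliberately out of scope.
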