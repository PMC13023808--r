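---
title: "Methods: two-sample MR with two-step mediation in mrchain"
author: "mrchain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with two-step mediation in mrchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`mrchain` implements two-sample Mendelian randomization (MR) along a causal
chain: a genetically instrumented exposure (for example blood expression of a
regulatory gene), a candidate mediator (for example the abundance of a gut
microbial taxon), and a binary disease outcome. Using only GWAS summary
statistics from non-overlapping cohorts, the package estimates the total causal
effect of the exposure on the outcome, the two legs of the indirect pathway
through the mediator, and decomposes the total effect into direct and mediated
components. Every estimate rests on the three instrumental-variable
assumptions: instruments are strongly associated with their exposure,
independent of confounders, and affect the outcome only through that exposure.
The sensitivity battery exists because the third assumption (exclusion
restriction) is untestable directly and fails in recognizable ways —
heterogeneity, directional pleiotropy, single outlying instruments, reverse
causation.

## Instrument quality control

A `gwas_table` validates one summary-statistics table per trait (distinct
A/C/G/T alleles, `se > 0`, p-values in (0, 1], frequencies in [0, 1]); invalid
rows are dropped and logged, never silently repaired. Instrument construction
then applies, in order:

1. **P-value selection** — strict `p < p_threshold`. Defaults follow the two
   data shapes the package targets: `5e-8` for cis-acting molecular exposures,
   `5e-6` for microbiome abundance traits, where genome-wide significance
   would leave too few instruments.
2. **Greedy LD clumping** — keep the smallest-p SNP, remove everything on the
   same chromosome within `window_kb` (default 10,000 kb, center-to-center)
   with squared correlation at or above `r2_max`, repeat. Default `r2_max` is
   0.1 for the exposure layer (lenient, preserving cis instruments) and 0.001
   for the mediator layer. SNPs missing from the LD matrix are treated as
   unlinked and logged; positions are 1-based.
3. **Weak-instrument filtering** — the per-SNP F statistic is approximated by
   `(beta/se)^2`, the square of the marginal Z score, which needs no per-SNP
   variance-explained input; SNPs with `F < 10` are excluded. The boundary is
   strict (exactly 10 is retained) and the threshold configurable.
4. **Allele harmonization** — outcome effects are re-expressed on the
   exposure's effect allele: matching orientations copy, swapped alleles
   negate the outcome beta and take `1 - EAF`, and strand-complement matches
   are folded in the same way. Palindromic pairs (A/T, G/C) carry no
   orientation information in their alleles, so orientation is inferred from
   allele frequency; when either study's EAF lies within 0.08 of 1/2 (or is
   missing) the SNP is dropped as `ambiguous_palindrome`. The band is a
   compromise between losing instruments and mis-orienting them, and is
   configurable.
5. **Steiger directionality filtering** — a SNP that explains more variance in
   the outcome than in the exposure is more plausibly an outcome instrument.
   Variance explained is approximated by `r² = Z²/(Z² + n)` for both traits;
   for binary outcomes this observed-scale approximation is flagged in the
   report rather than corrected to the liability scale, since the filter only
   compares the two quantities and the approximation is monotone in |Z|. The
   per-SNP report includes a Fisher-z two-correlation test p-value (needs
   n > 3 in both studies; otherwise NA).

Duplicated SNP identifiers keep the smallest-p record. Every exclusion at
every stage lands in a drop log `(snp_id, stage, reason)` that the pipeline
serializes, so a filtered analysis is fully auditable.

## Estimators

All estimators operate on the harmonized set and return effects on the
exposure-unit → outcome scale (log-odds for binary outcomes).

- **Wald ratio** (single SNP): `beta_out/beta_exp`, SE `se_out/|beta_exp|`
  (first-order delta; exposure-side noise enters only at second order).
- **IVW with multiplicative random effects** (primary): weighted regression of
  outcome on exposure effects through the origin, weights `1/se_out²`. The
  fixed-effect SE is inflated by `max(1, sqrt(Q/(J-1)))` — overdispersion is
  absorbed, but the SE never deflates below the fixed-effect value. The cap
  makes the test mildly conservative under exact homogeneity (its exact null
  rejection rate at J = 50 is about 0.043 at nominal 0.05; the test suite
  verifies this by numerical integration rather than pretending the rate is
  exactly 5%). Additive (DerSimonian–Laird-style) random effects were
  deliberately not used: the multiplicative form is the convention in the
  two-sample MR literature this package follows.
- **MR-Egger**: instruments are oriented so all exposure effects are positive
  (the slope is invariant to this allele recoding; the intercept is not), then
  weighted regression with an unconstrained intercept. The intercept estimates
  the average directional pleiotropic effect under InSIDE; slope and intercept
  use t inference with J − 2 degrees of freedom and the same capped
  multiplicative inflation.
- **Weighted median**: linear interpolation of the weighted ratio quantile
  function at 0.5 using `p_j = (S_j - w_j/2)/S_total`; consistent when valid
  instruments carry half the weight. SE by seeded parametric bootstrap
  (default 1,000 draws) redrawing both effect columns from their normals.
- **Simple and weighted mode**: Gaussian-kernel density over the per-SNP
  ratios with bandwidth `phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)` (phi = 1
  by default), argmax over a 512-point grid spanning the ratios; the weighted
  variant scales each kernel by the SNP's inverse-variance weight. When all
  ratios coincide the bandwidth is zero and that ratio is returned directly.

P-values are normal for IVW/median/modes and t-based for Egger; these are
conventions, not identities, and are recorded with the results. Bootstrap SEs
are bit-reproducible under a fixed seed; because the bootstrap redraws are
paired with SNPs in input order, reordering SNPs leaves every point estimate
unchanged but can perturb a bootstrap SE in the last digits.

## Sensitivity battery

- **Cochran's Q** on the ratio estimates against the fixed-effect IVW, with
  chi-square reference (J − 1 df).
- **MR-PRESSO**: the observed residual sum of squares uses leave-one-out IVW
  slopes; `n_sim` (default 1,000) parametric simulations redraw both effect
  columns under the per-SNP leave-one-out fit, giving an add-one Monte-Carlo
  global p `(1 + #{RSS* ≥ RSS}) / (n_sim + 1)`. Per-SNP outlier p-values come
  from each SNP's own simulated residual distribution, Bonferroni-adjusted by
  the instrument count. The distortion test compares the shift in the IVW
  estimate after removing flagged outliers against a null of equally many
  randomly removed SNPs; it is reported only when at least one SNP is flagged,
  and the outlier-corrected estimate is an annex, never a silent replacement.
- **Leave-one-out**: full IVW re-estimates per excluded SNP.
- **Scatter and funnel tables**: emitted as plain data.frames (points, fitted
  lines, precision coordinates) so any plotting layer can render them; the
  package deliberately does not bundle styled figures.

## Two-step mediation

With `beta_all` the total exposure→outcome effect, `beta1` the
exposure→mediator effect (estimated with exposure instruments) and `beta2` the
mediator→outcome effect (estimated with mediator instruments):

- indirect effect `beta1 * beta2`, SE by first-order propagation of error
  `sqrt(beta1² se2² + beta2² se1²)`; the second-order term `se1² se2²` is
  available behind a flag (it matters only for weak, noisy legs);
- direct effect `beta_all - beta1*beta2`, SE assuming independence of the two
  terms (the three estimates come from different instrument/outcome pairings;
  when cohorts overlap this is optimistic, and the report says so);
- proportion mediated `beta1*beta2 / beta_all`, SE by the delta method on the
  ratio. Proportions outside [0, 1] are reported as computed with an
  `inconsistent_mediation` flag — truncation would hide a qualitatively
  important signal (opposing direct and indirect paths). A zero total effect
  leaves the proportion undefined, with a reason, rather than infinite.

The decomposition `direct + indirect = total` holds to machine precision by
construction. Screening before decomposition requires all three links to pass
the nominal IVW significance level `alpha` (default 0.05); multiple-testing
modes (Bonferroni, Benjamini–Hochberg) annotate the tables and report the
implied corrected threshold, but screening itself stays nominal — the
expected-false-positive arithmetic (`tests × alpha`) is printed alongside so
the cost of that choice is visible.

## The synthetic chain generator

`simulate_chain()` emulates the statistical shape of the three data layers:
a quantitative exposure instrumented by ~10 cis SNPs at n = 30,000
(expression-QTL scale), a quantitative mediator at n = 5,959 with instruments
near the 5e-6 threshold (microbiome-GWAS scale), and a binary outcome with
8,434 cases among 778,614 subjects. True per-SNP effects get random signs and
uniform magnitudes scaled so the instruments jointly explain a configured
variance (defaults 10% for the exposure, 5% for the mediator — the latter
deliberately places mediator instruments at the edge of the 5e-6 threshold, as
in the data it mimics). Exposure SNPs act on the mediator through `beta1` and
on the outcome liability through `beta_direct + beta1*beta2` plus an optional
per-SNP pleiotropy draw; mediator SNPs act on the outcome through `beta2`.

Two engines generate observed summary statistics. The **analytic** engine sets
`se = 1/sqrt(2p(1-p)n)` for unit-variance quantitative traits, scales binary
SEs by `1/sqrt(k(1-k))` (k the case fraction), maps liability effects to
log-odds with the small-effect constant `phi(t)/(k(1-k))` at the liability
threshold `t`, and samples observed effects around their true marginals. The
**individual** engine simulates genotypes and phenotypes explicitly (liability
threshold at the empirical prevalence quantile, per-SNP linear or logistic
fits) and is restricted to n ≤ 50,000; it exists to validate the analytic
engine, and the test suite checks that pooled standardized deviations
(observed minus true, over analytic SE) have unit spread across engines within
10%.

What the generator does **not** emulate: realistic LD (blocks are
exchangeable and effects across SNPs are drawn independently), compositional
microbiome count structure (abundance is a latent quantitative trait, as in
the transformed-abundance GWAS it stands in for), winner's-curse selection in
the source GWAS, or sample overlap between cohorts. Tests passing on this
generator therefore establish correctness of the estimators and the plumbing
under the stated model, not robustness to those real-data features.

`plant_violations()` injects auditable defects — weak instruments (F planted
in (2, 8)), one-or-more gross ratio outliers (10× the true effect, halved SE),
directional pleiotropy shifts, reverse-causal SNPs (outcome variance explained
built to exceed exposure variance explained several-fold), and palindromic
recodes at EAF 0.49 — each recorded in the truth object so filter bookkeeping
can be asserted exactly.

## Pipeline and reproducibility

`run_study()` executes the four-step design: (1) each exposure against the
outcome at the exposure-layer thresholds; (2) each mediator against the
outcome at the mediator-layer thresholds, plus a reverse-direction MR
(outcome as exposure, instruments at 5e-8 with mediator-layer clumping — the
reverse threshold is an assumption, stated in the config) for every mediator
that passes screening; (3) screened exposures against screened mediators;
(4) mediation screening and decomposition. Reverse-significant mediators are
annotated, never excluded: a mediator can be both cause and consequence, and
hiding the latter would overstate certainty. A fatal error in one pair aborts
that pair only and is listed in the report.

Per-pair sub-seeds are derived from the master seed and the pair label by a
deterministic string hash, so adding or removing one pair never changes
another pair's bootstrap or simulation draws. Two runs with the same inputs,
config and master seed write byte-identical report bundles (TSV tables plus a
JSON config echo), which the test suite asserts via file checksums.

## Validation problem sizes

The packaged checks run at deliberately moderate sizes chosen to make the
statistical assertions sharp while keeping the suite quick to iterate on:
type-I calibration at J = 50 over 2,000 null replicates (compared against the
capped test's exact rate obtained by numerical integration), estimator bias at
J = 100 over 1,000 replicates, MR-PRESSO detection/specificity over 200
replicates of J = 20 with 1,000 simulations each, Steiger behavior over 200
replicates with 5 planted reverse SNPs, and mediation-proportion CI coverage
over 500 replicates of a 50+50-instrument chain with strong instruments
(coverage lands near 96%). The delta-method check uses a 4×10⁷-draw product
oracle so the oracle's own Monte-Carlo error is negligible against the 2%
tolerance (the first-order SE truly sits 1.94% below the exact product SD).

## Known limitations

- Instruments are treated as independent by all estimators; there is no
  correlated-instrument (generalized) IVW, so lenient clumping (r² ≥ 0.1) is
  flagged in the pair result but not corrected for.
- The liability-to-log-odds constant is a small-effect approximation; very
  large per-SNP effects on a binary outcome would need logistic fits.
- Direct-effect and proportion SEs assume independent inputs; overlapping
  cohorts make them anti-conservative and there is no overlap correction.
- The mode estimators' bandwidth rule is a pragmatic default; their bootstrap
  SEs are the slowest component and dominate pipeline runtime.
- No multivariable MR: the direct effect is obtained by subtraction, not by
  joint instrumentation of exposure and mediator.
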