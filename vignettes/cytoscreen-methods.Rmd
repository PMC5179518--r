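---
title: "Models and methods behind cytoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoscreen)
```

`cytoscreen` analyses cytokine screens of differentiating human CD4⁺ T
cells measured by flow cytometry. This vignette is the package's account of
the statistical machinery: the models, their assumptions, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, and the numerical and design choices that were genuinely open.

## The screen and its design table

A screen crosses cytokine conditions with donors and activation times. The
default panel is eight recombinant cytokines at their working
concentrations — IL-1β 12.5 ng/ml, IL-6 25 ng/ml, IL-21 25 ng/ml, IL-23
25 ng/ml, IL-2 100 IU/ml, IL-10 25 ng/ml, TGF-β1 5 ng/ml, TGF-β3 5 ng/ml —
with a no-cytokine control per time point, every single cytokine, and all
28 pairwise combinations (`generate_design()`). Concentrations are
nonnegative, the control rows are exactly the all-zero rows, and every
cytokine column must vary; these invariants are enforced on construction
and on file read. Culture-condition arithmetic is part of the config
surface: `medium_sodium()` encodes that the serum-free base medium holds
115.8 mM sodium and the standard 30 mM NaCl supplement brings it to the
145.8 mM "physiologic" level; the low-sodium condition is the
unsupplemented base.

## Sequential gating

Raw event tables pass through the standard sequence — lymphocyte scatter
gate, doublet exclusion, viability gate, optional CD4 gate (applied only
when the channel exists) — with each step deterministic and
parameter-driven (`gating_config()`):

* **Lymphocyte gate.** The dominant FSC-A/SSC-A mode is found by a Gaussian
  mixture (1–3 components, BIC-selected); events of the heaviest component
  within its empirical `lymphocyte_rule` (default 0.95) Mahalanobis
  quantile are kept. We chose a model-based gate over a kernel-density
  contour because a density contour at coverage q cannot simultaneously
  guarantee at-least-q retention on clean samples and high precision on
  debris-contaminated ones; the mixture gate is deterministic, has no
  hand-drawn polygon, and meets both.
* **Doublet exclusion.** Doublets carry roughly doubled pulse width *and*
  doubled area, which makes them high-leverage points for a naive robust
  regression; the pulse-width trend against FSC-A is therefore fitted (by
  an M-estimator) on the FSC-A interquartile bulk only, and events whose
  positive residual exceeds `doublet_rule` (default 4) robust SDs are
  removed.
* **Viability gate.** With a stained (dead-cell) control, the threshold is
  the control's `viability_rule` quantile (default 0.01). Without one, a
  two-component mixture on log dye intensity supplies the dead component;
  a unimodal sample is treated as all live, because an all-dead unimodal
  sample is indistinguishable from an all-live one without a control —
  operators should supply the control, as at the bench.
* **Marker positivity.** The threshold is the `positivity_quantile`
  (default 0.999) quantile of an isotype or FMO control's distribution;
  about 0.1% of the control itself calls positive, matching standard
  isotype practice. Where isotype and FMO controls disagree, the choice of
  control is the caller's; both are accepted.
* **Generations.** The proliferation dye halves per division, so
  `log2(reference/intensity)` counts divisions; generation g spans
  [g − 0.5, g + 0.5) and generations are capped at 7 (dye resolution
  limit), later cycles pooling into the last bin. We deliberately use
  half-integer boundaries rather than per-peak deconvolution: the rule is
  exact in the noise-free limit and correct to >99% at a realistic 10%
  dye CV, and it has no fitting failure modes.

## The net-effect regression

For every treated sample the response is the within-donor, within-time (and
within-experiment, when an experiment key is present) difference in
%positive against the matched control; replicate wells are averaged before
differencing. Predictors are (i) per-cytokine concentrations min-max
normalized over the design, (ii) one column per unordered cytokine pair,
and (iii) normalized time. "Standardized" means exactly this min-max
scaling — no z-scoring is layered on top, since double-scaling would
distort the interaction columns.

The pair columns deserve the detail: the product of two Uniform(0,1)
variables is not uniform, so raw products would enter the penalty on a
different scale than the main effects. The product of n independent unit
uniforms has density (−ln x)ⁿ⁻¹/(n−1)! on (0,1]; its CDF

$$F_n(p) = p \sum_{k=0}^{n-1} \frac{(-\ln p)^k}{k!},$$

which reduces to p − p·ln p for n = 2, maps the product back to a uniform
scale. `uniformize_product()` implements F_n for any n ≥ 2; it is strictly
increasing, maps (0,1] onto (0,1], and p = 0 (an absent cytokine) maps to 0
by continuity inside `build_design()` while being rejected at the public
boundary to expose upstream errors. No time-by-cytokine interactions are
formed: interactions are defined between cytokine pairs only.

The lasso objective is (1/2n)·‖y − β₀ − Xβ‖² + λ‖β‖₁ with an unpenalized
intercept, solved by cyclic coordinate descent with covariance updates,
warm-started along a decreasing log-spaced λ grid (50 values from the
smallest all-zero λ down to 10⁻³ of it; the grid is configuration, the
published profile does not fix one). Convergence is declared when the
largest coefficient change in a sweep falls below 10⁻⁷. The solver exposes
per-sweep objective traces so the tests can assert monotone descent, and it
is cross-checked against an independent solver on shared grids.

λ is the minimizer of the mean CV curve: 10-fold cross-validation with
squared-error loss, repeated over independent fold-split realizations and
averaged. We default to 50 repeats — the selected λ is already stable there
for screens of this size — with the full 1,000 available by argument. The
minimizer (not a one-SE rule) is the plainest reading of "optimal λ"; a
one-SE alternative would shrink more aggressively and is easy to add at the
call site. Folds can be grouped by donor so that all samples of a donor
stay in one fold, since responses within a donor share an offset; the donor
count bounds the usable fold count in that mode, and with fewer donors than
folds the fold count drops to the donor count with a warning.

Net effects read off the selected fit: a cytokine's net effect is its
coefficient; a pair's is the sum of both single coefficients and the
interaction coefficient. No p-values or intervals are attached to lasso
coefficients — the method reports effects, not inference.

## Co-expression at two levels

Population-level: Spearman ρ between %positive fractions of marker pairs
across samples (condition × donor × experiment), ties handled by average
ranks. The accompanying p-value treats the per-donor ρ as the random
variable: ρ is recomputed within each donor and a two-sided one-sample
t-test against zero is applied across donors. This operationalizes a
"paired test on ρ"; it is one defensible reading of pairing for a
correlation coefficient, and the output flags it as an interpretation
rather than the only possible construction.

Single-cell level: Spearman ρ between min-max normalized intensities over
the cells of each sample (≥ 10 cells; smaller samples are skipped with a
warning), reported per sample and grouped by condition class. Because ρ is
a rank statistic, any strictly monotone per-channel transform — logicle,
arcsinh, linear gain — leaves it unchanged. The two levels answer different
questions and can legitimately disagree: markers induced by the same
conditions need not be expressed by the same cells. The test suite plants
exactly this dissociation (population-level co-regulation of GM-CSF with
FOXP3, single-cell copula co-expression of GM-CSF with IFN-γ) and checks
that both orderings are recovered.

Group comparisons use a Shapiro–Wilk pre-test on the paired differences;
non-normal (or too-small) samples fall to the exact Wilcoxon signed-rank
test paired within donors, and the test actually applied is always
reported. All tests are two-sided. All-zero differences are degenerate and
reported as p = 1 with a flag rather than an error. No multiple-testing
correction is applied by default, matching the reporting convention of
screens of this kind; Benjamini–Hochberg can be layered on downstream.

## Subpopulation discovery

GM-CSF⁺ cells are pooled in equal numbers per donor and condition
(`select_positive_subset()`), the selection marker's own channel is
excluded, and the remaining five features (FOXP3, CD25, IFN-γ,
proliferation dye, IL-2) are min-max normalized after pooling.

The embedding is exact t-SNE: full N² input affinities with a per-point
bandwidth search, θ = 0 (no tree approximation), the standard momentum
schedule with early exaggeration, and a default budget of 10,000
iterations. Perplexity follows the 10%-of-N rule, rounded half-up
(`compute_perplexity()`; 2,580 pooled cells give 258), and must stay below
N/3. Initialization is the first two principal components scaled to SD
10⁻⁴ plus a seeded jitter — the reference implementations initialize
randomly, but a PCA start makes runs reproducible bit-for-bit under a seed,
which we value more than initialization diversity. KL divergence is traced
so tests can assert descent.

Clustering operates on the 2-D embedding (a config switch allows
feature-space clustering for comparison): full-covariance Gaussian
mixtures — the ν = ∞ limit of a t-mixture, implemented directly as
Gaussians — fitted by EM to a relative log-likelihood tolerance of 10⁻¹⁵
with up to 10,000 iterations and k-means-seeded restarts, keeping the best
likelihood. Components collapsing below a covariance floor trigger a
restart; if all restarts collapse, the fit errors rather than returning a
degenerate model. BIC is 2·logL − npar·log N. The cluster count is chosen
as the *smallest* K whose BIC lies within a tolerance of the best BIC over
the candidate range (default 1–12). Raw BIC values are scale-dependent and
essentially never "close to zero", so the closeness clause is
operationalized as within-δ-of-best with δ defaulting to 1% of the BIC
range across candidates; the minimal-K clause is kept literally. Points
whose squared Mahalanobis distance to their assigned component exceeds the
80% quantile of χ²₂ (≈ 3.219) are flagged as out-of-cluster outliers.
Clustering is run per condition, mirroring how such screens compare
induction conditions.

## Cycle-conditioned quantification

`fraction_by_cycle()`, `quadrant_by_cycle()` and `cycle_distribution()`
condition marker statistics on the proliferation generation. Quadrant
fractions sum to 100 within each generation and the triple-positive
fraction can never exceed any pairwise double-positive fraction; both are
asserted. Generations with fewer than 20 cells (configurable) are reported
as explicit missing values, never as zeros — a binomial-noise control the
underlying experiments do not state, so it is ours and documented as such.
The point of conditioning is confounder removal: if positivity depends
only on generation and a treatment shifts only the generation
distribution, per-cycle fractions are treatment-invariant even though the
marginal fractions differ; a dedicated fixture asserts exactly this.

## The synthetic generator: what it does and does not emulate

The generator produces the statistical structure the analysis assumes, with
full ground truth:

* **Bimodal marker fluorescence** as a two-component log-normal mixture
  (autofluorescence ~ meanlog log 100, positive component ten-fold
  brighter, sdlog 0.35) — the simplest family producing realistic bimodal
  histograms.
* **Per-cell co-expression** through a Gaussian copula on latent scores;
  intensity is the mixture-quantile transform of the copula's uniform
  score, so the planted rank correlation is exactly the copula's
  ((6/π)·asin(ρ/2) for latent ρ). One idealization follows: the quantile
  transform makes marker rank order globally monotone in the latent score,
  so positive cells never rank below negative ones, whereas real mixture
  components overlap slightly in intensity.
* **Effect structure on fractions**: baseline + additive donor offset +
  main effects on normalized concentrations + interaction effects on
  uniformized products + Gaussian noise, clipped to [0, 100]. Donor
  offsets shift treated and control samples identically, so they cancel
  exactly in within-donor differences — a property the tests exploit. The
  default planted screen (TGF-β1 +10, IL-6 −10, IL-23 −10 percentage
  points, donor SD 3, noise SD 2, baseline 10%) mirrors the qualitative
  induction/repression pattern such screens report, at a signal-to-noise
  ratio of 5.
* **Proliferation dye** at a 20,000-unit undivided mean, halving per
  generation, with 5% multiplicative CV (10% in stress tests).
* **Contamination**: debris (low scatter), doublets (doubled width, area
  and fluorescence), and dead cells (bright viability dye).

Not emulated: spectral spillover and compensation (channels are
spillover-free; compensation is assumed already applied), instrument noise
beyond log-normal spread, acquisition-time drift, and secreted-protein
(ELISA) readouts. Passing tests therefore demonstrate correctness of the
algorithms under the generative assumptions, not robustness to every
artefact of real cytometry; on real data the gating steps in particular
should be inspected visually.

Per-condition cell counts are configurable everywhere (the underlying
experiments do not state recorded counts); fixtures default to
10³–10⁴ cells per sample.

## Determinism and problem sizes

Every stochastic routine takes a seed; per-sample and per-stage seeds are
derived from the root seed by a fixed counter scheme, and
`run_pipeline()` writes a manifest (parameters, seeds, MD5 hashes) such
that identical configs yield byte-identical outputs. The test suite and the
acceptance script run scaled problem sizes chosen as adequate for their
statistical assertions: screens of 6–8 donors at 3 time points (648–864
regression rows), 50 CV repeats (of the published 1,000), 10⁵-draw KS
checks, t-SNE at a few hundred cells and a few hundred iterations, 100
cluster-count simulations, and 200 replicate screens for sign-recovery
power. Each assertion's tolerance is derived from the binomial or
Monte-Carlo error of its own sample size.

## Known limitations

* The lymphocyte gate assumes the dominant scatter mode is the population
  of interest; panels where lymphocytes are a minority need an explicit
  scatter window first.
* Generation assignment trusts a single undivided reference; if generation
  0 is empty and the reference is auto-detected from the brightest peak,
  labels shift by the number of missing leading generations.
* The paired t-test on per-donor ρ requires each donor to contribute ≥ 3
  samples with nonconstant fractions; sparse designs yield NA p-values
  rather than a fallback test.
* Exact t-SNE is O(N²) per iteration; beyond ~5,000 pooled cells the
  iteration budget should be reduced or the pooled count capped
  (`per_group_count`), as the default profile is deliberately exact rather
  than tree-approximated.
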