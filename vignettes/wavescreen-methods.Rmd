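---
title: "Wavelet-based regional association screening: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based regional association screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the model and its assumptions, the parameters that matter, the Monte-Carlo
calibration, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open and a choice had to be made.

## 1. The model

### Genotype signal and measurement error

Within a window `[lb, ub]` we observe imputed dosages
`G_k(bp) = G_{0,k}(bp) + ε_k(bp)` at positions `bp_1 < … < bp_n`, with the
imputation-error variance tied to the per-SNP imputation quality,
`σ²(bp) = 1 − IQ(bp)`. Only SNPs with `IQ ≥ 0.8` are analysed (the
`iq_min` argument of `read_genotypes()`). The proportionality constant
between `σ²` and `1 − IQ` is taken as exactly 1: it only enters through the
shrinkage thresholds, where a common constant rescales all thresholds
together, and the final inference is calibrated by simulation, so the
constant is immaterial.

### Gridding and the wavelet pyramid

Positions are mapped affinely onto `[0, 1]` by
`x ↦ (x − bp_1)/(bp_n − bp_1)`, and each individual's signal is linearly
interpolated onto the grid `t_k = (k + ½)·2^{−J}` with
`J = min{ j : 2^j ≥ n }` (constant extrapolation beyond the outermost SNPs).
Linear interpolation is exact on locally linear signals and cannot
overshoot, which keeps interpolated dosages inside `[0, 2]`.

The signal is decomposed into the orthonormal Haar *sum* pyramid: coefficient
`(s, l)` is the normalised sum of the `2^{J−s}` grid values in its dyadic
footprint — a local minor-allele burden at resolution `s`. Scales `0..S` are
retained; the full difference spectrum (`haar_forward(..., pyramid = "d")`)
is also available, is exactly orthogonal, conserves energy, and inverts to
machine precision, but testing uses the sum pyramid, whose coefficients have
the burden-score interpretation.

### Denoising and Gaussianisation

Each coefficient is soft-thresholded at `√(2 log N)·σ_{s,l}` (`N = 2^J`),
where `σ²_{s,l}` is the per-SNP noise variance propagated diagonally through
the interpolation weights and the transform row — a coefficient built from
well-genotyped SNPs is barely touched, one built from poorly imputed SNPs is
shrunk hard. Hard thresholding is available (`threshold = "hard"`), soft is
the default as is standard for universal-threshold shrinkage. Columns are
then mapped to exact normal scores by the rank-based inverse-normal
transform with the Blom offset 3/8 (`inv_normal_offset`; any fixed offset in
[0, ½] would do, the choice is recorded for reproducibility). Constant
(degenerate) columns cannot be Gaussianised — they would enter the linear
model as discrete variables — so they are flagged, excluded from regression
and testing, and their thresholded posteriors fixed at 0.

### Reverse regression and the constrained mixture

Each normalised coefficient is regressed on the phenotype (plus covariates)
through one shared QR factorisation; only the phenotype coefficient
`β̂_{sl,1}` is kept. Because the response is quantile-transformed, the
residual variance is 1 by construction and `Var(β̂) = v = (XᵀX)⁻¹₂,₂` under
the null — the residual variance is deliberately *not* re-estimated per
column.

The pyramid of `β̂` values is fitted with the two-component mixture
`(1 − π_alt)·N(0, σ²_null) + π_alt·N(μ_alt, σ²_alt)` under the constraints
`σ²_null > v/10` and `σ²_alt > k·v` with `k = 100` (configurable). A single
global `π_alt` is estimated: per-coefficient weights are unidentifiable from
one observation each. Constraints are enforced by clamping after each
M-step; since the M-step objective is separable and unimodal in each
variance, the clamp is the box-constrained M-step maximiser and the
generalised-EM ascent property is preserved — the log-likelihood trace is
non-decreasing, which the test suite checks. EM starts from `π_alt = 0.05`,
`μ_alt` = mean of the 5 % largest `|β̂|`, `σ²_null = v`, `σ²_alt` = the
larger of that top set's variance and `1.01·k·v`; it stops at a relative
log-likelihood change below 1e-8 or 500 iterations, returning the best
iterate with `converged = FALSE` on non-convergence (screening continues and
flags the region). All-identical inputs take a degenerate path with
`converged = FALSE` rather than erroring.

### Posteriors, summaries, and the composite statistic

Posterior alternative probabilities `π̂_{l,s}` follow the two-component Bayes
formula, computed in log space. They are thresholded by
`π̃ = max(π̂ − 1/(√(2 ln K)·√(2^s)), 0)`, decreasing in both the sample size
`K` and the scale. The `n` inside the logarithm is the *sample size*: the
threshold is described as decreasing with sample size, although the
universal-threshold analogy it descends from uses the signal length — with
`K` of order 10³–10⁴ and `2^S` of order 10²–10³ the two readings give
thresholds of the same order, and the sample-size reading is implemented.

Three summaries with equal weight per scale follow: the average evidence

`L_h = Σ_s 2^{−s} Σ_l [ π̃·φ(β̂; μ_alt, σ²_alt) − (1 − π̃)·φ(β̂; 0, σ²_null) ]`,

the horizontal proportion `p_h = Σ_s 2^{−s} Σ_l π̃`, and the vertical
proportion `p_v`, which splits the finest-scale axis into `S − 1` equal
sub-regions with boundaries `⌊2^S(k−1)/(S−1)⌋..⌊2^S k/(S−1)⌋` and averages
`π̃` over the coefficients (scales 1..S) whose dyadic footprint overlaps each
sub-region; a coefficient straddling a boundary belongs to both neighbours.
For `S < 2` there is no proper split and `p_v` falls back to `p_h`. The
composite statistic is `T = L_h + λ·min(p_h, p_v)`.

## 2. Null calibration

The wavelet transform correlates the `β̂`, so the null cannot be simulated
marginally. Four constructions are available (`method` of
`ws_calibrate()` / `simulate_null_betas()`):

* `"permutation"` — reverse-regress fresh standard-normal (or permuted
  observed) phenotypes against the *observed* coefficient matrix. This
  reproduces the test's null exactly, including the empirical coefficient
  correlation and the per-draw design-variance jitter, and is the default
  wherever a genotype matrix is in hand (experiments, `ws_screen()`).
* `"random-signal"` — wavelet-transform white-noise signals and rescale the
  columns to mean 0, variance 1 (the default of `simulate_null_betas()`;
  needs no data at all).
* `"empirical-cov"` — multivariate normal with covariance `v·R`, `R` the
  column correlation of a supplied coefficient matrix (this follows from
  `β̂_m = wᵀG̃_m` with `wᵀw = v` and exchangeable individuals).
* `"theoretical"` — multivariate normal with the exact row-overlap
  correlation of the sum-pyramid rows.

Non-positive-semidefinite covariances are repaired by clipping negative
eigenvalues, with a warning. On LD-free data the four constructions agree
(the suite checks pairwise Kolmogorov–Smirnov distances); on strongly
LD-structured data the permutation null is the trustworthy one, which is why
it is the default for inference.

Each null draw is pushed through the *full* statistic — including a fresh
mixture refit — because the observed statistic also refits the mixture;
freezing the mixture parameters across draws would calibrate a different
statistic than the one being tested. This is the single most consequential
design decision in the package (see §5).

### Choosing λ

`λ*` balances power (large λ exploits `min(p_h, p_v)`, which is larger under
the alternative) against null normality (λ·minp is bounded and skewed, so
large λ deforms the null). For each λ on a geometric grid
`λ_j = (sd(L_h)/sd(minp))·2^j`, `j = −10..40`, a normal is fitted to the
null draws of `T_λ` and their p-values are histogrammed into 1000 equal bins
on [0, 1]. The first bin (p near 0) is the one whose inflation would distort
the false discovery rate; bins are ranked by descending count. The search
stops once the first bin becomes clearly more prominent than at λ = 0 and
`λ*` is the largest grid value at which its prominence still matches the
λ = 0 reference.

Implementation detail that matters in practice: the first bin's *rank* also
moves when unrelated bins reshuffle by Monte-Carlo noise, so a literal
rank-comparison stop fires spuriously at the first grid point. The package
therefore judges "clearly more prominent" and "equal" on the first-bin
*count* with Poisson noise bands (`c₀ + 3√(c₀+1)` to stop, `c₀ + √(c₀+1)`
for equality), while recording both the rank and count trajectories in the
returned object. On a noiseless trajectory this is the same criterion; under
noise it is stable across seeds (the suite checks that 10⁵-draw calibrations
yield `λ* > 0` and a criterion-satisfying first bin).

The final null is the normal fitted to `T_{λ*}` by sample mean and standard
deviation (no robust fit; recorded in the calibration object), and region
p-values are its upper tail. Calibrations serialise to JSON
(`write_calibration()`) so screening runs can reuse them.

## 3. Screening

Windows default to 1 Mb with half overlap (a signal on any window boundary
is interior to the neighbouring window), a maximum adjacent-SNP gap of 10 kb
(a 50 kb setting suits sparse arrays), and at least 64 SNPs; windows
violating either rule are excluded and the excluded fraction reported. The
analysis depth follows the rule of thumb of about 10 SNPs per finest-scale
coefficient: the largest `S` with `region_len/(2^S·spacing) ≥ 0.85·10`. The
0.85 slack resolves near-ties toward the deeper resolution and reproduces
both worked examples that motivated the rule (202 bp spacing → S = 9 at 9.7
SNPs per coefficient; 3525 bp → S = 5 at 8.9), whereas a strict `≥ 10` rule
would contradict them. Fewer than ~10 SNPs per coefficient would make the
finest coefficients effectively discrete and break the Gaussian linear
model.

Half-overlapping windows mean a real signal is typically reported twice; the
screen table keeps both rows (no de-duplication rule is imposed — merging is
the analyst's decision). Coordinates are 1-based inclusive throughout, as in
VCF. Failed regions keep their row with the failure reason in `status`,
never silently dropped. Runs are deterministic given `seed`, and a JSON
manifest (versions, seed, calibration summary) is written next to the TSV.

## 4. The synthetic-data generator

`ld_block_model()` + `simulate_genotypes()` emulate a densely imputed 1 Mb
locus: 5209 SNPs at 202 bp spacing partitioned into 28 contiguous LD blocks;
within a block, latent Gaussians share an exchangeable correlation
ρ = 0.8, across blocks they are independent; latents are cut at
Hardy–Weinberg thresholds for a per-SNP MAF uniform on [0.05, 0.5]; additive
noise with variance `1 − IQ` (IQ uniform on [0.8, 1]) is added and dosages
are clipped to [0, 2] — the error law is deliberately unspecified in the
underlying model, and the clipped truncated normal is our concrete choice,
harmless because the inference is simulation-calibrated.

Phenotypes are local-polygenic scores: the (signed) sum of dosages over a
causal set, plus Gaussian noise scaled so the score explains 0.5 % of the
phenotypic variance (the empirical score variance is used, and the realised
fraction is returned). Mono-directional (MD) effects are all `+1`;
random-direction (RD) signs are iid `±1`. "High-LD" selection opens eligible
blocks (≥ 5 members) in random order and fills each with up to five causal
SNPs before opening the next, so causal SNPs are mutually correlated — the
block-polygenic signature in which the score variance is superadditive and
nearby burden coefficients track the score strongly. "Random-LD" selection
draws uniformly, giving mutually independent causal SNPs and the classic
dilution effect. With `n_causal = 0` the phenotype is exactly standard
normal, the same path the type-I driver uses.

What the generator does **not** emulate: realistic recombination maps and
coalescent haplotype structure, MAF–LD coupling, non-exchangeable
within-block correlation, population stratification or relatedness, variable
SNP density, and real imputation-error correlation. Passing tests therefore
demonstrate the pipeline's internal correctness and its calibration under a
plausible LD-structured null — not that power or error rates transfer
quantitatively to any particular cohort.

In the power driver each simulated phenotype is standardised before
regression. `L_h` is not scale-invariant (its component densities scale with
`1/√v`), and the simulated phenotypes' raw variance depends on the causal
set, while the calibration is built for unit-variance phenotypes;
standardisation puts the observed statistic and its null on the same scale
and is what any analyst does with a continuous trait anyway.

## 5. Open design choices, and what they cost

* **Affine map.** The stated map `x ↦ (x − bp_1)/bp_n` cannot reach 1; the
  implemented `x ↦ (x − bp_1)/(bp_n − bp_1)` maps the window onto [0, 1] as
  intended.
* **Mixture refit vs. freeze in calibration.** We refit per null draw,
  mirroring the test's full randomness. The alternative — freezing mixture
  parameters at the observed fit — produces null draws whose
  `min(p_h, p_v)` is essentially always zero, which lets the λ search run to
  enormous values and makes the λ·minp term a near-oracle detector; but it
  calibrates a statistic other than the one actually computed on data, and
  under our generator it would be anti-conservative at small α (a fraction
  of true-null refits do produce `minp > 0`). The refit choice is honest and
  conservative; its cost is that `λ*` stays moderate and the composite
  statistic's extreme tail is lighter than the normal fit assumes.
* **Consequences for type-I error.** Under the LD-block generator the null
  `L_h` (and hence `T`) is mildly left-skewed, so the fitted normal
  under-covers the right tail: the suite's type-I experiments land below
  nominal (around 3–4 % at the 5 % level, and a few per-mille at the 1 %
  level), never above. The method is over-conservative under these
  conditions; empirical (rank-based) p-values from the calibration draws
  would be exactly uniform but are not what the procedure specifies.
* **Consequences for power.** With the total variance explained fixed at
  0.5 % and split over a diluted causal set, individual standardised effects
  reach only ~2–6 at K = 10⁴; the mixture detects the clustered high-LD
  configurations, and end-to-end power at the 1e-5 threshold is clearly
  nonzero at K = 10⁴ while sitting at the floor at K = 10³ — the orderings
  (MD ≥ RD under clustering, power growing with K) are reproduced, absolute
  values are generator-specific.
* **Eq.-style threshold `n`.** Sample size, not signal length (§1).
* **Depth-rule slack 0.85.** See §3.
* **λ-scan robustification.** See §2.
* **High-LD causal clustering.** One-causal-SNP-per-block selection would
  make "high-LD" statistically identical to "random-LD"; the clustered rule
  restores the intended contrast (§4).

## 6. Numerical choices and degenerate inputs

EM tolerance 1e-8 (relative log-likelihood), cap 500 iterations; posterior
and mixture densities in log space; energy identity and reconstruction exact
to 1e-10 and checked on a thousand random signals; constant coefficient
columns excluded with `π̃ = 0`; `p = 0` inputs to Fisher's method clamped to
the smallest positive double with a warning; non-PSD null covariances
repaired by eigenvalue clipping with a warning; rank ties in the quantile
transform resolved by average ranks.

Problem sizes used by the test suite and the acceptance script are scaled to
desk-top runs and are the package's own choice: type-I experiments use
10³–5×10³ phenotype replicates over a fixed 5209-SNP region with 1.5–2×10⁴
calibration draws; λ* behaviour is checked on 10⁵ draws; power cells use 250
replicates. Monte-Carlo tolerances in the tests are three binomial standard
errors at the sizes actually run.

## 7. Known limitations

Reverse regression shrinks with phenotype measurement error; allele-coding
direction matters for MD-type signals (a miscoded risk allele behaves like
RD); the normal null fit is conservative under skew (above); a single
calibration is shared across windows of equal depth, ignoring window-specific
LD; multi-allelic variants must be split upstream; no relatedness or
mixed-model correction is provided.
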