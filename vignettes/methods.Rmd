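---
title: "Methods: urinary 1H-NMR profiling with OPLS-DA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary 1H-NMR profiling with OPLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urimet)
```

This vignette documents the statistical model, the synthetic-data
generator, the numerical choices made in the implementation, and the
resolution of the ambiguities that any implementation of this kind of
pipeline must decide.

## 1. The discrimination problem

Two groups of urine ¹H-NMR spectra — a reference group (benign prostatic
hyperplasia, BPH, n = 51 by default) and a case group (prostate cancer,
PCa, n = 64) — are to be discriminated from bucketed spectral intensities,
and the discriminating spectral regions assigned to metabolites and
confirmed univariately. Urine is hostile raw material: dilution varies
several-fold, peak positions shift with pH and ionic strength, and the
water and urea resonances are unusable. Each pipeline stage targets one of
these nuisances.

## 2. The synthetic cohort generator

`simulate_cohort()` draws spectra from an explicit generative model so that
ground truth exists for every quantity the pipeline estimates.

Each metabolite in `default_metabolite_library()` is a set of Lorentzian
resonances parameterized by **area**: a peak with area $A$, center $\mu$
and half-width $h$ contributes $(A/\pi)\, h / ((\delta-\mu)^2 + h^2)$,
evaluated on the acquisition grid and truncated at $\pm 50$ half-widths.
Because the integral of the Lorentzian density is 1, window integrals are
analytically predictable — the test suite exploits this.

Per sample $i$ and metabolite $m$:

- concentration $c_{im} = \bar c_m \, e_{m}(g_i) \, L_{im}$ with
  $L_{im} \sim \text{LogNormal}(0, \sigma_{\log} = 0.2)$ (biological
  variation, ~20% CV) and $e_m(g)$ the planted group-effect ratio from
  `default_effect_map()` (1 for the reference group);
- dilution $d_i \sim U(0.5, 2)$ multiplies the whole spectrum;
- chemical-shift jitter: per-metabolite Gaussian shifts, sd 0.003 ppm,
  truncated at ±0.01 ppm;
- a slowly rolling sinusoidal baseline (amplitude 0.01) and i.i.d.
  Gaussian noise (sd 0.02) are added.

The default acquisition grid is δ 0.15–9.50 at 0.001 ppm. The effect map
plants increases in branched-chain amino acids, glutamate and
pseudouridine and decreases in dimethylglycine, glycine, the unassigned
δ 6.49 singlet, fumarate and 4-imidazole-acetate; the ratios are chosen to
reproduce representative literature group means for these windows.

Realism and limits: peaks are pure Lorentzians with no J-coupling
fine structure beyond fixed multiplet patterns, jitter moves whole
metabolites rigidly, and noise is white. These simplifications keep
analytic ground truth available; they understate the difficulty of real
alignment and baseline correction, which is why the aligner and baseline
handling are validated on the properties they claim (variance reduction,
fixed points) rather than on absolute realism.

## 3. Bucketing

`bucket_spectra()` tiles $[\delta_{\min}, \delta_{\max})$ with half-open
rectangular buckets from the low-ppm end, summing grid intensities. Any
bucket with open-interval overlap of the water (δ 4.55–5.09) or urea
(δ 5.52–6.10) exclusion regions is dropped whole. Over δ 0.15–9.50 at
0.01 ppm this gives $935 - 54 - 58 = 823$ variables; the pipeline reaches
the same table by fine 0.001-ppm bucketing followed by `rebin(, 10)`, and
a test asserts the two routes agree bucket-for-bucket.

Bucket values are *sums* (not means) of grid intensities, so integrals
scale as $1/\Delta\delta_{\text{grid}}$ and total signal is conserved
under rebinning — also asserted.

## 4. Alignment

`align_spectra()` implements a reference-based segment aligner: the
reference is the spectrum with maximal mean correlation to the others;
peaks are local maxima above median + 3·MAD; segments are split
recursively at the largest inter-peak gap and each segment is shifted by
the integer lag maximizing cross-correlation with the reference. It is
deliberately simple — the validated claims are that an aligned cohort is a
fixed point, that a rigidly shifted copy returns to within one fine
bucket, and that planted jitter's peak-position variance collapses.

## 5. Normalization

**PQN** (`pqn_normalize`): spectra are first integral-normalized, a median
reference spectrum is computed, and each sample is divided by the median
of its bucket-wise quotients to the reference. The returned `dilution` is
the **total** per-sample factor (integral ratio × quotient median), so on
a cohort where dilution is the only per-sample scale factor it correlates
with the true dilution at r > 0.999. With biological concentration noise
at its default 20% CV the correlation is bounded near 0.95: the median
quotient over ~16 metabolites has irreducible sampling noise. "Noiseless
recovery" therefore means all per-sample noise sources off, including
concentration noise; the acceptance script reports both numbers.

**Unit-variance scaling** (`uv_scale`) divides each centred column by its
standard deviation, dropping zero-variance columns with a warning and
returning an invertible scaling model so fold-wise refitting inside
cross-validation is exact.

## 6. PCA screening

`pca_fit()` (SVD on centred data) with Hotelling
$T^2_i = \sum_a t_{ia}^2 / s_a^2$ against the critical value
$\frac{A(n-1)}{n-A} F_{1-\alpha}(A, n-A)$. Score-space $T^2$ flags samples
extreme in the dominant-variance plane; a narrow single-peak contaminant
that does not reach that plane is by design *not* flagged, whereas a broad
contamination dominating PC1 is. Outlier exclusion is an explicit pipeline
option, never automatic.

## 7. OPLS-DA

With $y \in \{-1,+1\}$ (centred) and centred $X$, the predictive weight is
the closed form $w = X'y/\lVert X'y\rVert$ (NIPALS fixed point for
univariate $y$). Each orthogonal component takes
$w_o \propto p - (w'p)w$, $t_o = X w_o$, $p_o = X't_o/t_o't_o$ and
deflates $X \leftarrow X - t_o p_o'$; since $X'y$ is invariant under this
deflation, orthogonal scores have exactly zero correlation with $y$
(asserted at 1e-8). Prediction collapses to a single regression vector
$b = \left[\prod_i (I - w_o^{(i)} p_o^{(i)\prime})\right] w q$ applied to
centred new data. A zero-orthogonal model is exactly PLS1, which is how it
is validated: against an independently coded iterative NIPALS oracle and
against `mixOmics::pls`.

## 8. Validation

- **Cross-validation**: stratified 7-fold; scaling (centering/UV) is refit
  inside each training fold (`scale = "refit"`) so no information leaks.
  $Q^2Y = 1 - \mathrm{PRESS}/\mathrm{SS}$.
- **Permutation test**: 100 random relabelings, each refit and
  cross-validated; empirical
  $p = (1 + \#\{Q^2_{\text{perm}} \ge Q^2\})/101$; R²/Q² intercepts from a
  least-squares line through the permuted points plus the original at
  correlation 1.
- **CV-ANOVA**: $F = ((\mathrm{SS}-\mathrm{PRESS})/A) /
  (\mathrm{PRESS}/(N-1-A))$ with $A = 1 + n_{\text{orth}}$ degrees of
  freedom for the model. The statistic is *conservative* under the null
  (the null rejection rate in Monte-Carlo is below nominal), which the
  test suite asserts as such rather than pretending uniformity.

## 9. Variable selection and selection bias

Buckets are kept when $|b_j| / \mathrm{SE}_{cv}(b_j) > 1$, where
$\mathrm{SE}_{cv}$ is the jackknife standard error over the $K$ fold
models, $\sqrt{\frac{K-1}{K} \sum_k (b_j^{(k)} - \bar b_j)^2}$. The
jackknife form (rather than the plain sd of fold coefficients scaled by
$\sqrt{(K-1)/K}$) was chosen because fold coefficients are highly
correlated — the plain sd underestimates the sampling variability and
retained ~83% of variables, while the jackknife retains roughly 40–55%
and all planted windows.

Reporting the cross-validated $Q^2$ of the *selected* model on the same
data is optimistically biased. The pipeline therefore also provides
`nested_cv_q2()`, which repeats selection inside each outer training fold;
on label-free data the nested estimate has non-positive median while the
naive select-then-revalidate estimate is strongly positive — both
demonstrated in the test suite. The headline selected-model $Q^2$ in
reports should be read with this caveat; the honest generalization
estimate is the nested one.

## 10. Univariate confirmation

`integrate_region()` integrates a ppm window as an overlap-fraction
weighted sum of bucket values. For windows whose edges align with bucket
edges this is exact and representation-invariant; for misaligned edges the
boundary buckets are weighted by covered fraction, which assumes locally
uniform intensity — with a sharp peak inside a boundary bucket the
discrepancy is bounded by that bucket's content (asserted as such). The
eight default windows are compared between groups with the Mann-Whitney
U test (exact enumeration for combined n ≤ 20 without ties, corrected
normal approximation otherwise, via `stats::wilcox.test`) and percent
variation $100(\bar x_{\text{case}} - \bar x_{\text{ref}})/\bar
x_{\text{ref}}$. Under 200 label-free cohorts the per-window type-I rate
at α = 0.05 is ≈ 0.05.

## 11. Problem sizes and budgets

All acceptance-grade checks run at the full study dimensions (115 samples
× 823 buckets). Representative timings on a single core: cohort
simulation ~0.5 s, bucketing ~0.2 s, one 100-round permutation test
~3 s, the entire test suite ~4–5 minutes, the acceptance script
~3.5 minutes (dominated by the 200-cohort type-I Monte-Carlo and the
20-cohort null permutation study).

## 12. Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(cohort = cohort_config(seed = 1),
                       n_permutations = 100, seed = 1)
rep <- run_pipeline(cfg)
rep
rep$univariate
compare_models(rep)
```
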