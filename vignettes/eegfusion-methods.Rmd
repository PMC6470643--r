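---
title: "eegfusion: methods, modelling choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eegfusion: methods, modelling choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfusion)
```

# Overview

`eegfusion` discriminates two clinical brain states — a delta-dominant,
low-complexity "coma-like" state and a spectrally flatter, higher-complexity
"death-like" state — from multichannel frontal EEG. The pipeline is:
non-overlapping epoching, sub-band filtering, parametric spectral features
(relative band power from an autoregressive spectrum), ordinal complexity
features (permutation entropy), PCA reduction, canonical-correlation feature
fusion, group ANOVA with Bonferroni correction, and a Gaussian-kernel SVM
evaluated by leave-one-out cross-validation. This vignette documents the
models, every tunable that matters, the synthetic world used for testing,
and the numerical choices made where the design was genuinely open.

# Epoching and sub-bands

Recordings are segmented into contiguous non-overlapping epochs starting at
sample 0 (default 60 s; any tail is discarded). The six sub-bands are
δ 0.5–4, θ 4–7, α 8–12, β 13–30, γ1 30–40 and γ2 41–100 Hz, kept with their
conventional gaps (7–8, 12–13, 40–41 Hz); intervals are closed-open
`[low, high)`. Relative-power denominators always use the full 0.5–100 Hz
range rather than the union of bands, so the six fractions sum to strictly
less than one on any real spectrum.

**Band-pass realization.** No IIR filter-design library is available in the
supported environment, so band-pass filtering is performed in the frequency
domain: a zero-phase amplitude mask with raised-cosine transitions
(half-width 0.5 Hz, half-amplitude at the band edge). This filter is exactly
linear and zero-phase, numerically robust at the 0.5 Hz delta edge, and its
stop-band rejection is effectively complete; the trade-off is a small,
fixed spectral leakage of ±0.5 Hz at each edge. Artifact removal
(ICA-based in clinical practice) is out of scope; `preprocessHook()` offers
a no-op (default) or a 0.5 Hz high-pass in its place.

# Parametric spectral estimation

The power spectral density is estimated parametrically. An AR(p) model
$x(n) = \sum_{k=1}^{p} a_k x(n-k) + \varepsilon(n)$ is fitted by the
Yule–Walker method: Levinson–Durbin recursion on the biased sample
autocovariance. The spectrum is the standard AR transfer-function form

$$\hat p(f) = \frac{\hat\sigma_\varepsilon^2}
{f_s\,\bigl|1-\sum_{k=1}^{p} \hat a_k e^{-i 2\pi f k / f_s}\bigr|^2}.$$

(Printed forms of this estimator sometimes omit the squared modulus; only
the squared form has the units of a power density, so that is what is
implemented.)

Defaults follow the field's operating point: order `p = 10`, sliding
Hamming windows of 250 samples with half overlap, arithmetic averaging of
per-window spectra, and a 0.5 Hz frequency grid over `[0, fs/2]`. Each
window is tapered and its autocovariance rescaled by the taper power
`mean(w^2)`; the signal is demeaned **once globally** — demeaning every
250-sample window separately would act as a high-pass at ≈ 4 Hz (at
1000 Hz sampling) and destroy the delta band. Relative band power uses
trapezoidal integration on the frequency grid with interpolated band edges.

**A known estimator limitation.** An AR(10) spectrum is a rational function
with five pole pairs; it cannot represent a strictly band-limited plateau.
On synthetic signals whose delta component is flat over 0.5–4 Hz and absent
elsewhere, the AR(10) estimate redistributes roughly a sixth of the delta
power into the 4–13 Hz region: a class built with delta weight 0.8 measures
≈ 0.63–0.66 rather than the designed ≈ 0.77 (the raw periodogram recovers
0.78; an independent reference Yule–Walker implementation reproduces the
same 0.66). This is a property of low-order AR approximation, not of the
implementation, and it affects *absolute* fractions only: band dominance,
class ordering and class separation are preserved, which is what the
statistics and classifiers consume. Real EEG spectra are smooth and
1/f-like and do not exhibit this plateau mismatch.

**Time-varying spectrum.** For monitoring, sliding windows (default 2 s,
step 0.1 s) are each tapered with `K` orthogonal discrete prolate spheroidal
sequences (computed from the classical tridiagonal eigenproblem;
time-bandwidth 2, `K = 3` by default — a reading of the conventional
"2–3 tapers" range), each tapered copy is AR-fitted, and the `K` spectra
are averaged, reducing estimator variance; `K = 1` degenerates to a plain
sliding-window AR spectrogram.

# Permutation entropy

For order `m` and lag `τ`, every embedded vector
$(x_i, x_{i+\tau}, \dots, x_{i+(m-1)\tau})$ is mapped to its ordinal rank
pattern and PE is the Shannon entropy of the pattern distribution,
$-\sum_j P_j \log P_j$, with $0 \log 0 = 0$. PE is bounded by `log(m!)`,
zero for monotone series, and invariant under strictly monotone transforms.

Choices: ties are broken by order of occurrence (stable ranking), so
permuting equal values never changes a pattern; a seeded-jitter alternative
is available. The default log base is e (nats) and the defaults `m = 4`,
`τ = 1` keep the pattern space (24) well below the epoch length. Published
mentions of very large "embedding dimensions" (e.g. 20) cannot be meant as
pattern length (20! patterns) and are not reproduced. Time-varying PE uses
consecutive non-overlapping windows (tail discarded); the degenerate
one-window case equals plain PE.

# Feature fusion

Each subjects × electrodes view (epoch-averaged delta-band rPSD; epoch-
averaged broadband PE) is column-centred, z-scored (the views mix unit-free
fractions with entropies in nats; z-scoring is the package's choice — the
literature is silent) and PCA-reduced to the minimal number of leading
components whose cumulative explained variance reaches 70 %. Principal
components carry a deterministic sign convention (largest-magnitude loading
positive) so results are reproducible and row-permutation-equivariant.

The reduced views `A`, `B` are fused by the compact-SVD canonical
correlation construction: `A = U_A Σ_A V_A'`, `B = U_B Σ_B V_B'`,
`U_A' U_B = U Σ V'`; projections `W_A = V_A Σ_A^{-1} U`,
`W_B = V_B Σ_B^{-1} V`; fused features `Z = [A W_A \,|\, B W_B]` with
`2r` columns, `r = min(rank A, rank B)`. The diagonal of `Σ` holds the
canonical correlations. (Some printed versions use `U` in both projection
formulas; that contradicts the underlying CCA construction, and the
standard right-singular-vector form is implemented.) Numerical rank uses
the `max(dim) · eps · σ_max` tolerance; a paired sign convention keeps the
fused features deterministic. Four feature sets are assembled: the two
PCA-reduced views, their concatenation, and the fused `Z`.

# Statistics and classification

Per feature, a one-way two-group ANOVA is computed (for two groups
`F = t²` of the pooled t statistic, df `(1, n₁+n₂−2)`), with Bonferroni
correction over the feature family (default size 6 — electrodes or bands)
at α = 0.01. The unit of observation is the subject (epoch-averaged
features), avoiding pseudo-replication; per-epoch tables remain available.

Classification uses a soft-margin SVM with Gaussian kernel
`exp(-γ‖x−z‖²)`. The dual QP is solved exactly with `quadprog` (a tiny
ridge ensures positive-definiteness). Evaluation is leave-one-out; for each
fold, `(C, γ)` are selected on the training subjects only, by stratified
3-fold inner CV over a coarse-to-fine grid: exponents of 2 in `[-5, 15]`
with step 4, then step 2 and 1 centred on the incumbent (the package's
reading of a "3-stage grid search"; ties resolve to the smallest grid
point). Features are z-scored with training-fold statistics only. Decision
scores are pooled across folds into a single ROC; AUC is the normalized
Mann–Whitney statistic with ties counting ½. Confusion counts are taken at
decision threshold 0 with the death-like class positive, so sensitivity is
the true-positive rate for death-like recordings. No class reweighting is
applied by default. All feature sets are evaluated under identical fold
structure and seeds, making set comparisons fair.

# The synthetic world

`generateCohort()` emulates the recording protocol (six frontal channels,
1000 Hz, five 1-min epochs by default) with two classes: coma-like
(label 0) and death-like (label 1). Each subject's signal is a sum of
independent band-limited Gaussian components whose expected band powers
follow the class profile, plus a class-specific fraction of broadband white
noise governing ordinal pattern diversity. Components are synthesised in
the frequency domain (shaped complex-Gaussian spectra, one inverse FFT per
channel-epoch) — distributionally identical to band-pass-filtered white
noise and exact in expected band power by construction.

Defaults state the world once: delta weight 0.85 (coma-like) vs 0.60
(death-like), noise fractions 0.1 vs 0.6 — the directions reported
clinically (death: less delta, more complexity), with magnitudes chosen for
a clearly separated reference world. Between-subject variability is a free
parameter with no published value; the package uses lognormal jitter
(sd 0.15) on band weights and logit-normal jitter (sd 0.25) on the noise
fraction. Identical specs (including seed) generate bit-identical cohorts.

What the generator does **not** model: neurophysiological generators,
1/f background structure, artifacts (ECG, movement, electrode noise),
volume conduction, inter-channel correlation. A green end-to-end test
therefore establishes that the pipeline recovers class structure planted
in band power and pattern diversity — not that it would achieve any
particular accuracy on clinical data.

# Numerical and degenerate-input choices

* Epochs start at sample 0; no epoch rejection.
* Constant signals are rejected by the AR fitter; the Levinson recursion
  stops if the prediction-error variance collapses.
* `relativeBandPower` errors when the band leaves the total range; the
  identity band returns exactly 1.
* PCA on a constant view errors; constant columns are left unscaled when
  z-scoring.
* CCA requires ≥ 2 subjects and nonzero rank; canonical correlations are
  clipped to `[0, 1]`.
* ANOVA requires ≥ 2 observations per group and nonzero within-group
  variance.
* The SVM bias uses free support vectors when available, otherwise the
  midpoint of the feasible interval.
* EDF input/output is not supported (no reader available in the supported
  environment); the interchange format is a delimited-text matrix plus a
  plain-text sidecar carrying `fs`, channel labels, subject id and label.

# Limitations

* Absolute rPSD levels from the AR(10) estimator are biased on spectra
  with sharp band edges (see above); comparisons across groups are
  unaffected.
* The multitaper taper count/time-bandwidth reading (K = 3, NW = 2) is an
  interpretation of an ambiguous convention; both are configurable.
* Leave-one-out with a nested grid search is computationally heavy for
  large cohorts; the implementation caches fold-level kernel inputs but
  remains O(n · grid · folds) QP solves.
* No non-parametric PSD beyond test references, no weighted-PE variants,
  no kernel/sparse CCA, no classifiers beyond the Gaussian-kernel SVM.
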