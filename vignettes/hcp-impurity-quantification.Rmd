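---
title: "Label-free quantification of host-cell-protein impurity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free quantification of host-cell-protein impurity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcpurity)
```

## Problem

A highly purified recombinant protein intended as a reference material still
contains residual proteins of the expression host (host cell proteins, HCP).
Its purity on a total-protein basis cannot be certified without quantifying
that impurity. `hcpurity` implements a label-free LC-MS approach: the summed
MS1 intensity of all identified host proteins, relative to the summed
intensity of the target protein itself, is calibrated against gravimetric
spikes of a host-proteome calibrant.

## The measurement model

### The intensity ratio

For one LC-MS run, with host-protein intensities $I_h$ and target-protein
intensities $I_t$ (summing over proteoforms of the target where applicable),

$$R = \frac{\sum_h I_h}{\sum_t I_t}.$$

The target acts as a pseudo internal standard: any factor common to all
intensities of a run (injected amount, ionization efficiency drift, detector
gain) cancels. `compute_ratio()` treats a missing protein as *absent from the
identification list*, contributing nothing to either sum — explicitly
distinct from an observed zero. A run with no target signal has an undefined
ratio and raises an `hcp_ratio_error` rather than returning `Inf`.

The ratio is approximately proportional to the impurity mass fraction $w$
(mg impurity per g target) when the intensity-per-mass response of the host
ensemble is stable across levels. It is *not* assumed that individual
proteins share a response factor; only the ensemble-weighted mean response of
the calibrant matters, which is why the calibrant's protein composition
should resemble the sample's (commutability).

### Calibration

Gravimetric spikes at design levels $w_i$ give pairs $(w_i, R_i)$, one per
run (replicate runs are separate points). `fit_calibration()` fits ordinary
unweighted least squares with intercept,

$$R = a + b\,w + \varepsilon,$$

via `stats::lm`, and stores the sufficient statistics for inverse
prediction: $s_{yx}$ (residual SD), $n$, $\bar w$, $\bar R$,
$S_{xx} = \sum (w_i - \bar w)^2$, and $\mathrm{df} = n - 2$. An intercept is
retained because a small host background in the "pure" target matrix or a
constant identification artifact shifts the line without changing its slope.
At least three distinct levels are required; fewer raise typed errors.

Known calibration-design levels can be computed from the gravimetric
preparation with `compute_design_level()`:
$w = 1000\,(m_\mathrm{cal} c_\mathrm{cal})/(m_\mathrm{tgt} c_\mathrm{tgt})$,
where $m$ are weighed masses and $c$ the protein mass contents of the two
stocks.

### Inverse prediction

For a sample measured in $m$ runs with mean ratio $\bar y_0$,

$$\hat w_0 = \frac{\bar y_0 - a}{b}, \qquad
s_{x_0} = \frac{s_{yx}}{b}\sqrt{\frac{1}{m} + \frac{1}{n} +
\frac{(\bar y_0 - \bar R)^2}{b^2 S_{xx}}}.$$

This is the standard first-order inverse-calibration approximation; it
combines sample replication ($1/m$), calibration size ($1/n$) and the
leverage of the sample ratio relative to the calibration centroid.
`predict_mass_fraction()` reports $\hat w_0$, $s_{x_0}$ and the relative
standard uncertainty $u_\mathrm{meas} = 100\,s_{x_0}/\hat w_0$, and flags
(without forbidding) extrapolation beyond the calibrated range and
predictions at or below the fitted blank. Tests verify $s_{x_0}$ against a
2000-replicate Monte-Carlo simulation of the whole fit-and-invert procedure.

Averaging is done on the ratio scale ($\bar y_0$ into one prediction). The
alternative route — predicting each run separately and averaging the $w$
values — is also available by calling `predict_mass_fraction()` per ratio
and `summarize_replicates()` on the results; for a linear calibration the
two point estimates coincide, and the replicate SD gives an empirical
(rather than model-based) spread.

### Uncertainty budget

`expand_uncertainty()` expands $u_\mathrm{meas}$ with the two-sided 95 %
Student-t quantile at the calibration's df,
$k = t_{0.975,\mathrm{df}}$, giving $U_\mathrm{meas} = k\,u_\mathrm{meas}$.

The calibrant's own value assignment (typically amino-acid-analysis-based
protein content, quoted as an expanded 95 % uncertainty $U_\mathrm{cal}$
with coverage factor $k_\mathrm{cal} \approx 2$) is independent of the
measurement. Because the two expanded components carry *different* coverage
factors, `combine_budget()` combines them on the standard-uncertainty scale
and re-expands with the measurement's $k$:

$$U_\mathrm{imp} = k\sqrt{\left(\frac{U_\mathrm{meas}}{k}\right)^2 +
\left(\frac{U_\mathrm{cal}}{k_\mathrm{cal}}\right)^2}.$$

When $k = k_\mathrm{cal}$ this reduces to the plain root-sum-square of the
expanded values, $U_\mathrm{imp}^2 = U_\mathrm{meas}^2 + U_\mathrm{cal}^2$,
the form usually quoted. The standard-level combination is the
GUM-consistent choice whenever the t-based $k$ differs appreciably from 2
(small calibrations), and it is the default throughout
(`run_value_assignment()`).

### Purity conversion

The impurity is expressed per mass of *target*; the purity per mass of
*total protein* is

$$P = \frac{1000}{1 + w/1000} \quad \text{mg target / g total protein}.$$

`impurity_to_purity()` converts the central value and the endpoints of the
symmetric expanded impurity interval $w(1 \mp U_\mathrm{imp}/100)$ (the
lower impurity bound mapping to the *upper* purity bound). Because the
transform is convex and decreasing, the purity interval is asymmetric with
the upper arm the longer one. The relative purity uncertainty is reported as
the half-width of the transformed interval over the central purity. The
lower impurity bound is clamped at zero; $w = 0$ yields exactly 1000 mg/g
with a degenerate interval.

## Validation tools

- **Leave-one-out cross-validation.** `loo_cv()` refits the calibration
  without each point in turn, inverse-predicts the held-out ratio, and
  summarizes the relative errors by their median and type-7 quartiles, with
  fliers beyond 1.5 IQR (an absolute guard of
  $\sqrt{\varepsilon_\mathrm{mach}}$ prevents numerically-zero errors on
  noise-free data from being flagged). The median is used rather than the
  mean because inverse-prediction errors are heavy-tailed near the blank.
- **Pooling.** `pool_calibrations()` concatenates several calibration series
  (different days, different calibrant lots) into one fit and reports the
  per-series fits alongside, for slope-commutability comparisons.
- **Profile analysis.** `profile_matrix()` + `pca_profiles()` decompose the
  runs × host-proteins intensity matrix (missing → 0, centered, *unscaled*
  by default so that high-abundance proteins carry their real weight;
  `scale. = TRUE` is available). Component signs are fixed by making the
  largest-magnitude loading positive. `copurified_fraction()` reports the
  share of host signal carried by a watchlist of co-purifying proteins, and
  `top_n_capture()`/`capture_bias()` quantify the error committed by
  monitoring only the N most intense host proteins: a capture fraction $c$
  underestimates the impurity by $(1-c) \cdot 100\,\%$ and overestimates the
  purity accordingly.

## Protein-subsampling simulation

How many calibrant proteins does the method need? `subsample_experiment()`
drafts $n$ of the $K$ calibrant host proteins, recomputes every calibration
and sample ratio using only the drafted proteins in the numerator, rescales
the design levels by the drafted mass share (when the design carries
`mass_shares`; disable with `rescale = FALSE` for whole-lysate designs whose
per-protein composition is unknown), refits, and inverse-predicts. Summary
statistics (median, SD, relative SD) over many drafts per $n$ show how the
sampling error shrinks as the draft approaches the full set;
`sampling_error_threshold()` returns the smallest $n$ whose relative SD
stays below a chosen threshold. Drafts whose numerator is empty in some run
are redrawn (counted in `n_resampled`). An exhaustive mode enumerates all
$\binom{K}{n}$ subsets for small $K$. Reproducibility is exact under a fixed
seed: each $(n, \mathrm{draft})$ pair uses a derived seed substream, so
results do not depend on evaluation order.

## The synthetic generator

`synthetic_spec()` / `generate_dataset()` produce complete, realistic
datasets used by the test suite (the generator is first-class, tested code):

- Each protein $j$ gets a lognormal mean-1 response factor $r_j$ with
  coefficient of variation `response_cv` (default **0.30** — intensity per
  mass varies several-fold between proteins, as observed for label-free
  MS1 quantification).
- Each cell gets multiplicative lognormal mean-1 noise with `noise_cv`
  (default **0.05**, typical run-to-run repeatability of summed MS1 areas).
- Intensity: $I_{jk} = s\, r_j\, m_{jk}\, \varepsilon_{jk}$, with host
  masses $m_{jk} = (w_k/1000)\cdot \mathrm{share}_j$ per 1 g of target and
  target masses from `target_shares`. With equal mean responses the true
  slope is $1/1000$ per mg/g; the generated truth (including the exact
  response-weighted slope) is returned alongside the data.
- `target_response_cv = 0` models a shared target stock across
  datasets for commutability studies; `detection_floor` censors low
  intensities to missing (not zero).

What it deliberately does **not** emulate: peptide-level detection,
chromatographic or charge-state effects, intensity-dependent missingness,
or correlated run effects beyond the common scale factor — the generator
targets the protein-level summing statistics the pipeline actually
consumes, not the raw instrument physics.

`make_mix_fixture()` builds a nine-protein defined-mix calibrant with a
fixed gravimetric composition, a broad-range grid (22.7–140.8 mg/g, three
replicates, $n = 18$, $\mathrm{df} = 16$) and a low-range grid
(0.2–1.4 mg/g, two replicates, $n = 12$, $\mathrm{df} = 10$), matching the
two regimes in which such a calibration is typically operated.

## Numerical choices and limitations

- All intermediates are carried at full double precision; rounding happens
  only in `print` methods and user-side reporting.
- OLS is solved by `stats::lm` (QR); tests pin it to a normal-equations
  oracle at $10^{-10}$ on realistic designs.
- $t$-quantiles via `stats::qt`; PCA via `stats::prcomp` (SVD).
- Seeds: `generate_dataset()` requires an explicit seed;
  `subsample_experiment()` derives per-draft seeds below $2^{31}$ from the
  user seed, the draft index and $n$.
- The inverse-prediction uncertainty is a first-order approximation; it
  degrades when $s_{yx}/(b\,\sqrt{S_{xx}})$ is large (calibrations barely
  distinguishable from flat) or when extrapolating far below the lowest
  level. The extrapolation flag, the below-blank error and the LOO
  diagnostics are the intended guards.
- Unweighted OLS assumes homoscedastic ratio noise across levels; over wide
  dynamic ranges (broad grid vs. low grid) separate calibrations per regime
  are preferable to one weighted fit, and that is how the fixtures are
  organized.
- The budget treats the calibrant value-assignment uncertainty and the
  measurement as independent and ignores commutability bias between
  calibrant and sample proteomes; `pool_calibrations()` and the generator's
  two-proteome mode exist to probe exactly that assumption.

## Typical problem sizes

All analyses here are desk-scale: calibrations of 12–18 runs, tens to
hundreds of host proteins, subsampling simulations of a few hundred drafts,
Monte-Carlo validations of 200–2000 replicates. The full test suite runs in
about a minute on one CPU.
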