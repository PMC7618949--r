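---
title: "Models and methods behind megmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind megmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megmetrics)
```

`megmetrics` computes resting-state electrophysiological summaries from
parcellated MEG source time courses and tests group and ageing effects on
them with permutation-based family-wise error control. This vignette
documents the underlying models, the parameters that matter, the numerical
conventions adopted where the methodology literature leaves latitude, and
what the synthetic validation suite does and does not establish.

## The measurement model

A subject's data is a parcels × samples matrix of source time courses
(nominally 52 cortical parcels at 250 Hz; both are configurable). Source
amplitudes from beamformed MEG are unitless, so every metric operates on
z-scored time courses: all densities are relative to unit total variance,
and between-parcel amplitude differences carry no information.

**Preprocessing** (`preprocess_subject()`) standardises each parcel,
applies a zero-phase (forward–backward) order-5 Butterworth band-pass of
1–80 Hz — zero-phase so downstream amplitude envelopes suffer no group
delay — and removes bad segments. A 1 s window is flagged when the z-score
of its log-variance across windows exceeds 3; log-variance symmetrises the
right-skewed distribution of windowed variance so the threshold acts on an
approximately Gaussian quantity. The union of per-parcel masks is removed
from every parcel, keeping parcels sample-aligned for connectivity, and the
concatenated remainder is re-standardised.

**Spectral power** (`welch_psd()`, `band_power()`) uses Welch's method with
2 s Hann windows and 50% overlap, giving a 0.5 Hz grid; no detrending is
applied because the input is standardised. The density scaling satisfies
Parseval: for a z-scored signal the one-sided density integrates to ≈ 1
over 0–Nyquist (the suite checks 5%). Band summaries are the *mean*
density over bins with `lo ≤ f < hi`, which keeps bands of unequal width
comparable; half-open membership means adjacent bands (delta/theta at 4 Hz,
alpha/beta at 13 Hz) never share a bin, and the 48–52 Hz gap between the
gamma bands excludes the line-noise notch region.

## Spectral parameterisation

`parameterize_spectrum()` decomposes each log-spectrum over 1–70 Hz
(higher frequencies are excluded to limit spectral-plateau bias) as

$$\log_{10} P(f) \;=\; b - \chi \log_{10} f \;+\;
  \sum_k PW_k \exp\!\left(-\frac{(f - CF_k)^2}{2\,(BW_k/2)^2}\right)$$

with the aperiodic mode fixed (no knee). The settings — peak bandwidth
limits 0.5–12 Hz, minimum peak height 0.05 log10 units, relative detection
threshold 2 SD of the flattened spectrum, unlimited peaks (safety-capped at
20) — follow common practice for resting MEG spectra.

Estimation proceeds in four steps. (1) A robust aperiodic line: ordinary
least squares, then a refit restricted to bins whose positive residual lies
below its 2.5th percentile, which discards peak regions. (2) Iterative peak
extraction from the flattened spectrum: the tallest residual point seeds a
Gaussian whose SD is guessed from the half-height span (FWHM/2.355, clipped
to the bandwidth limits); extraction stops when the tallest candidate falls
below `max(0.05, 2·SD(flattened))`. (3) Joint bounded least-squares
refinement of all Gaussians (L-BFGS-B; centres bounded to ±2 SD of their
guess, SDs to the bandwidth limits); peaks below the height floor or
outside the fit range after refinement are dropped. (4) A final aperiodic
fit on the peak-removed spectrum gives the reported offset and exponent χ.

Two caveats are inherent to this family of algorithms. Heavily overlapping
peaks (separation below roughly their common width) merge into a single
bump with a single maximum, and are fitted as one Gaussian. And on finite
recordings the Welch spectrum carries multiplicative sampling noise
(≈ 0.03–0.04 log10 units SD at 300 s), so occasional small residual bumps
(below ≈ 0.1 log10 units) are retained as peaks even for purely aperiodic
signals; genuine oscillatory peaks in these data are several times larger.

### Periodic spectrum and centre of energy

The periodic ("de-FOOOFed") spectrum is the *flattened* spectrum: log10
power above the final aperiodic fit. We use the log-domain convention
deliberately: a symmetric oscillatory peak is symmetric in log power, so
its balance point is its centre frequency. (In linear power the same peak,
riding a falling 1/f background, is left-skewed, and the balance point sits
systematically below the peak centre.) Negative values — aperiodic-fit
overshoot — are floored at zero.

The centre of energy (CoE), the oscillatory-speed summary, is the smallest
frequency at which cumulative periodic power reaches half the total
(`centre_of_energy()`, method `"balance"`). Each bin's mass is treated as
spread over its half-open 0.5 Hz cell, so the crossing is interpolated
within a bin and a symmetric single peak balances exactly at its centre.
With the ≥ convention, two exactly equal narrow peaks put the split point
at the lower peak. A power-weighted mean-frequency variant is exposed as
method `"mean"` for sensitivity analysis; the balance-point definition is
the default because it matches the operational definition of an
equal-power split and is robust to high-frequency tails. If the floored
periodic spectrum carries no power the CoE is missing (no oscillations).

### Peak bookkeeping

`select_band_peak()` reports, per subject × parcel × band (alpha 7–13,
beta 13–30 Hz), the retained peak of highest power, ties broken towards the
lower frequency. Missing cells are imputed with the mean over all
participants for that parcel and band (`impute_missing_peaks()`), pooled
across groups — group-wise imputation would build the group difference
being tested into the imputed values. Cells missing for every participant
stay missing and are excluded from designs. Missing-peak counts per subject
and band are computed before imputation and are themselves analysable
metrics (reduced peak detectability is a disease signature in its own
right).

## Amplitude-envelope connectivity

`amplitude_envelope()` computes the band-limited analytic signal in a
single spectral step: the FFT is masked to the positive frequencies of the
band, doubled, and inverted; the magnitude is the envelope, with 1 s
trimmed at each end for edge effects. This filter–Hilbert construction is
zero-phase and exactly scale-linear, so the AEC — the Pearson correlation
of two parcels' envelopes (`aec_matrix()`) — is invariant to parcel
rescaling at machine precision. (An IIR band-pass before the Hilbert
transform leaves the correlation invariant only to ≈ 1e-9: the narrow-band
filter's near-unit-circle poles amplify last-bit rounding.) Global
connectivity is a parcel's mean off-diagonal AEC; the self-correlation is
excluded since it would bias every value upward by 1/n. No leakage
correction (signal orthogonalisation) is applied; with beamformed data some
zero-lag leakage inflates short-range AEC, a caveat for interpretation on
real recordings. Envelopes are correlated at full sampling rate without
downsampling, and on the same good-segment-concatenated data as power.

## Group inference

Each metric cell (parcel × metric/band) is fitted by OLS against a design
built by `build_design()`: an ageing design (intercept, age, centred sex
and scanner), a group-comparison design (per-group indicators plus centred
age, sex, scanner and grey-matter volume, with pairwise ±1 contrasts), or a
per-group age-slope design for divergent-trajectory tests. Covariates are
mean-centred so group indicators keep their group-mean interpretation;
constant columns (e.g. a single-scanner cohort) are dropped with a warning;
rank deficiency is an error naming the collinear columns.

The cope (contrast of parameter estimates) `c'β̂` is reported with its
standard error, `t = cope/SE`, and residual degrees of freedom
`n − rank(X)`. `residual_df_report()` additionally echoes the bookkeeping
formula `n − (n_comparisons + n_regressors − 1 + 1)` that appears in
published reports, whose term accounting is ambiguous; inference always
uses the rank-based value.

Family-wise error across cells is controlled by the maximum-statistic
method (`maxt_permutation()`): for each of `n_perm` permutations (default
5000) the rows of the effect regressors — group indicators for group
contrasts, age for ageing contrasts — are permuted with nuisance columns
fixed, and the maximum |t| over all cells and contrasts is recorded. The
two-tailed corrected p-value is `(1 + #{null max ≥ |t_obs|})/(n_perm + 1)`,
the standard exceedance form, which is bounded away from zero and gives
small p-values to large effects; a literal "proportion of null maxima
smaller than t" would invert that orientation. Simple permutation of the
effect columns (rather than full Freedman–Lane residual permutation) is
exact under the strong null of no effect and no effect-nuisance dependence,
which holds by construction in the validation cohorts; cohorts with fewer
distinct permutations than requested are sampled with replacement and
flagged. `chi_squared_sex_balance()` provides the standard demographic
balance check (Pearson, no continuity correction).

## The synthetic-cohort generator

Because parcellated patient MEG recordings are not publicly deposited, the
package validates against simulated cohorts with known ground truth
(`simulate_cohort()`). Per parcel, the signal is

* an aperiodic background: white Gaussian noise shaped in the frequency
  domain by `f^(−χ/2)` above 1 Hz and flat below, scaled to unit variance —
  this gives the exact target log-log slope cheaply;
* oscillatory components: narrow-band carriers with Gaussian spectral
  profiles (centre CF, spectral SD BW/2) multiplied by slow positive
  envelopes `max(1 + g, 0)`, where `g` is a unit-SD Gaussian process
  low-passed below 1 Hz. Each component's envelope mixes a process shared
  across the parcels carrying it with an independent one,
  `w·shared + (1−w)·own`, so the sharing weight `w ∈ [0,1]` controls the
  between-parcel envelope correlation and hence the AEC. The modulated
  carrier is normalised to unit RMS and scaled by the component amplitude,
  so squared amplitude is exactly the component's variance share.

Covariate effects are linear and additive on the exponent, on log10
amplitude and on centre frequency — matching the GLM's linearity — with age
centred at the cohort age-range midpoint. Effects driving parameters out of
range are clipped with a warning. Covariates are sampled per the cohort
spec: ages uniform, sex Bernoulli, scanner uniform, and grey-matter volume
linear in age plus Gaussian noise (≈ −2.2 ml/year around 780 ml, a
realistic atrophy gradient; on real data this covariate comes from
structural MRI). All randomness derives from one root seed via
deterministic per-subject sub-seeds, so a fixed seed reproduces the cohort
bit-for-bit.

`expected_band_power()` maps ground truth and covariates to the expected
Welch mean density analytically, including the preprocessing chain: the
spectral shape is weighted by the forward–backward Butterworth power
response (|H|⁴) and renormalised to unit variance, since z-scoring happens
after filtering (the filter removes the sub-1 Hz plateau, ≈ 20–30% of total
variance at typical exponents, inflating retained densities accordingly).
This is the analytic truth used by the effect-recovery checks; the
comparable estimand for an OLS cope is the least-squares projection of that
expectation onto the design.

`default_effects()` encodes the qualitative directions reported for ageing
and neurodegeneration-like groups — beta amplitude rising and the exponent
falling with age; reduced beta amplitude, increased exponent and a leftward
alpha shift in the affected group — at magnitudes of one to two
within-group SD under the default recording length.

What the generator does *not* emulate: sensor-level physics and noise,
head geometry and source leakage, non-Gaussian or non-stationary artefacts,
heavy-tailed amplitude distributions, and spatially structured parcel
covariance beyond envelope sharing. Passing validation therefore
establishes the correctness of the estimators under the stated generative
model, not robustness to every property of real recordings.

## Validation suite and problem sizes

The acceptance suite (mirrored by `scripts/acceptance.R`) computes:

* the demographic sex-balance chi-squared from published group sizes and
  male percentages (exact reproduction of the printed statistic and df);
* aperiodic exponent recovery at χ ∈ {0.5, 1, 2} from 300 s pure-aperiodic
  recordings (mean absolute error below 0.05);
* centre-of-energy identities (symmetric peak at its centre ± 0.25 Hz;
  leftward shift strictly decreases CoE);
* AEC against the directly correlated constructed envelopes (± 0.05) and
  exact invariance to parcel rescaling;
* family-wise error calibration under a global null — 200 replicate
  datasets of 10 parcels × 2 metrics, 60 subjects, 500 permutations —
  with the rejection rate required to lie in [0.02, 0.09];
* recovery of injected effects over 20 replicate cohorts of 30 subjects
  per group, 10 parcels, 60 s recordings: a −0.06 log10 group effect on
  beta amplitude (≈ 1.5 within-group SD) must yield correctly signed,
  FWE-significant beta copes in ≥ 90% of replicates, and a +0.004/yr age
  effect must be recovered within 2 SE of its analytic projection in
  ≥ 95%;
* the Welch/Parseval unit-integral identity.

These sizes were chosen as the smallest cohorts at which the inferential
claims are meaningful (≈ 30 per group is also the scale of the patient
groups such studies recruit); the statistical thresholds are properties of
the procedures, not tuned constants.

## Known limitations

Knee-mode aperiodic fitting, time-resolved (dynamic) spectra and
connectivity, phase-based coupling, leakage correction and cluster-based
or TFCE corrections are out of scope. The bad-segment detector assumes
variance artefacts; flat or phase-distorted artefacts pass through. CoE is
undefined (missing) for spectra with no detected periodic power, and peak
imputation assumes missingness at random given parcel and band, which group
differences in detectability can violate — the missing-peak counts are the
diagnostic for that situation.
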