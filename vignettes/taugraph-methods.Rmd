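---
title: "Methods: EEG network measures, tau PET quantification, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG network measures, tau PET quantification, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taugraph)
```

# The scientific question

In the asymptomatic stage of Alzheimer's disease, tau aggregation in the
medial temporal cortex marks the transition from stable amyloid positivity
toward clinical symptoms. `taugraph` implements a pipeline for asking whether
that regional tau burden is reflected in *global functional-network*
properties of the resting-state EEG: the weighted global clustering
coefficient `C` (network segregation) and the characteristic path length `L`
(network integration), computed in sensor space from alpha-band (8–13 Hz)
weighted Phase Lag Index (wPLI) connectivity with eyes closed.

The pipeline has six stages: a synthetic-cohort generator, EEG signal
conditioning, wPLI connectivity, graph metrics, region-level PET arithmetic,
and the statistical battery. Because the kind of patient data this design
needs (high-density EEG plus dynamic tau PET plus amyloid PET plus
neuropsychology) is not publicly deposited, the generator is a first-class,
tested component: every downstream stage is exercised end-to-end on cohorts
whose ground truth is known.

# EEG preprocessing

The conditioning chain is deterministic and fixed in order:

1. **Down-sampling** to the analysis rate (256 Hz by convention) with
   polyphase anti-aliased resampling (`resample_recording()`, backed by
   `signal::resample`). Upsampling is refused.
2. **Average re-reference** (`rereference_average()`): the instantaneous
   mean over electrodes is subtracted; output channel means are exactly zero.
3. **Broadband band-pass** 0.5–40 Hz (`bandpass()`): zero-phase
   forward–backward Butterworth, order 4 per pass. Zero phase is mandatory
   because phase-based connectivity follows; a windowed-sinc FIR alternative
   (also zero-phase) is available via `type = "fir"`. Because re-referencing
   and filtering are both linear, their order is immaterial (asserted to
   1e-8 in the tests); the order above is the one logged.
4. **Epoching** (`epoch_recording()`): the first 60 s are discarded
   (accommodation), then consecutive non-overlapping 20 s epochs are cut and
   any remainder is dropped. A 300 s condition therefore yields exactly
   12 epochs (240 s).
5. **Welch spectra** (`welch_psd()`): Hamming-tapered 500 ms segments with
   50 % overlap, averaged over segments and epochs; 2 Hz resolution;
   one-sided PSD in µV²/Hz.

Artifact handling (bad channels, ICA) is an explicit no-op hook
(`artifact_fun` in `recording_to_adjacency()`): synthetic recordings are
artifact-free, and cleaning of real data is expected upstream of this
package.

Numerical choices worth stating:

* The Welch overlap (50 %) is the conventional default; it is configurable.
* `relative_band_power()` integrates the PSD with the rectangle rule (sum of
  bins × bin width). A trapezoid would half-weight the band's edge bins,
  which carry taper leakage from in-band activity: a pure on-bin tone then
  reads as only ~86 % "in band", which misrepresents the physics.
* The band-pass defaults to order 4 because higher-order transfer-function
  Butterworth designs with a 0.5 Hz edge at 256 Hz are numerically unstable
  under `filtfilt`; the FIR path is the right tool when stronger stop-band
  attenuation is needed.
* Forward–backward filtering pads each edge with an even reflection tapered
  to zero by a raised-cosine ramp (at least 384 samples where the data
  allow): the outer pad edges then match the filter's zero initial state,
  so the slowly settling near-DC high-pass poles are not excited and no
  start-up transient rings into the retained samples.

# wPLI connectivity

For each epoch, Welch cross-spectra are computed from the same tapered
segments (79 segments per 20 s epoch). For a channel pair \(i,j\) and
frequency bin \(f\),

\[
\mathrm{wPLI}_{ij}(f) =
\frac{\left|\sum_k \mathrm{Im}\, X_{ij,k}(f)\right|}
     {\sum_k \left|\mathrm{Im}\, X_{ij,k}(f)\right|},
\qquad X_{ij,k} = S_{i,k} \overline{S_{j,k}},
\]

with \(k\) over Welch segments, and the convention \(0/0 = 0\) (identical,
i.e. zero-lag, signals are *not* lag-coupled). The band value is the
unweighted mean over bins whose centres lie in the closed band interval (at
2 Hz resolution, alpha 8–13 Hz selects bins 8, 10, 12 — fixed here so
results are bit-reproducible). Per-epoch matrices are averaged element-wise
into the subject adjacency (`subject_adjacency()`). Entries are nonnegative
by construction, matching the absolute-value adjacency convention; the plain
estimator is the default and a debiased squared variant sits behind
`debias = TRUE`.

The expectation is taken over segments *within* an epoch and then averaged
over epochs; pooling segments across epochs is a reasonable alternative that
the estimator interface does not currently expose. wPLI's defining property
— blindness to zero-lag (volume-conduction-like) mixing — is verified by a
property test using the generator's instantaneous-mixing switch, against a
Monte-Carlo null.

Cross-spectra are held in factored form (the per-segment channel spectra);
pair cross-spectra are materialised on demand. This is exact and avoids a
channels² × bins × segments × epochs array (~0.5 GB at 128 channels).

# Graph measures

Both measures operate on the symmetric nonnegative wPLI adjacency with zero
diagonal; wPLI graphs are dense, and no thresholding is applied (a threshold
option exists but defaults off).

**Global clustering coefficient** (`clustering_coefficient_global()`):
Onnela's geometric-mean-of-triangles variant on max-normalised weights
\(\hat w = w / \max w\),

\[
c_i = \frac{\sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}}{k_i(k_i-1)},
\qquad C = \frac{1}{n}\sum_i c_i ,
\]

with \(k_i\) the count of nonzero-weight neighbours and \(c_i = 0\) when
\(k_i < 2\) — the Brain Connectivity Toolbox convention. The
max-normalisation makes `C` exactly invariant to uniform weight scaling
(asserted in the tests). The Barrat variant is available behind a flag.

**Characteristic path length** (`characteristic_path_length()`): edge
lengths \(\ell = 1/w\) (a `1 - w` alternative is exposed), Dijkstra shortest
paths per source via `igraph::distances`, and the mean over ordered pairs
with finite distance; unreachable pairs are excluded and counted (they
cannot occur on dense wPLI graphs, but degenerate inputs need a rule).
Under \(w \mapsto \lambda w\), `L` scales as \(1/\lambda\) — exactly.

Electrode-subset variants (`subset_metrics()`) restrict the adjacency to a
reduced 10-10 cap (64/32/24 labels, shipped as editable text files, each a
strict subset of the 128-channel 10-5 montage) and recompute both measures.
Hospital-cap label sets vary by site; the shipped defaults are standard
10-10 reductions and explicitly user-replaceable.

# PET quantification

* **Centiloid conversion** (`suvr_to_centiloid()`): exact tracer-specific
  linear maps for 11C-PiB (CL = 132.53·SUVR − 147.64), 18F-NAV4694
  (CL = 107.78·SUVR − 114.71) and 18F-florbetaben (CL = 147·SUVR − 166.5).
* **Amyloid positivity**: CL > 23.5 (the pathologically validated cut-off);
  the boundary itself classifies negative. The tie rule is a documented
  choice — CL is continuous, so ties are measure-zero.
* **VOI aggregation** (`aggregate_voi()`): voxel-count-weighted mean of
  member-region DVRs. The early metaVOI comprises entorhinal, perirhinal,
  caudal+rostral hippocampus, lateral+medial parahippocampus and fusiform
  cortex; the neocortical VOI comprises inferior/lateral temporal and
  inferior/medial parietal cortex. Shipped voxel counts are plausible
  relative sizes for synthetic work; real counts are user-supplied.
* **Tau positivity** (`tau_positivity_threshold()`): mean + 1 sample SD
  (n−1) of the amyloid-negative cognitively unimpaired reference sample,
  with the reference n recorded. A CU− reference summarised as 0.86 ± 0.06
  gives a threshold of 0.92; thresholds quoted to a third decimal (such as
  0.921) are not exactly recoverable from rounded summary statistics and
  are treated as approximate anchors only.

# Statistical battery

`run_full_analysis()` mirrors a primary/secondary/tertiary design:

* **Primary**: OLS of each graph measure on early-metaVOI tau DVR + age +
  sex + APOE-ε4 (sex coded 0 = M / 1 = F, APOE 0 = noncarrier /
  1 = carrier — stated because β signs depend on the coding), with
  per-coefficient t-tests and the overall F-test; Kruskal–Wallis with
  tie-corrected Dunn post hoc z-tests (Holm-adjusted by default) across the
  three groups.
* **Gatekeeping**: subgroup correlations and per-region analyses run *only*
  when the primary tau term is significant. Within the gate, subgroup
  associations use Spearman correlations (the subgroups are small and
  heteroscedastic) with Fisher-z 95 % CIs, plus partial variants adjusted
  for age and sex: all variables are rank-transformed, ranks are
  residualised on covariate ranks by least squares, and the Pearson
  correlation of residuals is reported with t-tests on n−k−2 df and
  Fisher-z CIs with variance 1/(n−k−3). Per-region CU+ correlations carry a
  Benjamini–Hochberg column within each outcome family.
* **Amyloid contribution**: the same regression with Centiloid + age + sex,
  restricted to the cognitively unimpaired.
* **Tau-positivity split**: threshold from the CU− reference, then a
  normality-gated two-group comparison (Shapiro–Wilk at α = 0.05 on each
  group; both normal → Welch t, otherwise Wilcoxon rank-sum; the branch is
  reported).
* **Cognition**: minres factor analysis of the 10 neuropsychological scores
  with varimax rotation, refused unless Bartlett's sphericity p < 0.05 and
  KMO ≥ 0.6; fit is summarised by the empirical chi-square (n × sum of
  squared off-diagonal residual correlations), RMSEA, and CFI against the
  independence model. Thurstone regression scores (\(W = R^{-1}\Lambda\))
  are correlated with tau and the graph measures, partial for age, sex and
  education. Minres extraction optimises uniquenesses by L-BFGS-B on the
  off-diagonal residual sum of squares; the ML solution (`stats::factanal`)
  is used as an independent cross-check in the tests, never as the
  implementation.

When the full tidy feature table is supplied, the primary regressions are
additionally rerun for every other stratum present — the theta band
(4–8 Hz), the eyes-open condition, and each reduced electrode set — as an
exploratory robustness block (`strata` in the result bundle).

Degenerate inputs (constant columns, empty groups, singular designs) skip
the affected stage with a logged reason rather than failing the run.

# The synthetic cohort

`simulate_cohort()` emulates the joint data structure the analysis assumes.
A latent per-subject severity \(s \in [0,1]\) drives everything; group
ranges are CU− [0, 0.15], CU+ [0.05, 0.45], prodromal [0.45, 0.95] —
deliberately overlapping, as biomarker stages do.

**EEG.** All channels share one alpha source: an analytic band-limited
process (carrier drawn in 9–11 Hz, ±1.75 Hz bandwidth; its phase drifts
slowly by construction). Each channel receives it with

* a continuous lag of 1–4 samples (continuous so that no channel pair is
  accidentally zero-lag: integer lags would zero out every equal-lag pair,
  since wPLI is blind to zero-lag coupling),
* a random source-projection phase (propagation/dipole geometry), spreading
  pairwise phase offsets around the circle,
* a coupling gain \(g \cdot (1 + \text{coupling\_slope} \cdot s \cdot a_c)\)
  with channel-specific attenuation factors \(a_c\), and
* slow per-channel phase jitter with standard deviation
  \(\sigma_c = 0.2 + u + 2.0 \cdot s \cdot a_c\) radians, where \(u\) is a
  per-subject half-normal baseline (SD 0.8 rad).

The phase-jitter term carries most of the severity effect on connectivity:
wPLI is amplitude-blind, so a pure gain decline leaves it nearly unchanged
as long as the per-bin SNR stays high — hyposynchrony (loss of phase
locking) is the mechanism a phase-lag measure can see. The heterogeneous
attenuation matters for `C` specifically: a uniform degradation would be
cancelled by the max-normalisation. The per-subject baseline term encodes
the wide severity-independent spread of network measures seen among healthy
amyloid-negative individuals. These parameters were calibrated once so that
the pooled Spearman correlation between early-metaVOI tau and `C` is ≈ −0.4
at study size, and not revisited.

Each channel adds an independent band-limited theta (4–8 Hz) oscillation
whose amplitude grows with severity (the "slowing" shift: theta/alpha ratio
strictly increases in s) and independent 1/f noise (spectral shaping of
white noise). Eyes-open recordings halve the alpha source amplitude — a
plain, flagged choice, not an empirical claim. A `zero_lag_gain` switch
adds a shared *instantaneous* broadband component with channel-specific
gains, used to verify that wPLI (unlike amplitude correlation) does not
inflate under volume-conduction-like mixing.

**Tau.** \(DVR_r = base_r + slope_r\,s + \varepsilon\), with intercepts set
to the emulated design's amyloid-negative group means and slopes to its prodromal−CU−
group deltas per unit severity; the perirhinal slope (0.87) is the largest
(earliest/steepest region) and the config validator enforces that ordering.
Gaussian region noise has SD 0.07.

**Amyloid.** Group-conditional Centiloid draws truncated at the 23.5
cut-off (CU− below, CU+ and prodromal above), converted back to
tracer-specific SUVR so the stored SUVR/tracer columns and the Centiloid
pipeline stay mutually consistent.

**Cognition.** Ten test scores from a 2-factor model (memory;
language/semantic) with unit-bounded loadings; the memory factor declines
with severity, the language factor is independent of it. True factor scores
are retained in the ground truth for recovery tests.

**Covariates** (age, sex, education, APOE) are drawn from group-matched
distributions but independent of severity by default, so the tau effect is
isolated; a `confound_covariates` switch couples age to severity for
sensitivity work.

Everything is seeded: the cohort seed fixes per-subject sub-seeds, and
identical configs give byte-identical cohorts.

## What the generator does *not* emulate

No scalp geometry or electrode positions, no ocular/cardiac artifacts (the
ICA stage is a no-op hook), no amplifier differences, no non-stationarity
beyond the slow phase drift, no spatially structured tau topographies beyond
the region-level linear model, and no mechanistic link from tau to specific
anatomical connections — the tau–network association is imposed through the
shared severity variable. Passing tests therefore demonstrate that the
*pipeline* recovers structure it is designed to measure, under realistic
noise; they say nothing about whether real cortex behaves this way. Absolute
wPLI levels at low severity run higher than typical empirical sensor-space
values; directions and relative group contrasts, not absolute levels, are
the emulation target.

# Problem sizes and reproducibility

The Monte-Carlo suites use reduced, documented problem sizes chosen to keep
a full run on one CPU comfortable while leaving the study design (group
sizes 37/14/15, default effect sizes) untouched:

* direction recovery: 20 cohorts of n = 66, 16 channels, 100 s, 128 Hz;
* type-I error: 500 null cohorts of n = 30, 4 channels, 80 s;
* electrode-subset robustness: one cohort of n = 66 at the full 128-channel
  montage, 100 s;
* `scripts/acceptance.R`: one cohort of n = 66, 32 channels, 140 s.

Wherever channel counts or durations are reduced, the epoching contract
(60 s discard, 20 s epochs) and all estimator settings stay at their
defaults.

# Known limitations

* The Welch segment count within a 20 s epoch (79) fixes the wPLI null
  level (≈ 0.09); shorter epochs raise it.
* Minres extraction assumes a well-conditioned correlation matrix;
  near-singular inputs fall back to a ridge-regularised Thurstone inverse
  with a warning.
* The EDF writer truncates to whole seconds and quantises to 16 bits; it is
  an interchange convenience, not an archival tool.
* Partial Spearman CIs use the Fisher-z approximation; for the smallest
  subgroup (n = 14) these are first-order approximations only, matching
  common practice rather than exact small-sample theory.
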