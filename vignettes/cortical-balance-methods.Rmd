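---
title: "Methods: simulating and measuring cortical balance after sequential bilateral cochlear implantation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring cortical balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cibalance)
```

## The scientific problem

When a child who is deaf in both ears receives a cochlear implant (CI) in
one ear only, the auditory pathways develop under unilateral stimulation:
inputs from the implanted ear are strengthened, and the deprived ear's
representation weakens. If a second implant arrives only after many years,
the question is whether the cortex can re-balance — whether the two ears
come to be weighted equally, whether the normal contralateral dominance of
each auditory cortex is restored, and whether the ipsilateral-suppression
machinery that underlies bilateral integration works for the new ear.

`cibalance` implements the full measurement chain used to study this
longitudinally with auditory-evoked EEG in adolescents implanted
sequentially (first implant in the right ear in early childhood, second in
the left about a decade later): evoked responses to unilateral (CI-1,
CI-2) and bilateral (CI-B) electrical stimulation are recorded repeatedly
over the first year of bilateral hearing, localized to the cortex with an
artifact-suppressing beamformer, reduced to normalized hemispheric balance
indices, and modelled with linear mixed effects over time.

Because raw patient EEG cannot ship with a package, every stage is backed
by a synthetic-data generator with known ground truth, so the whole chain
is testable end to end.

## Cohort and time bins

The packaged cohort table (`inst/extdata/cohort_table1.csv`) holds the 13
participants' demographics: ages at deafness onset and at each
implantation, the inter-implant delay (mean 10.07 years, SD 2.19), and
electrode arrays. `load_cohort()` validates it (ages ordered, printed delay
consistent with the two implant ages to 0.05 years, duplicate participants
rejected, missing electrode arrays kept as explicit `"Not available"`
sentinels) and `summarize_cohort()` reproduces the published summary row
with sample SDs (n − 1).

Recording sessions cluster at roughly 9, 42, 100 and 285 days after
activation of the second implant. The four categorical bins used by every
longitudinal model are bounded at 21, 75 and 135 days — boundaries placed
between the session-day clusters so that each cluster mean ± SD falls
inside its own bin; they are configurable in `assign_time_bin()`. A
participant with two sessions in one bin is flagged by
`flag_duplicate_bins()`, never silently dropped.

## The synthetic recording

`simulate_epochs()` emulates the acquisition protocol: 62 cephalic
channels referenced to the right earlobe, 1000 Hz sampling, 1000 ms epochs
from −200 to 800 ms around 1 Hz stimulus trains. The electrode montage is
an idealized extended 10-20 layout constructed geometrically on the scalp
sphere (`ten_ten_montage()`); no manufacturer montage file is emulated.

**Sources.** Cortical responses are current dipoles in left and right
auditory cortex (±62, −18, 8 mm) with Gaussian-lobe time courses:
a mature P1-N1-P2 complex (lobes at 60, 100, 180 ms; signs +, −, +) for
the long-stimulated first ear, and an immature, larger two-lobed
N(CI)-P(CI) complex (95, 200 ms; −, +) without P1 for the long-deprived
ear — latencies chosen inside the reported first-component bands
(≈94-97 ± 12 ms). Amplitudes are in nA·m; waveforms are exactly zero over
the pre-stimulus baseline by construction.

**Forward model.** An analytic three-shell concentric-sphere head model
(radii 80/85/92 mm, conductivities 0.33/0.0042/0.33 S/m, the usual ≈80:1
scalp:skull ratio) stands in for subject-specific boundary-element models:
it is computable at desk scale with no template downloads, and the
`leadfield` interface would accept a BEM drop-in. The series solution per
spherical-harmonic degree is solved with shell-normalized radial bases for
conditioning and validated against the closed-form homogeneous-sphere
potential to machine precision. Lead fields are reported in µV per nA·m
and average-referenced to match the processed data.

**Implant artifact.** Stimuli are 36 ms trains of charge-balanced biphasic
pulses at 250 pulses/s. At the scalp the artifact is modelled as a rank-1
topography (Gaussian falloff from a site behind the stimulated ear) times
a waveform: the alternating pulse train plus a sustained intra-train
pedestal (default 40% of the 500 µV peak). The pedestal matters: the
radio-frequency pulse alternation is essentially eliminated by the 1-30 Hz
analysis band, and it is the sustained shift — a standard feature of
scalp-recorded electrical-stimulation artifact — that survives filtering
and makes artifact suppression necessary at all. The scalp amplitude is a
free parameter, not a claim about any particular device.

**Noise.** Independent Gaussian sensor noise (default SD 12 µV per sample,
of which roughly a quarter survives the 1-30 Hz band — in the range of
band-limited background EEG). Spatially correlated brain noise is *not*
simulated; consequences are discussed under Limitations.

**Longitudinal ground truth.** `simulate_longitudinal_cohort()` plants the
study's qualitative structure via `effect_model()`:

* baseline cortical representation of input depends linearly on
  inter-implant delay (default intercept 10%, slope −5 %/year, so a
  10-year delay gives ≈ −40%, i.e. dominance of the newly implanted ear,
  with a between-participant SD of 8%);
* a fixed leftward hemispheric lateralization (−20%) for all conditions;
* second-ear and bilateral response amplitudes decay exponentially across
  sessions toward a 60% plateau while first-ear responses stay constant;
* bilateral enhancement is present in the right auditory cortex (+0.25 of
  the base amplitude) and absent/negative in the left (−0.15).

The defaults were chosen once to mirror the reported effect directions and
magnitudes (baseline representation medians ≈ −34 to −49%, lateralization
EMMs −7 to −25%); they are parameters of the generator, not fitted values.
Per-cell epoch sets are generated on demand from per-cell seeds, and a
ground-truth table (amplitudes and the indices they imply) always
accompanies the generator, so recovery can be scored.

Speech scores are binomial percent-correct draws
(`simulate_speech_scores()`), 50 words per list by default.

## Sensor-space processing

`preprocess_epochs()` applies the fixed order filter → reject → bad
channels → common average reference → average:

* **Filtering.** 4th-order Butterworth, 1-30 Hz, zero phase. The default
  realization applies the filter's magnitude-squared response in the
  frequency domain to each channel's *concatenated* trial record: at a
  1 Hz stimulus rate with 1000 ms epochs the epochs tile the continuous
  recording, so filtering them as one record is both physically correct
  and free of per-epoch edge transients (which would otherwise make the
  noise variance non-stationary across the epoch and bias the pseudo-Z
  statistics). A per-trial `signal::filtfilt()` path is available for
  comparison.
* **Rejection.** An epoch is dropped iff any included channel exceeds
  ±100 µV anywhere in 100-800 ms; the log records each decision with the
  offending channel, extremum and latency, and reproduces the decision by
  itself.
* **Bad channels.** Flat (variance below a floor) or noisy (variance above
  10× the median channel variance) channels are flagged; the variance is
  assessed at 100-800 ms so the stimulus artifact, which legitimately
  dominates implant-side channels early in the epoch, is not mistaken for
  channel noise. The visual ocular screening of the original protocol is
  replaced by the amplitude rule; no ICA/regression correction is
  attempted.
* **Averaging** warns below 100 accepted epochs (the protocol minimum).

`global_field_power()` is the across-channel SD per sample (the spatial
RMS under the average reference). `find_first_component()` finds the
earliest GFP local maximum after the artifact (search window 36-250 ms)
that exceeds the baseline GFP mean + 2 SD *and* half the window maximum —
the latter is the automated surrogate for "visually identifiable", and
without it noise ripples on the rising flank of the component win. Peaks
tie-break to the earliest latency. `peak_topography()` averages a 5 ms
window centered on the component.

## Source imaging

`compute_leadfield()` evaluates the forward model on a regular volumetric
grid inside the brain shell (default 10 mm ≈ 1900 voxels; 5 mm approaches
dense whole-brain scans at ≈ 8× the voxel count). The beamformer
(`tracs_weights()`) is a linearly constrained minimum-variance spatial
filter with time restriction and coherent suppression:

* the **noise covariance** is estimated from single trials inside
  stimulus-free windows — the pre-stimulus baseline and the late epoch
  (450-800 ms, after the slowest modelled component has decayed) — with
  5% diagonal loading. Restricting the covariance away from both the
  artifact *and* the response matters: an adaptive filter trained on data
  containing a strong evoked response cancels the very signal it
  measures, both against its own lead-field discretization mismatch and
  against the perfectly coherent source in the opposite hemisphere;
  during development this produced pseudo-Z values that saturated
  independently of source amplitude, which would destroy every amplitude
  ratio the balance indices are built from;
* the artifact's spatial subspace (top-k left singular vectors of the
  evoked 0-36 ms segment, k = 1 per stimulated side) enters as exact null
  constraints, implemented by solving in the orthogonal complement — the
  artifact gain of every filter is zero to machine precision regardless
  of the generator's true artifact rank;
* per voxel the **max-SNR orientation** is used: the top generalized
  eigenvector pairing the evoked signal covariance (36-400 ms) with the
  noise covariance in the projected space;
* **coherent-source suppression** runs in two passes: a first pass with
  artifact nulls only locates each auditory ROI's peak voxel and
  orientation; the second pass images each hemisphere with the
  contralateral peak's single lead-field column added to the nulls. (A
  rank-3 basis of the whole contralateral box was rejected: those lead
  fields project ~70% of the opposite hemisphere's lead field and crush
  its pseudo-Z through the added noise gain; the single column costs only
  a few percent.)

The artifact subspace is also projected out of the evoked response before
component detection, since the band-pass smears some artifact energy past
36 ms and would otherwise capture the GFP peak search.

**Pseudo-Z.** Each voxel's evoked activity is reduced to a pseudo-Z over
a 5 ms signal window centered on the detected component (mirroring the
surface convention). The production form is the *vector* pseudo-Z
`sqrt(m' S⁻¹ m)`: `m` is the 3-D unit-gain dipole-moment estimate
averaged over the window and `S` the trial-to-trial covariance of that
window mean — exactly the maximum over dipole orientations of
`|window mean| / SE(window mean)`, in closed form (a per-voxel
Hotelling-type statistic). Everything in the statistic is strictly
window-local, which is what makes the omnibus honest: signal and null
windows undergo the identical construction, so nothing can favor the
signal window. This form is the product of an explicit calibration
campaign; three simpler realizations each failed a pure-noise
false-positive audit for an identifiable reason and were replaced:

* the literal temporal SD of the 120 ms averaged baseline has ≈ 4
  effective samples under 1-30 Hz autocorrelation, so max-over-voxels
  statistics ride on whichever voxel's SD is underestimated by chance;
* a data-chosen fixed "optimal orientation" is aligned to the evoked's
  realized noise and inflates signal-window statistics ≈ 10% relative to
  any null that does not undergo the same selection (false-positive rates
  0.13-0.27);
* a noise scale estimated from the baseline segment alone inherits
  in-sample variance shrinkage of the adaptive weights and the filtered
  record's variance profile, leaving ≈ 5% positional asymmetry
  (rate 0.085).

The window-local trial covariance has only `n_trials − 1` degrees of
freedom, so max-over-voxels peak *ranking* benefits from trial counts
nearer the acquisition target (≥ 40 in the localization suites);
shrinking the covariance toward a fixed spatial expectation was tried and
rejected because any departure from strict window locality measurably
degraded the false-positive calibration.

The paper-level scalar definition (fixed filters, temporal baseline SD)
remains available when no trials are supplied and carries the worked
ratio-identity and scale-invariance examples; the package's realization
of "the SD of the pre-stimulus baseline" is the trial-to-trial SE
evaluated at the baseline/null windows.

**Omnibus threshold.** The statistical threshold of baseline brain
activity is a max-statistic resampling test: windows of signal-window
length are drawn at random from response-free segments — the pre-stimulus
baseline *and* the late epoch (450-800 ms, after the slowest modelled
component has decayed) — each is reduced to the same window-local vector
pseudo-Z per voxel, and the threshold is the 95th percentile of the
max-over-voxels statistic. Two distant segments are used because
band-limited background activity is correlated over tens of
milliseconds, so windows confined to the 120 ms baseline share its
realized slow level and understate how far the distant signal window can
stray. Residual late activity in real data inflates the threshold, i.e.
errs conservative; the response's 1 Hz high-pass undershoot contributes
only marginally at the achieved signal-to-noise ratios. This realization
calibrates to ≈ 0.06 at α = 0.05 over 200 pure-noise simulations, with
thresholds independent of the planted response amplitude. The omnibus
value is subtracted from every voxel (`apply_omnibus()`); positive
corrected values mark significant activation.

**ROI peaks.** `extract_roi_peak()` takes the largest corrected pseudo-Z
in each auditory box (left x ≤ −55, right x ≥ 55; −35 ≤ y ≤ 5;
−10 ≤ z ≤ 20, MNI mm, RAS order), tie-breaking to the lowest voxel index;
a peak is significant iff its corrected value is positive.

## Balance indices

With subthreshold peaks set to exactly zero
(`apply_subthreshold_rule()` — representing the absence of a significant
response), the indices are:

* **Cortical lateralization (%)** = (R − L) / (R + L) × 100 across the two
  auditory cortices per condition; negative = left-hemisphere dominant.
* **Cortical representation (%)** = (right ear − left ear) /
  (right ear + left ear) × 100 within one hemisphere; negative = dominance
  of the (left, newly implanted) second ear. Undefined for bilateral
  stimulation.
* **Bilateral enhancement** = bilateral − ipsilateral-ear unilateral
  response per hemisphere (pseudo-Z difference; positive is the typical
  ipsilateral enhancement).
* **Bilateral speech benefit** = bilateral − opposite-ear score
  (percentage points), and normalized by the attainable headroom
  `(bilateral − opposite) / (100 − opposite) × 100`.

When both hemisphere peaks are zero the ratio indices are 0/0: the package
returns an explicit `NA` rather than fabricating symmetry with 0, and such
rows are dropped listwise (with counts logged) in the models. When the
opposite ear scores 100%, normalized benefit has no headroom and is `NA`.

## Mixed models

`fit_lmm()` wraps REML `lmerTest` fits with sum-to-zero factor coding, a
participant random intercept, and the two standing covariates (age at
first implantation, inter-implant delay). The four standard models
(`fit_standard_models()`) are: corrected pseudo-Z ~
time × condition × hemisphere; lateralization ~ time × condition;
representation ~ time × hemisphere; enhancement ~ time × hemisphere.
`anova_table()` reports Type-III F tests with Satterthwaite denominator
df; `estimated_marginal_means()` averages over the other factors at
covariate means (the covariate-centering choice is recorded with the
table); `pairwise_contrasts()` applies the Tukey family-wise adjustment
with Kenward-Roger df (Satterthwaite fallback), and the df method label
travels with every table. Single-level factors are dropped with a warning
rather than failing the fit; singular fits are flagged, not silently
zeroed. `fit_predictor_model()` provides the auxiliary OLS models
(e.g. baseline lateralization predicting later bilateral speech
perception) with marginal F tests from single-term deletions.

## The pipeline and problem sizes

`run_pipeline()` chains everything: cohort → simulate → preprocess →
localize → indices → models, writing peak tables, index tables
(wide and tidy long), model summaries (JSON), a run log with the seed and
all decided defaults, and optional trajectory figures with EMM overlays.
Identical seeds give byte-identical index tables.

Default problem sizes are desk-scale choices: 60 epochs per simulated
condition in the pipeline (the acquisition target was ≥100, typically
≈200 — `sim_config()`'s own default), a 10 mm grid, 300 sign-flip null
statistics for the omnibus. The package's verification suites use reduced
sizes chosen to keep each property measurable: localization oracles on a
20 mm grid with near-noiseless trials; omnibus calibration with 200
pure-noise runs; end-to-end slope recovery on baseline sessions with the
two unilateral conditions on a 20 mm grid, using 24 epochs with the
sensor noise scaled so the evoked-average noise level (0.86 µV) matches a
full-length ≈200-epoch session; the LMM-level power and coverage
properties at 13 × 4 cells matching the cohort's shape.

## Numerical choices and degenerate inputs

* Zero-phase filtering preserves latencies; the frequency-domain
  realization equals forward-backward filtering up to edge handling.
* The beamformer flags (rather than fails on) voxels whose constrained
  system is degenerate; the lead field excludes voxels within 2 mm of the
  brain-shell boundary where the series loses accuracy.
* Pseudo-Z errors out on a zero baseline SD naming the voxel; the omnibus
  quantile at α = 1 degenerates to the minimum resampled maximum.
* ROI and GFP ties break deterministically (lowest voxel index, earliest
  latency).
* A dipole at the sphere center has no defined radial direction; the
  forward solution is continuous there (only the degree-1 term survives)
  and is exercised by a continuity test. A central dipole is *not* silent
  in EEG — only its magnetic counterpart is.

## Limitations

* The spherical head model ignores real anatomy; localization accuracy
  statements (median error ≤ one grid spacing) hold within the model's own
  geometry (an inverse-crime setting) and say nothing about template or
  individual-MRI accuracy.
* Sensor noise is white; real EEG background is spatially and temporally
  correlated brain activity, against which beamformer depth bias and the
  omnibus calibration will differ.
* The generator plants exactly two auditory sources (plus an optional
  frontal source for qualitative experiments); real responses recruit
  distributed generators.
* Ocular artifacts are not modelled; the rejection rule is tested with
  injected square pulses instead.
* Passing the packaged end-to-end recovery suites therefore demonstrates
  the correctness and calibration of the measurement chain under its own
  stated assumptions, not clinical reproducibility on recorded EEG.
* Ingestion of continuous EDF/BrainVision recordings is out of scope in
  this build; the analysis operates on the package's native epoch
  container, and deposited-data reanalysis would enter through a reader
  producing `epoch_set` objects.
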