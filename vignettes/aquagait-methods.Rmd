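---
title: "Methods: synchronous sEMG and axial kinematics for treadmill and water-treadmill gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synchronous sEMG and axial kinematics for treadmill and water-treadmill gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquagait)
```

## What the package computes

`aquagait` compares equine walking conditions — overground (OG), dry
treadmill at two belt speeds (TM, 1.7 m/s; TM80, 1.4 m/s) and water
treadmill (WT80, 1.4 m/s at mid-metatarsal depth) — from three synchronous
data streams: surface EMG of hindlimb and epaxial muscles (2000 Hz), the
vertical acceleration of a sacral IMU (2000 Hz), and optical marker
trajectories of the axial skeleton and pelvis (200 Hz). Overground trials
carry no optical data; kinematic analyses therefore span the treadmill
conditions only, while sEMG analyses span all four conditions.

The analysis chain is:

1. **Stride segmentation.** Sacral vertical acceleration is double-integrated
   to vertical displacement; right-hind impacts are its displacement minima.
2. **Kinematics.** Rigid back and pelvis segments give thoracolumbar
   flexion/extension and lateral bending, and pelvic roll, pitch and yaw.
3. **sEMG conditioning.** Linear envelopes, per-stride peak amplitudes (PA),
   robust outlier-stride removal, and amplitude normalisation to a reference
   voluntary contraction (RVC) defined per muscle as the maximum PA across
   retained overground strides.
4. **Stride assembly.** Every retained stride is time-normalised to 101
   nodes (0–100% stride) and stride counts are equalised across conditions.
5. **Inference.** One-dimensional statistical parametric mapping (SPM):
   paired t-fields over the 101-node domain, random-field-theory (RFT)
   critical thresholds, and cluster-level p-values, with a sign-flip
   permutation oracle for validation.

Because the study design rests on a single subject, all SPM variance is
intra-subject (stride-to-stride), and strides are the experimental units.

## The synthetic-data generator

Single-subject sessions of this kind are rarely shared publicly, so the
package ships a generator (`generate_session()`) that emulates the
acquisition with known ground truth; every downstream stage is validated by
recovery against that truth.

* **Stride timing.** Stride durations are i.i.d. lognormal (median 1.10 s
  for OG/TM, 1.20 s for TM80, 1.25 s for WT80; CV 2%). Walk strides of
  1.1–1.3 s are typical for horses at these belt speeds, and the slight
  lengthening with water reflects the prolonged swing reported for water
  treadmill work. The stride phase through time is a C1 cubic Hermite
  through the impact times, so the phase rate is continuous across strides
  and the prescribed displacement has a continuous second derivative —
  without this the generated acceleration could not satisfy the
  double-integration consistency check below.
* **Sacral displacement and IMU.** TS vertical displacement is
  `-A cos(4πφ) - εA cos(2πφ)` with half-amplitude `A = 15` mm (two
  oscillations per stride, one minimum per hindlimb impact) and asymmetry
  `ε = 0.15` deepening the right-hind minimum so limb side is detectable
  from a single midline sensor. The IMU channel is the exact second time
  derivative of this curve plus white noise (SD 0.3 m/s²), a constant bias
  (0.1 m/s²) and a slow sinusoidal drift (0.2 m/s² at 0.03 Hz). Numerically
  integrating the noise-free acceleration twice recovers the displacement to
  under 0.1 mm RMS.
* **Markers.** Rigid cranial (T5–L1), caudal (L1–TS) and pelvic segments are
  placed each frame at prescribed angle waveforms (sums of the first two
  stride harmonics, amplitudes 3–6°, typical of walking back and pelvis
  motion) and marker positions are read off the segments, plus isotropic
  Gaussian noise (default SD 0.5 mm, a typical optical residual). The
  placement inverts the package's own angle definitions, so noise-free
  recovery is exact up to second-order Cardan coupling (≪ 0.5°).
* **sEMG.** Each channel is band-limited (20–450 Hz) Gaussian noise — the
  typical surface-EMG bandwidth — amplitude-modulated by a per-muscle burst
  profile (circular Gaussian bursts on the stride cycle), plus a DC offset
  and a sub-20 Hz motion-artefact tone at step frequency. A deterministic
  150 Hz sine carrier is available for envelope-recovery tests. The default
  "study replication" profiles (`study_effects()`) encode the reported
  contrasts qualitatively: a mid-stance (10–40% stride) biceps femoris and
  gluteus medius burst appearing on the treadmill and strongest in water;
  delayed late-swing bursts in water; reduced tensor fasciae latae
  amplitude; and a longissimus pattern that becomes biphasic in water.
  Burst amplitudes are free generator parameters, not claims about any real
  horse, and no acceptance check depends on their values.

What the generator deliberately does **not** model: water drag forces,
sensor-to-skin movement artefacts of underwater pouches, inter-stream clock
drift (the hardware trigger is modelled as exact simultaneity), forelimb
signals, and limb-joint kinematics. Passing tests therefore demonstrate
that the *processing chain* is correct and calibrated, not that real
water-treadmill sEMG is this clean.

## Signal-processing choices

All filters are Butterworth, 4th order by design, applied forward–backward
(zero phase) because burst and cluster *timing* across conditions is the
scientific object; the bidirectional pass doubles the effective attenuation.
`signal::filtfilt` starts from zero initial conditions, so `butter_filter()`
pads with an odd reflection of 10/cutoff seconds at each end; at the lowest
cutoff used (≈0.4 Hz) uncorrected startup transients would otherwise corrupt
the first and last two strides.

* **Displacement:** accelerometer-mean removal, trapezoidal integration,
  mean removal, second integration, mean removal, adaptive high-pass at
  0.5 × stride frequency, 30 Hz low-pass. The 0.5 fraction passes the stride
  fundamental and harmonics while removing integration drift. The initial
  mean removal is needed so a constant sensor bias (gravity calibration
  error) does not survive integration as a quadratic trend.
* **Stride frequency** is estimated from the autocorrelation peak in the
  0.3–1.5 Hz band (lags 0.67–3.3 s). The band's upper edge excludes the
  half-stride *step* lag for strides up to ~1.3 s, and the left/right
  asymmetry makes the stride lag dominate where both fall in band. A peak
  below 0.25 autocorrelation is rejected with advice to supply the
  frequency manually.
* **Impact detection:** all displacement minima separated by at least
  0.35 stride periods (plateau minima resolve to their midpoint), two stride
  periods trimmed at each end for residual transients, alternate minima
  split into two classes, and the class with the deeper mean minimum taken
  as right hind. A single midline sensor cannot encode side; the deeper-
  minimum rule matches the generator's asymmetry and is user-selectable
  (`side`) for real data. Classes closer than 0.05 mm are flagged ambiguous
  and default to the first class with a warning.
* **Envelopes:** mean removal, 40 Hz high-pass, full-wave rectification,
  10 Hz low-pass; negative ringing from the final low-pass (typically well
  under 1% of samples) is clipped to zero and counted.
* **Outlier strides:** a stride is removed when any muscle's PA lies outside
  median ± 3 scaled MAD for that muscle within the trial (`outlier_k`
  configurable). The robust rule flags < 2% of clean normal data at n ≈ 32.
  Removal is global across signals so sEMG and kinematic stride sets stay
  aligned; whether the original study pooled muscles is unstated, so
  independent flagging with global removal is this package's documented
  rule.

## Kinematic conventions

The laboratory frame is right-handed: x cranial (direction of travel),
y left, z up. Two-point segments (cranial T5→L1, caudal L1→TS, reference
T5→TS) take local x along the segment pointing *cranially*, local z as the
lab-vertical component orthogonal to x, and y = z × x. Pointing x cranially
(rather than caudally) makes every neutral segment frame coincide with the
laboratory axes, so relative rotations are small near neutral and the
Cardan x,y,z decomposition (`cardan_xyz()`) is far from its singularity.
Two-point segments need the lab vertical to complete a frame, which is why
angle invariance holds exactly under translations and heading (vertical-
axis) rotations but not arbitrary tilts of the whole scene; the four-marker
pelvic segment is fully rotation-equivariant.

Thoracolumbar flexion/extension (+ = flexion) and lateral bending
(+ = right) are the Cardan y and z components of the caudal segment
relative to the cranial segment. For the pelvis the package implements the
stated sign conventions *directly*: roll is the elevation of the
tuber-coxae line in the reference (T5–TS) frame (+ when the right tuber
coxae moves ventrally relative to the left), yaw its cranial deviation
(+ when the right tuber coxae moves cranially), and pitch the elevation of
the pelvic long axis (S3 → mid tubera coxarum; + = flexion). These direct
definitions coincide with the Cardan components to second order in the
angles (differences ≪ 0.1° at walking amplitudes) and — unlike any Cardan
decomposition of a frame whose long axis ignores the lateral markers —
exactly negate roll and yaw when the left and right tuber coxae labels are
swapped, which is the property that makes the sign conventions testable.
A virtual marker 20 mm to the left of S3 gives the distal end of the pelvic
segment its mediolateral width, mirroring the four-point segment definition
used by common motion-capture modelling software.

Sagittal angles (thoracolumbar flexion/extension, pelvic pitch) are
normalised to the static square-stance trial so positive values mean
flexion beyond the static posture; lateral bending, roll and yaw cross zero
at anatomical neutral and are not normalised. All angle series are low-pass
filtered at 30 Hz before normalisation. Marker gaps are linearly
interpolated at read time when shorter than 0.1 s (counted and reported);
frames with longer gaps are invalid and any stride containing them is
excluded from the kinematic analysis.

## Stride assembly and equalisation

Each stride is the half-open interval between successive right-hind
impacts, mapped to nearest-sample windows on each stream's clock; the
closing sample (next impact) serves as the 100% endpoint. Interpolation to
the 101-node grid is linear: shape-preserving, no overshoot on envelope
data (a cubic option was considered and rejected for exactly that
overshoot risk). Stride counts are equalised across conditions by removing
strides alternately from the beginning and end of each trial's retained
sequence, beginning first — fixed for determinism, since only "beginning
and end" is stated in the source protocol. The replication default
generates one 60 s trial per condition (~50 strides), comfortably above the
32-stride equalisation target after outlier removal and edge trimming; with
four sEMG conditions and three kinematic conditions this yields the 128 and
96 analysed strides of the replication design.

## SPM inference

For each variable and condition pair, strides are paired by rank order of
occurrence (strides are not physically paired across conditions; an
unpaired pooled-variance option is available via `paired = FALSE`, and the
choice is recorded in the result). At node q the paired t statistic uses
stride-to-stride variance with ν = n − 1 degrees of freedom. Field
smoothness is estimated from the pointwise-standardised residuals'
node-to-node gradients, `FWHM = sqrt(4 log 2 / mean(gradient²))`, clamped
to [1, 3Q] with a flag. The critical threshold t\* solves
`P(max |T| > t*) = α` with the standard one-dimensional
Euler-characteristic expectation (0-dimensional t tail plus EC density ×
resels, resels = (Q−1)/FWHM), α split equally between tails. Supra-
threshold runs become clusters; cluster p-values use the expected-cluster-
extent approximation with extent in resel units, doubled for two-tailed
inference, capped at α, and reported to three decimals with a "<0.001"
floor. Multiple comparisons across the many muscle/angle × condition-pair
maps are *not* corrected, matching the per-comparison α = 0.05 of the
replication design; `alpha` can simply be lowered for a Bonferroni-style
correction.

Numerical edge cases: zero-variance nodes give t = 0 when the mean
difference is zero and are otherwise capped at 10⁶ with a warning;
all-zero residuals make smoothness undefined and raise an error; the
threshold solver brackets (0, 100) to 1e-8.

The sign-flip permutation oracle (`permutation_oracle()`) rebuilds the
max-|t| and max-cluster-extent null distributions (exhaustively when
2ⁿ ≤ n_perm) and is used in the test suite to validate the RFT threshold
(agreement within 5% on smooth nulls) and cluster p-values (within a factor
of two in the median). On 2000 smooth-field nulls (kernel FWHM 15 nodes,
n = 32) the empirical family-wise error of the full RFT chain lies in
[0.03, 0.08] at α = 0.05, and on 300 full end-to-end null sessions the
significant-cluster rate lies in [0.02, 0.10]; an injected mid-stance
envelope increase of ≥3 stride-SDs is recovered as an overlapping
significant cluster in ≥90% of 200 runs. These problem sizes (300/200
Monte-Carlo sessions, 60 s trials, 32 strides per condition) are the
package's chosen test scale; they keep the whole validation suite to a few
minutes while leaving Monte-Carlo bands far wider than their standard
errors.

## Interfaces and limitations

Sessions read and write as plain CSV bundles (`write_session()` /
`read_session()`): one directory per trial with `emg.csv`, `imu.csv`,
`markers.csv` (blank cells = gaps) and `meta.json`, plus `config.yaml` and
ground-truth sidecar CSVs for synthetic sessions. The study configuration
maps one-to-one onto a YAML file. C3D import is not provided: no installed
dependency parses C3D, and the vendor toolchains this package targets
export CSV; this is a known limitation. There is no shell entry point —
`run_study()` plus the examples here are the orchestration interface, and
every processing parameter (high-pass fraction, minima separation, side
selection, outlier multiplier, pairing, tailedness) is a function argument.

```{r example, eval = FALSE}
session <- generate_session(duration = 60, seed = 7)
report <- run_study(session)
glance(report)           # stride totals, comparison counts
tidy(report)             # one row per comparison
autoplot(report$results[["BF|OG vs WT80"]])
```
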