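---
title: "Methods: tailored tACS waveforms, alpha-gamma coupling features, and the nonparametric plan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tailored tACS waveforms, alpha-gamma coupling features, and the nonparametric plan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The experiment this package models

Occipital alpha (7–13 Hz) rhythmically inhibits visual processing; gamma
(>30 Hz) activity carries the stimulus representation and is normally
strongest near alpha troughs, where inhibition is weakest. `pactacs`
implements the computational side of a stimulation experiment built on that
mechanism: transcranial alternating current stimulation (tACS) whose
injection current is a 10 Hz carrier with a short 80 Hz burst riding on a
chosen phase of every alpha cycle — on the troughs (the hypothesized
effective condition), on the peaks (active control), or a brief
ramp-up/ramp-down sham. Around the stimulation sits a dynamic visual acuity
(DVA) task with EEG/EOG recording, a feature pipeline (inter-trial phase
coherence, spectral power, alpha–gamma phase–amplitude coupling), and a
nonparametric statistical plan.

No subject-level data are publicly deposited, so everything here runs on a
synthetic cohort whose generator encodes the structure the analysis assumes.
The package therefore makes two kinds of claims: *design-level* quantities
(trial counts, waveform timing and amplitudes, entrainment phases) that are
exactly reproducible, and *statistical behavior* (calibration, power to
recover the trough-only pattern) that is checked by simulation.

# Waveform synthesis

`stim_params()` fixes the design: a 10 Hz carrier of 1.8 mA peak-to-peak,
three cycles of an 80 Hz burst of 1.2 mA peak-to-peak per alpha period, and
the composite rescaled to 3 mA peak-to-peak; 30 s linear ramps around a
20 min plateau; 2048 Hz sampling.

Two choices deserve explanation because the design as printed does not close
arithmetically:

* **Entrainment interval.** Two interval sets are in circulation for this
  design: a narrow one (peak \(\pi/8\)–\(3\pi/8\), trough
  \(5\pi/8\)–\(7\pi/8\); span \(\pi/4\), i.e. 12.5 ms of a 100 ms alpha
  cycle) and a wide one (peak \(\pi/16\)–\(15\pi/16\), trough
  \(17\pi/16\)–\(31\pi/16\); span \(7\pi/8\), 43.75 ms). A three-cycle 80 Hz
  burst lasts 37.5 ms and cannot fit the narrow slot, and the wide intervals
  are exactly centered on the carrier extrema under the sine convention
  (peak at \(\pi/2\), trough at \(3\pi/2\)), so the wide set is the default
  (`intervals = "discussion"`). The narrow set remains selectable for
  sensitivity checks with shorter bursts; the constructor refuses
  combinations the slot cannot hold.
* **Amplitude semantics.** 1.8 mA and 1.2 mA are treated as component
  peak-to-peak amplitudes, and the composed plateau is rescaled so its
  sampled peak-to-peak is exactly 3 mA, preserving the 1.8:1.2 ratio. This
  is the only reading consistent with a stated 3 mA composite; the raw
  superposition reaches only ≈2.35 mA peak-to-peak.

The burst carries a Hann taper (no envelope is prescribed anywhere; a taper
avoids spectral splatter and splice discontinuities) and recurs once per
alpha cycle, every cycle. The composite is evaluated analytically in
continuous time, so no tiling error arises when the sampling rate is not a
multiple of the alpha frequency; the rescale factor is measured on the
actual sampling grid over one full second (all distinct sample phases), which
is why the plateau peak-to-peak is exact to machine precision. Ramps are
linear; sham is a pure 10 Hz sinusoid under a triangular envelope reaching
3 mA peak-to-peak at its apex, active for 60 s, then zero.

`verify_entrainment()` checks the construction independently: band-pass the
plateau at 7–13 Hz for instantaneous phase (sine convention), at 70–90 Hz
for the amplitude envelope, and compute the envelope-weighted circular mean
phase and mean resultant length. Both verum conditions recover their
interval midpoint within \(\pm\pi/8\).

# Task and behavior

`build_schedule()` enumerates the full 6 (speed: 200–700 deg/s) × 2
(direction) × 4 (gap) × 3 (MAR size) factorial once — 144 trials — and
shuffles it under a seed; ISIs are uniform on 1.5–2.5 s. The factorial is
shuffled without replacement: the trial count equals the number of
combinations, which settles the otherwise ambiguous "random" ordering.
Stimulus rendering (240 Hz display, 70 cm distance, ±10° sweep) is metadata
only; the analysis consumes factors and correctness. Chance level for the
4-alternative forced choice is 25%, and `screen_exclusions()` flags a
subject's size-specific analyses when that size stays below chance in all
three sessions of one condition.

Synthetic responses follow a guessing-floored logistic model
\(P(\text{correct}) = 0.25 + 0.75\,\sigma(a_{\text{size}} - b\,v +
u_{\text{subj}} + \delta_{c,s})\) with intercepts \(a = (-0.5, 0.5, 1.3)\)
for 3/4/5 MAR, speed slope \(b = 0.002\) per deg/s, subject intercepts
\(u \sim N(0, 0.4)\), and a condition × session log-odds shift \(\delta\).
Defaults put pre-session accuracies near 0.40/0.55/0.70 across sizes —
plausible mid-range DVA performance with a clear size gradient. Effects
enter as a shift common to all sizes; sizes differ by intercept only (the
simplest model with size-graded accuracy).

# Synthetic EEG and EOG

`gen_eeg()` sums: 1/f-shaped background (white noise shaped to power slope
−1, SD 8 µV), an alpha component with a random-walk phase (10 µV, phase
diffusion 0.5 rad/√s — onsets are therefore never phase-locked to alpha,
which is also what the uniformly jittered ISIs are for), a gamma component
whose amplitude follows the standard Tort-style benchmark construction
\(A_\gamma (1 + \kappa\cos(\phi_\alpha - \phi_0))/(1+\kappa)\) with default
\(\kappa = 0.4\) and \(\phi_0 = 3\pi/2\) (troughs), and white noise (2 µV).
The preset effect structure scales only what the hypothesis touches: the
`moderate` preset adds +1.0 log-odds of accuracy and a 1.6× alpha boost in
the trough condition's post sessions; `strong` is +1.5 / 2.0×; `null` is
flat. These are calibrated to qualitative significance patterns only — no
effect sizes are published to match.

What the generator does *not* emulate: multi-channel topography and volume
conduction, non-stationary artifacts other than the injected transients,
eye-movement leakage into EEG, alpha waveform asymmetry, and any
biophysical mechanism linking stimulation to the boost. Passing tests
therefore show the pipeline is correct and calibrated on data with the
assumed structure, not that the scientific claim holds on real recordings.

Artifacts are Gaussian-envelope transients (σ = 20 ms, 150 µV) placed inside
the pre-stimulus window of a seeded trial subset; they survive the 1 Hz
high-pass with >100 µV amplitude, so ground truth and rejection coincide.
EOG is slow drift plus step-like saccades (10–50 ms sigmoidal rise, 100 µV)
at Poisson times.

# Feature pipeline

Preprocessing is a 4th-order Butterworth high-pass at 1 Hz plus a 2nd-order
band-stop at 60 Hz (quality 30), both applied zero-phase. The squared
magnitude response of each design is applied in the frequency domain on a
continuity-padded extension — the transfer function of a forward-backward
pass without its startup transients, and O(n log n) on the long traces the
replicate studies generate. Epochs span −1000 to 0 ms relative to onset;
any epoch exceeding 100 µV absolute (after filtering, since filtering
precedes exclusion in the protocol) is rejected; epochs that would run off
the trace are marked invalid rather than dropped.

*ITPC*: complex Morlet wavelets on a 1–100 Hz grid, implemented as analytic
Gaussian kernels in the frequency domain; the cycle count rises linearly
from 3 at 1 Hz to 8 at 100 Hz (a standard resolution trade-off; the original
toolbox call is not parameterized anywhere, so numerical ITPC values are
implementation-dependent). Epochs are transformed with ±500 ms of trace
context attached and the padding discarded, suppressing edge artifacts.
ITPC(f,t) is the modulus of the across-trial mean unit phasor. Statistics
aggregate over six windows: {7–13, 70–90 Hz} × three 200 ms windows from
−600 ms.

*Power*: per-trial periodograms of the 1 s pre-stimulus window (1 Hz
resolution), trial-averaged, with the 10 Hz and 80 Hz bins extracted. Power
is \(A^2/2\) for a sinusoid of amplitude \(A\).

*PAC*: phase frequencies 4–20 Hz (step 1, half-bandwidth 2 Hz), amplitude
frequencies 30–100 Hz (step 5, half-bandwidth 15 Hz — wide enough to hold
the 80 ± 10 Hz sidebands that alpha-rate modulation creates). Kept epochs
are concatenated before filtering (per-trial PAC on 1 s segments is too
short for stable phase-bin estimates; whether the original analysis averaged
per trial or concatenated is not stated). Band-passing is brick-wall in the
frequency domain with the analytic signal taken in the same step. The
default coupling measure is the Tort modulation index with K = 18 phase
bins: \(MI = (\log K - H(P))/\log K\) where \(P\) is the normalized
phase-binned mean amplitude; empty bins contribute \(0\log 0 = 0\). The
Canolty mean vector length (normalized by mean amplitude) is available as
`method = "mvl"`. The window of interest is the 7–13 × 70–90 Hz sub-grid
(7 × 5 cells).

*Saccades*: low-pass at 30 Hz, velocity over a 10 ms step, threshold
25 µV/10 ms, 100 ms refractory merging.

Phases are sine-referenced everywhere (peak \(\pi/2\), trough \(3\pi/2\)),
matching the waveform module.

# Statistical plan

Friedman tests (tie-corrected, within-subject ranks) run over sessions for
every measure × condition, and over conditions for pre-session baselines.
The p-value comes from the exact permutation distribution when the
enumeration \((k!)^N\) is small (≤ 3·10⁵) and the χ² approximation with
k − 1 df otherwise. Post-hoc Wilcoxon signed-rank tests (pre–post0,
pre–post10, post0–post10) run only where the omnibus test is significant at
0.05; their two-sided p is exact (full sign-flip distribution by
convolution, valid under ties) up to n = 25 and normal-approximated with
tie and continuity corrections beyond. Zeros are dropped by default
(Pratt's method is a flag). Benjamini–Hochberg FDR is applied within each
measure × condition family of three contrasts — the narrowest family
consistent with per-measure reporting; a global scope is available. All
tests are two-sided; the omnibus gate treats exactly p = 0.05 as not
significant. The Shapiro–Wilk screen that justifies the nonparametric plan
delegates to the standard base-R implementation.

# Replicate studies and problem sizes

`calibrate_type1()` runs 200 null-preset behavioral cohorts (17 subjects,
full 144-trial sessions) and pools the 12 omnibus p-values per cohort; the
significant fraction sits near the nominal 5% (χ² approximation at N = 17
is very slightly conservative, ≈0.045).

`recovery_study()` runs moderate-preset cohorts and scores each against the
directional trough-only pattern: significant *increases* pre→post0 and
pre→post10 in overall accuracy and 10 Hz power for trough; no significant
increase in either measure for sham or peak; no baseline accuracy
difference across conditions. The direction requirement mirrors the
hypothesis (the claim is an increase, not any change); control conditions
still face their full two-sided false-positive risk on the increase side.
EEG for the replicates is simulated at 256 Hz with 48 of the 144 trials per
session (compacted schedule) — 10 Hz power at N = 16 subjects is
insensitive to this reduction, and it keeps 100 replicates to a few
minutes. The test suite runs 100 replicates to keep the Monte Carlo noise
on the reported fraction near ±3%; the expected rate is ≈0.9 against the
0.80 threshold the recovery check uses.

# Numerical choices and degenerate inputs

* Composite rescaling measured on the sampled grid makes the plateau
  peak-to-peak exact; a single cycle's sampled peak-to-peak is within one
  sample's quantization (≈0.1%) of 3 mA.
* `verify_entrainment()` returns concentration 0 (phase NA) when the gamma
  band is numerically empty, instead of 0/0.
* Constant samples make the Shapiro–Wilk W undefined → error; all-zero
  difference vectors give Wilcoxon p = 1 with a warning; k < 3 levels send
  the user to the Wilcoxon test; incomplete measure cells are skipped and
  logged, never imputed.
* Friedman with every row fully tied has a zero tie-correction denominator;
  the statistic is defined as 0 with p = 1.
* Seeds: every stochastic stage receives a seed derived from the master
  seed via one `sample.int` draw (kept below 2³¹); RNG state is always
  restored, so library calls never perturb a session's stream.

# Known limitations

Recordings serialize as plain-text TSV/CSV rather than EDF (no EDF codec in
the dependency set, and no real recordings exist to read); ITPC magnitudes
are wavelet-parameter-dependent and only comparable within this
implementation; PAC on concatenated epochs inherits splice boundaries
(negligible for the 18-bin MI at the data lengths used, but visible in
single-epoch regimes); and the behavioral and EEG effects enter the
generator independently, so the package cannot address mediation questions.
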