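---
title: "Models and methods behind lucisync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lucisync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucisync)
```

`lucisync` analyses longitudinal PER2::LUC bioluminescence from three kinds
of recording: continuous dual-photomultiplier traces from freely moving
pregnant dams, multi-frame image stacks of the abdomen (acquired on a mixed
every-12-h-then-every-4-h gestational schedule, or every 30 min under a
cooled camera), and explant luminometry in 10-min bins. This vignette
explains the signal model, every estimator's assumptions and tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## Signal model and the synthetic-data generator

All generators share one latent model per oscillating unit:

$$ y(t) \;=\; B_0\, e^{g t}\,\bigl(1 + \rho(t)\, a\, e^{-d t}
   \cos\tfrac{2\pi (t - t_0)}{T}\bigr) \; + \; \text{background} \; +
   \; \text{noise}, $$

with baseline $B_0$ (counts), growth rate $g$ (h⁻¹; the default gestational
scenario uses $g = \log(100)/216$ so the baseline rises 100-fold across a
9-day window, matching the near-exponential rise of fetoplacental signal),
relative amplitude $a$, damping $d$ (h⁻¹), period $T$ (h) and peak at
Zeitgeber Time `peak_time`. $\rho(t)$ is a logistic onset ramp: rhythms in
utero emerge gradually, and a logistic is the simplest differentiable ramp
with two interpretable parameters (`onset_time`, the hour the ramp begins,
and `onset_width`, the hours it takes to saturate; default 12 h).
`onset_time = 0` disables the ramp entirely.

Noise is Poisson on photon counts by default — the physically appropriate
model for luminometry — with a Gaussian option for high-count regimes.
Dual-PMT traces split the signal evenly across two sensors, add `dark_rate`
counts/min of detector dark signal to each, and close a programmable
shutter for `dark_duration` minutes every `dark_interval` minutes (1 min
every 15 min in the emulated instrument), during which only dark counts are
recorded.

Image stacks place disjoint rectangular unit regions (pup-sized areas) in a
frame; each pixel of a unit oscillates with a peak-time offset drawn from a
wrapped normal around the unit's peak. The offset's circular SD
interpolates linearly from `phase_dispersion_start` to
`phase_dispersion_end` across the record, so a shrinking dispersion
simulates progressive intra-pregnancy synchronization with exactly known
per-pixel truth. Cosmic-ray spikes are single-frame, single-pixel additions
of at least 20× the local signal — deliberately unambiguous, so the test
that adjacent-frame minimization removes 100 % of them is sharp. A flat
camera background and an optional Gaussian point-spread blur complete the
frame model.

What the generator does *not* emulate: animal movement and refocusing
between imaging sessions (the fixed-ROI assumption is taken at face value),
anatomical structure within a pregnancy (units are rectangles), luciferin
pharmacokinetics, and any mechanistic clock-gene network. Hormonal
treatments are represented only as alternative phase-convergence scenarios
(different dispersion trajectories), not as pharmacology. Passing tests
therefore demonstrate estimator correctness under the stated statistical
model, not robustness to every artifact of real imaging.

Absolute count scales for PMT versus camera are not meaningful here;
defaults (`baseline0 = 100` counts) are arbitrary and only signal-to-noise
ratios matter.

## Preprocessing

**Dark counts** (`subtract_dark_and_sum()`). Each sensor's dark level is
the mean of its shutter-closed samples within a sliding 1-h window,
interpolated to every timestamp. A local rather than global estimate tracks
slow dark drift; the 15-min shutter cadence gives four dark samples per
window, enough for a stable local mean. Dark-interval samples are dropped
(the gap in timestamps is retained), and the corrected sensors are summed.

**Running-mean detrend** (`running_mean_detrend()`). The 24-h moving
average is taken over a fixed span of *time*, computed as the exact
integral mean of the piecewise-linear interpolant, so the mixed 12-h/4-h
schedule is averaged without density bias. A 24-h window annihilates any
pure 24-h periodic component and any straight line exactly. Samples whose
full window does not fit are marked invalid rather than padded: padding
would fabricate data at recording onset, exactly the epoch analysed for
rhythm emergence. For exponential growth the window mean has a second-order
leftover, $-(\sinh(12g)/(12g) - 1)e^{gt}$ — about 1 % of the trend for the
gestational growth rate, which caps trend-slope suppression near 90-fold;
the test suite asserts this derived ceiling rather than a rounder number.

**Windowed-sinc filters** (`sinc_detrend_smooth()`, `sinc_lowpass()`).
Zero-lag Hamming-windowed sinc kernels, normalized to unit sum so constants
pass unchanged; edges are handled by reflection. Defaults follow common
wavelet-pipeline practice: detrend cutoff 48 h, smooth cutoff 4 h (neither
is dictated by the recordings themselves; both are exposed). The kernel
support is twice the cutoff, truncated to the record length; with 10-min
sampling the 48-h kernel passes ≤ 0.5 % of a 24-h component into the
subtracted trend.

**Images**. `adjacent_frame_minimize()` is the pixelwise minimum of
consecutive frames (last frame paired backward); it removes single-frame
artifacts exactly and biases smooth signal by at most the inter-frame
change — with 4-h frames this also shifts apparent peaks earlier by up to
about an hour, a bias common to all subjects that leaves synchrony indices
untouched. `frame_average()` averages non-overlapping blocks (two 30-min
frames into one hourly frame), dropping a trailing partial block.
`roi_flux()` is the fixed-ROI total flux minus area-scaled background
mean. `extract_pixel_series()` smooths each frame with an isotropic
Gaussian (default σ = 1 px; σ = 0 is the identity) and returns tidy
per-pixel series. The pipeline order is minimize → average → background
subtract → Gaussian → per-pixel detrend/smooth.

## Rhythm detection

`meta_rhythm_test()` screens a detrended trace with three members:

1. **Lomb–Scargle** over the 18–30 h band, with the peak refined by
   parabolic interpolation on the frequency grid. The p-value is an
   extreme-value false-alarm probability: the finite-sample beta tail of a
   single frequency combined with a Baluev-style correction for the
   maximum over the scanned band. A naive independent-frequency count
   underestimates the multiplicity of an oversampled band scan and was
   measurably liberal; the extreme-value form calibrates the screen.
2. **Rank-template (JTK-style)**: values binned onto a near-uniform grid
   (default bin = max(1 h, median sampling)), Kendall's tau against cosine
   templates over periods (2-h steps) × phase lags (2-h steps), one-sided
   normal tail of the best tau, Bonferroni over templates. Constant
   (all-ties) traces are degenerate and reported non-rhythmic with p = 1;
   monotone trends must be removed first (detrending is a stated
   precondition).
3. **Harmonic regression**: a cosine–sine pair at each candidate period,
   best period by residual sum of squares, F-test with denominator degrees
   of freedom shrunk by the residual lag-1 autocorrelation
   ($n_\mathrm{eff} = n(1-\rho)/(1+\rho)$), Bonferroni over periods.

The three members see the same data, so their p-values are strongly
positively dependent. Fisher's independence combination is therefore
liberal here — measured above the 1.5× nominal bound that this package's
own acceptance test imposes, and not rescued by scaled-chi-square
dependence corrections, whose null tail proved heavy and unstable to
calibrate. The default combination is therefore Šidák on the minimum
member p-value, $1-(1-\min p)^3$, which is conservative under positive
dependence while losing essentially no power on circadian signals of
realistic strength (the suite verifies power ≥ 0.9 at SNR 3 with 5-day,
10-min sampling). `meta_combine()` still provides the classical Fisher
combination, and `meta_rhythm_test(combine = "fisher")` uses it. The
integrated period is the $-\log p$-weighted mean of member periods.

Classification is the fixed rule: circadian iff 18 ≤ T ≤ 30 h and
p < 0.05 (strict).

## Damped-cosine fit

`fit_damped_cosine()` fits $m + A e^{-d t}\cos(2\pi(t-t_0)/T)$ on a fit
window (days 2–5 by default, skipping the post-explantation transient).
For fixed $(T, d)$ the model is linear in $(m, A\cos\phi, A\sin\phi)$ and
is solved exactly; the outer 2-parameter problem is optimized by bounded
quasi-Newton (T in 16–32 h, d in 0–0.2 h⁻¹) from a multi-start grid
(T ∈ {20, 22, 24, 26, 28} × d ∈ {0.001, 0.02}), keeping the lowest-SSE
convergent start. Goodness is the Pearson correlation between fit and data
on the window; classification uses 18–30 h and r > 0.70 (strict). The
reported amplitude is the envelope at the window start; `peak_time` is the
first fitted maximum at or after the window start and `peak_phase_zt` its
Zeitgeber Time — with T ≠ 24 h the peak's clock time drifts across days,
so a single stated cycle is the only unambiguous convention. Degenerate
outcomes (zero amplitude, undefined correlation, no convergent start) are
flagged and classified non-circadian rather than erroring.

## Daily peaks and amplitude

`daily_peak_times()` splits the record into Zeitgeber days (ZT0-anchored
windows), low-pass smooths at a 2-h cutoff when the sampling supports it
(prevents noise-sample argmax at 10-min sampling), takes each day's
maximum refined by a three-point parabola, merges candidates closer than
4 h keeping the larger (ties keep the earlier), and omits days sampled more
coarsely than 4 h (how peaks were defined on 12-h sampling is not
determinable, so none are reported there), days with no valid samples, and
days whose data cover less than 18 h of the window — a heavily truncated
window pins its maximum to the data edge, an artifact rather than a peak.
`peak_trough_amplitude()` is max − min on the 36–60 h window (the second
recorded cycle, past the transient but before strong damping).

## Wavelet phase and synchrony

`wavelet_phase()` computes a Morlet continuous wavelet transform
(time-frequency parameter ω₀ = 6, 40 log-spaced periods across 18–30 h by
default) of a standardized, uniformly resampled series; the ridge is the
per-time power maximum and the instantaneous phase is read along it, with
phase 0 at the waveform maximum so wavelet phase and peak times share a
convention. Two numerical choices matter at the edges of short records:

- The series is extended by *reflection*, not zero padding, before the
  FFT. Zero padding makes the transform near an edge draw mostly on
  interior data, right-shifting the effective phase estimate; in a
  converging-phase ensemble that inflates apparent coherence at the start
  of the record. Reflection keeps edge phases local.
- The cone of influence flags samples closer to an edge than one ridge
  period — roughly one standard deviation of the Morlet temporal envelope
  at that scale, a guard band wide enough that the reflected transform is
  dominated by real data. (The classical $\sqrt{2}s$ e-folding rule would
  mask essentially the whole 72-h late-gestation imaging window at 30-h
  periods, which would make pixel-phase analysis on such windows
  impossible.)

`sync_timecourse()` applies the Kuramoto order parameter per time point
across pixels. Pixels whose median ridge power falls below the 5th
percentile of a white-noise ridge-power null (simulated once per sampling
geometry from an internal fixed seed, hence deterministic, and memoised)
are excluded: such pixels carry no usable phase and only dilute the index.
By default the series is restricted to the common in-cone window of all
gated pixels, because pixels cross the cone boundary at phase-dependent
times and a changing ensemble composition there masquerades as a synchrony
change. A centred 2-h rolling mean smooths the series. Inter-subject
synchrony uses `rayleigh_stat()` on daily peak times; its uniformity test
uses the standard small-sample corrected p-value
$p = \exp(\sqrt{1+4n+4(n^2-Zn)} - (1+2n))$ with $Z = nR^2$, which the
suite checks against a Monte-Carlo null at n = 6. Paired tissue
comparisons use circular differences wrapped to (−12, 12] h.

## Study drivers

`run_inutero()` chains minimize → (optional) average → background-
subtracted ROI flux → 24-h running-mean detrend → meta rhythm test →
classification, per dam. The rhythm test runs on the densely sampled
late-gestation segment (frame spacing ≤ 4 h after detrending), the only
segment whose sampling supports the 18–30 h band; pixel synchrony is
likewise computed on the dense tail, since 12-h frames cannot resolve
instantaneous phase at circadian periods. Dams failing classification are
excluded from peak and synchrony summaries but listed with a
machine-readable reason. The report carries per-dam fits, daily peak
times, the day-by-day inter-pregnancy Rayleigh index (days with at least
two circadian dams), and per-dam Kuramoto series; reports are
deterministic given inputs, and a configuration hash plus package version
are embedded. `run_explant()` and `run_treatment_compare()` follow the
same pattern for the luminometry and group-comparison designs; group
comparison reports descriptive mean ± SEM trajectories and their
difference only — inferential group statistics are a standard downstream
step, not re-derived here.

Simulated study sizes in the test suite (16 × 16-px frames, one pup-sized
region, 4–6 dams; 100 simulated explants; a few hundred Monte-Carlo
replicates per operating characteristic) were chosen as the smallest
designs in which every tested property is identifiable with comfortable
margins.

## Known limitations

- The JTK member uses the normal approximation to the tau null throughout;
  for fewer than ~15 bins its Bonferroni-corrected p-values are coarse.
- The harmonic member's AR(1) degrees-of-freedom shrinkage is a first-order
  correction; strongly red noise will still inflate its member p slightly
  (the conservative combination absorbs this in practice).
- Adjacent-frame minimization on sparse (4-h) frames biases peaks early by
  up to about an hour; peak *differences* and synchrony indices are
  unaffected, absolute peak times on imaging data carry this bias.
- The wavelet quality gate's white-noise null is matched to series length
  and step but not to residual autocorrelation after sinc conditioning; it
  is a floor, not a rhythmicity test.
- Explant fits assume a single oscillator per trace; multi-component
  tissues (intact placenta) are summarized by their dominant component.
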