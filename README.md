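# lucisync

Circadian rhythm detection and synchrony analysis for longitudinal
bioluminescence recordings.

## The problem

Clock-gene reporters such as PER2::LUC make clock-protein abundance visible
as light, so a pregnant mouse, a tissue explant in a luminometer, or a
cooled-camera image stack each yield long, slowly drifting photon-count time
series with a circadian (~24 h) modulation riding on top. Turning those raw
counts into biology requires a chain of small, well-defined steps: remove
detector dark counts and the near-exponential gestational growth of the
baseline, decide whether a trace is circadian at all, extract the daily peak
times, amplitude and period, estimate per-pixel instantaneous phase, and
summarize how synchronized oscillators are — within one pregnancy (across
fetoplacental pixels) and across pregnancies (across dams). `lucisync`
implements that chain as composable, tibble-in/tibble-out R functions, plus
a synthetic-data generator that produces every input class with known ground
truth so each estimator can be scored without any animal data.

It is written for chronobiologists analysing luminometry or bioluminescence
imaging, and for methodologists who want the estimators exercised against
simulated truth.

## The statistics at its core

- **Rhythm screen** (`meta_rhythm_test()`): three members — a Lomb–Scargle
  periodogram over 18–30 h with a Baluev-style extreme-value false-alarm
  probability (uneven sampling welcome), a JTK-style Kendall-tau match
  against cosine templates over periods × phase lags, and harmonic
  regression with AR(1)-prewhitened degrees of freedom. Member p-values are
  combined (Šidák on the minimum by default; Fisher optionally) and a trace
  is *circadian* when the integrated period T satisfies 18 ≤ T ≤ 30 h with
  p < 0.05.
- **Damped-cosine fit** (`fit_damped_cosine()`):
  `m + A e^{−dt} cos(2π(t − t₀)/T)` by profiled least squares (the linear
  parameters solved exactly at each (T, d)), classification by period band
  and goodness r > 0.70.
- **Instantaneous phase** (`wavelet_phase()`): Morlet continuous wavelet
  transform, phase read along the per-time power ridge, cone-of-influence
  masking, phase 0 at the waveform maximum.
- **Synchrony**: the Kuramoto order parameter `r = |mean e^{iθ}|` per time
  point across pixels (`sync_timecourse()`, intra-pregnancy), and the
  Rayleigh resultant R of daily peak times across subjects
  (`rayleigh_stat()`, inter-pregnancy), with the small-sample Rayleigh
  uniformity test `Z = nR²`, `p = exp(√(1+4n+4(n²−Zn)) − (1+2n))`.

## Worked example

Simulate a placental explant recorded in 10-min bins for 5 days, fit the
damped cosine to days 2–5, and summarize peak-time clustering across eight
subjects:

```r
library(lucisync)

truth <- oscillator_truth("placenta_1", period = 24.5, peak_time = 11,
                          amplitude_rel = 0.5, damping_rate = 0.005)
scenario <- sim_scenario(seed = 42, duration = 120, sampling_interval = 10,
                         baseline0 = 800, noise = "poisson")
trace <- simulate_explant_trace(truth, scenario)

fit <- fit_damped_cosine(trace)         # days 2-5 by default
fit
#> <damped_cosine_fit> T = 24.42 h, peak ZT 12.06, A = 309, d = 0.0049 /h, r = 0.988, circadian: TRUE

peak_trough_amplitude(trace)            # 36-60 h window
#> [1] 671

peaks <- simulate_peak_times(8, mean_peak = 13, concentration = 8, seed = 42)
rayleigh_stat(peaks)
#> # A tibble: 1 × 4
#>       n     R mean_direction p_uniformity
#>   <int> <dbl>          <dbl>        <dbl>
#> 1     8 0.921           14.0     0.000201
```

The fitted period (24.42 h vs the simulated 24.5 h) and damping
(0.0049 vs 0.005 /h) recover the generator's truth; the peak at ZT 12.06 is
the first fitted maximum inside the fit window (with T ≠ 24 h the peak's
clock time drifts by T − 24 per day, so it is reported for a stated cycle).
The amplitude A = 309 is the envelope at the window start:
309 · e^{0.0049·48} ≈ 391 ≈ 0.5 · 800 at recording onset. The Rayleigh
summary says the eight simulated subjects cluster near ZT 14 with a
resultant length of 0.92 — significantly non-uniform timing (p ≈ 2e−4).

Whole-study drivers exist for the three designs: `run_inutero()`
(imaging of pregnant dams on the mixed 12 h → 4 h schedule: ROI photon
flux, running-mean detrend, rhythm classification with exclusions, daily
inter-pregnancy Rayleigh index, per-dam pixel Kuramoto series),
`run_explant()` (damped-cosine fits, amplitudes, per-tissue Rayleigh tests,
paired tissue phase differences), and `run_treatment_compare()` (group
mean ± SEM synchrony trajectories). `vignettes/lucisync-methods.Rmd`
documents the models, parameter choices and limitations; a thin CLI for
trace-level workflows is in `inst/cli/lucisync.R`.

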