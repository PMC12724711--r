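# shared simulation fixtures, built in code at test time

# a gestational imaging dam: 16 x 16 frames on the mixed 12 h -> 4 h
# schedule, one pup-sized region, exponential growth, Poisson noise
make_dam <- function(i, circadian = TRUE, seed = 100 + i) {
  geom <- list(dim = c(16, 16),
               regions = tibble::tibble(unit_id = sprintf("d%d", i),
                                        row_min = 5, row_max = 10,
                                        col_min = 5, col_max = 10))
  sc <- sim_scenario(seed = seed, duration = 216, sampling_interval = 60,
                     baseline0 = 40, growth_rate = log(100) / 216,
                     noise = "poisson",
                     units = oscillator_truth(sprintf("d%d", i), period = 24,
                                              peak_time = 13,
                                              amplitude_rel = if (circadian) 0.4 else 0,
                                              onset_time = 96),
                     phase_dispersion_start = 5, phase_dispersion_end = 0.5,
                     spike_rate = 0.2)
  simulate_image_stack(sc, geom, timestamps = gestation_schedule())
}

# an explant luminometer trace: 10-min bins over 5 days
make_explant <- function(id = "e1", period = 24, peak = 13, amp = 0.4,
                         damping = 0.008, seed = 1, noise = "poisson",
                         baseline0 = 800, duration = 120) {
  simulate_explant_trace(
    oscillator_truth(id, period = period, peak_time = peak,
                     amplitude_rel = amp, damping_rate = damping),
    sim_scenario(seed = seed, duration = duration, sampling_interval = 10,
                 baseline0 = baseline0, noise = noise))
}

# circular absolute difference on an arbitrary modulus
circ_abs_diff <- function(a, b, modulus = 24) {
  d <- (a - b) %% modulus
  pmin(d, modulus - d)
}
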