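# Small paradigms and canned ground truths shared across tests.

# scaled-down paradigm for fast unit tests (trial = 40 s)
small_paradigm <- function(n_trials = 3) {
  stim_paradigm(n_baseline = 10L, n_stim = 5L, n_post = 5L, n_discard = 2L,
                n_trials = n_trials)
}

# full-size acquisition paradigm (trial = 130 s)
full_paradigm <- function(n_trials = 10) stim_paradigm(n_trials = n_trials)

# 40x40 single-slice grid with a 6x6 active block
small_bold <- function(amplitude_pct, noise_sd_pct = 0.3, seed = 1,
                       paradigm = full_paradigm()) {
  mask <- rect_mask(c(40, 40, 1), 18:23, 18:23)
  gen_bold_trials(paradigm,
                  bold_truth(mask, amplitude_pct, noise_sd_pct, seed = seed),
                  grid = c(40, 40, 1))
}

# two well-separated units (brief/high-rate vs broad/low-rate)
two_unit_truth <- function(seed, noise_sd = 10e-6, stim_mult = c(1, 1)) {
  ephys_truth(data.frame(duration_ms = c(0.33, 0.9),
                         amplitude = c(120e-6, 90e-6),
                         rate = c(6, 3),
                         stim_mult = stim_mult, drug_mult = c(1, 1)),
              noise_sd = noise_sd, seed = seed)
}

# Poisson spike train at constant rate over [0, duration_s)
poisson_train <- function(rate, duration_s) gen_spike_times(duration_s, rate)
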