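# Shared builders for small synthetic fixtures (all generated in code).

# single active-active segment layout for two participants
two_party_layout <- function(duration_s) {
  lay <- data.frame(trial = 1, segment = 1, duration_s = duration_s)
  lay$active <- list(c("P1", "P2"))
  lay
}

# minimal two-party session: white-ish noise, no coupling unless given
tiny_session <- function(seed = 1, duration_s = 60, montage = c("C3", "C4"),
                         coupling = list(rho = 0), fs = 250, ...) {
  cfg <- synthetic_config(
    n_participants = 2, montage = montage, eog_labels = character(0),
    fs = fs, trial_layout = two_party_layout(duration_s), baseline_s = 60,
    coupling = coupling, seed = seed, ...)
  generate_session(cfg)
}

# deterministic sine-carrying recording for filter tests
tone_recording <- function(freqs, fs = 1000, duration_s = 10, amp = 1,
                           labels = paste0("ch", seq_along(freqs))) {
  t <- (0:(duration_s * fs - 1)) / fs
  data <- do.call(rbind, lapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  new_recording(data, labels, fs = fs)
}

# single-sided amplitude of a sinusoid at freq f
sine_amp <- function(x, f, fs) {
  n <- length(x)
  2 * abs(mean(x * exp(-2i * pi * f * (1:n) / fs)))
}

parse_time_for_test <- function(s) hyperbis:::parse_event_time(s)

# periodogram power in [lo, hi] Hz
band_power <- function(x, lo, hi, fs) {
  n <- length(x)
  X <- Mod(fft(x))^2 / n
  fr <- (0:(n - 1)) * fs / n
  sum(X[fr >= lo & fr <= hi])
}
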