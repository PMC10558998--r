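## Reference simulation scenarios at desk scale (16-channel montage, 250 Hz
## generation, 60-s active-active segments). Segment and rest blocks have
## matched window counts (L = 57) so the |complex mean| estimators being
## compared share one noise floor; the condition-defining parameters
## (rho levels, carrier band, SNR cap, lead time) are the study conditions.

#' Planted channel pairs of the detection-power scenario
#' @return list of five `c(chan_a, chan_b)` pairs.
#' @export
scenario_planted_pairs <- function() {
  list(c("Fp1", "F3"), c("F4", "C3"), c("C4", "T7"), c("T8", "P3"),
       c("P4", "O1"))
}

active_pair_layout <- function(duration_s) {
  lay <- data.frame(trial = 1, segment = 1, duration_s = duration_s)
  lay$active <- list(c("P1", "P2"))
  lay
}

#' Detection-power scenario configuration
#'
#' Two participants, 16-channel montage, one 60-s active-active segment with
#' gamma-band quadratic phase coupling (rho = 0.8, multicarrier comb at
#' 35 +/- 5 Hz) planted on five known channel pairs.
#'
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
scenario_power_config <- function(seed) {
  synthetic_config(
    n_participants = 2, montage = desk16_labels(),
    eog_labels = character(0), fs = 250,
    trial_layout = active_pair_layout(60), baseline_s = 60,
    coupling = list(rho = 0.8, f0 = 35, bandwidth = 10,
                    channel_pairs = scenario_planted_pairs()),
    seed = seed)
}

#' Null-session scenario configuration
#'
#' Identical layout to [scenario_power_config()] but with no coupling
#' anywhere (rho = 0): participants' signals are independent.
#'
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
scenario_null_config <- function(seed) {
  synthetic_config(
    n_participants = 2, montage = desk16_labels(),
    eog_labels = character(0), fs = 250,
    trial_layout = active_pair_layout(60), baseline_s = 60,
    coupling = list(rho = 0), seed = seed)
}

#' Event-recovery scenario configuration
#'
#' Two participants, 4-channel montage, one long active-active segment with
#' weak base coupling (rho = 0.1) on one channel pair and a schedule of 16
#' synchronized (SP, rho + 0.7) and 12 desynchronized (DP, rho - 0.1)
#' events, 45 s apart, whose modulation begins 3 s before the annotated
#' time.
#'
#' @param seed integer seed (also used to shuffle the SP/DP order).
#' @return a [synthetic_config()]; the coupled pair is `("T7", "O1")`.
#' @export
scenario_event_config <- function(seed) {
  set.seed(seed * 1009L)
  n_sp <- 16; n_dp <- 12
  times_rel <- 90 + 45 * (0:(n_sp + n_dp - 1))
  types <- sample(rep(c("SP", "DP"), times = c(n_sp, n_dp)))
  seg_start <- 120          # after the two pre baselines
  ev <- data.frame(type = types, time = seg_start + times_rel,
                   rho_delta = ifelse(types == "SP", 0.7, -0.1))
  synthetic_config(
    n_participants = 2, montage = c("T7", "O1", "Cz", "Pz"),
    eog_labels = character(0), fs = 250,
    trial_layout = active_pair_layout(max(times_rel) + 90),
    baseline_s = 60,
    coupling = list(rho = 0.1, f0 = 35, bandwidth = 10,
                    channel_pairs = list(c("T7", "O1"))),
    event_schedule = ev, event_duration_s = 20, lead_time_s = 3,
    seed = seed)
}

#' Run the detection-power scenario once
#'
#' Generates the session, scans the gamma family of the active-active
#' segment and counts how many of the five planted pairs reach Bonferroni
#' significance.
#'
#' @param seed integer seed.
#' @return list with `recovered` (0-5), `n_significant`, `results`.
#' @export
scenario_power_run <- function(seed) {
  g <- generate_session(scenario_power_config(seed))
  res <- scan_combinations(g$session, 1, 1, c("P1", "P2"), bands = "gamma")
  planted <- vapply(scenario_planted_pairs(), paste, character(1),
                    collapse = "->")
  found <- paste(res$chan_a[res$significant], res$chan_b[res$significant],
                 sep = "->")
  list(recovered = sum(planted %in% found),
       n_significant = sum(res$significant), results = res)
}

#' Run the null scenario once
#'
#' @param seed integer seed.
#' @return number of Bonferroni rejections in the gamma family (family-wise
#'   errors; 0 for a clean null).
#' @export
scenario_null_run <- function(seed) {
  g <- generate_session(scenario_null_config(seed))
  res <- scan_combinations(g$session, 1, 1, c("P1", "P2"), bands = "gamma")
  sum(res$significant)
}

#' Run the event-recovery scenario once
#'
#' Generates the session, builds the coupled pair's gamma temporal trace,
#' compares baseline-corrected SP against DP peri-event traces in the
#' active-active condition and returns the earliest sustained significant
#' timepoint.
#'
#' @param seed integer seed.
#' @return earliest sustained onset in seconds relative to the annotation
#'   (negative = anticipatory), or `NA`.
#' @export
scenario_event_run <- function(seed) {
  g <- generate_session(scenario_event_config(seed))
  ela <- event_locked_analysis(g$session, c("P1", "P2"), c("T7", "O1"),
                               band = "gamma", condition = "active-active")
  earliest_sustained(ela$comparison)
}
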