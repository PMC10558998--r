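#' Configuration for synthetic hyperscanning sessions
#'
#' Builds the parameter set for [generate_session()]. Defaults emulate a
#' staggered-entry ("exquisite corpse") improvisation study: three
#' participants wearing 64-channel caps (four channels repurposed as EOG),
#' 1000 Hz acquisition, three trials of three five-minute segments with one
#' participant joining per segment, and one-minute eyes-open/eyes-closed
#' baseline blocks before and after the performance.
#'
#' Cross-participant coupling is injected as quadratic phase coupling: per
#' ~4 s epoch, participant `a`'s channel receives a carrier at `f0` with a
#' random phase `phi`, and participant `b`'s channel receives the same
#' carrier phase-locked at `phi` plus its harmonic at `2*f0` with phase
#' `2*phi`, mixed with amplitude-matched incoherent copies so that the
#' coupled fraction is `rho` and total injected power does not depend on
#' `rho`. The diagonal cross-bispectrum at bin `f0` is the canonical detector
#' of exactly this structure.
#'
#' Synchronized-performance (SP) events raise `rho` starting `lead_time_s`
#' seconds before the annotated time; desynchronized-performance (DP) events
#' lower it. Coupling is only ever active while both dyad members are active
#' in the design.
#'
#' @param n_participants number of participants.
#' @param montage character vector of channel labels per participant.
#' @param eog_labels labels (subset of `montage`) carrying kind `"EOG"`.
#' @param fs sampling frequency in Hz.
#' @param n_trials,segments_per_trial,segment_s trial layout; segments are
#'   `segment_s` seconds long.
#' @param baseline_s duration of each EO/EC baseline block (s).
#' @param inter_trial_gap_s pause between trials (s).
#' @param entry_orders list (one per trial) of participant-id permutations:
#'   who enters at segment 1, 2, 3. Default rotates so each participant
#'   enters first exactly once.
#' @param trial_layout optional explicit layout `data.frame(trial, segment,
#'   duration_s)` with list-column `active`; overrides the regular layout.
#' @param coupling list with `rho` (coupled fraction in `[0, 1]`), `f0`
#'   (carrier Hz; the excited diagonal bin), `bandwidth` (Hz of per-epoch
#'   carrier jitter; 0 = fixed tone), `channel_pairs` (list of
#'   `c(chan_a, chan_b)`), `dyads` (list of dyad id pairs or `NULL` for all).
#' @param component_amp amplitude (uV) of each injected sinusoid. The default
#'   6.3 uV against the 20 uV background keeps injected variance at <= 10% of
#'   background variance.
#' @param noise_sd background noise standard deviation (uV).
#' @param noise_exponent spectral slope of the 1/f^a background.
#' @param blink_rate eye-blink rate (events/min) for EOG artifact injection.
#' @param event_schedule `data.frame(type, time, rho_delta)` with `type` in
#'   `"SP"`/`"DP"`, `time` in session seconds, and the additive change to
#'   `rho` (clamped to `[0, 1]`).
#' @param event_duration_s seconds each event's modulation persists after its
#'   annotated time.
#' @param lead_time_s seconds before the annotated time at which SP/DP
#'   modulation begins (anticipatory lead).
#' @param epoch_s epoch length (s) for phase redraws of injected components.
#' @param seed integer seed fixing all randomness end-to-end.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 3,
                             montage = acticap64_labels(),
                             eog_labels = default_eog_labels(),
                             fs = 1000,
                             n_trials = 3,
                             segments_per_trial = 3,
                             segment_s = 300,
                             baseline_s = 60,
                             inter_trial_gap_s = 30,
                             entry_orders = NULL,
                             trial_layout = NULL,
                             coupling = list(rho = 0, f0 = 35, bandwidth = 10,
                                             channel_pairs = list(c("T7", "O1")),
                                             dyads = NULL),
                             component_amp = 6.3,
                             noise_sd = 20,
                             noise_exponent = 1,
                             blink_rate = 0,
                             event_schedule = NULL,
                             event_duration_s = 20,
                             lead_time_s = 3,
                             epoch_s = 4,
                             seed = 1) {
  if (fs <= 0) stop("invalid argument: fs must be positive")
  if (segment_s <= 0 || baseline_s <= 0)
    stop("invalid argument: durations must be positive")
  if (blink_rate < 0) stop("invalid argument: blink_rate must be >= 0")
  if (!all(eog_labels %in% montage))
    stop("eog_labels must be a subset of the montage")
  cpl <- list(rho = 0, f0 = 35, bandwidth = 10,
              channel_pairs = list(c("T7", "O1")), dyads = NULL)
  for (k in names(coupling)) cpl[[k]] <- coupling[[k]]
  if (cpl$rho < 0 || cpl$rho > 1)
    stop("invalid argument: coupling rho must lie in [0, 1]")
  if (2 * cpl$f0 >= fs / 2)
    stop("invalid argument: 2*f0 must lie below the Nyquist frequency")
  ids <- paste0("P", seq_len(n_participants))
  if (is.null(entry_orders))
    entry_orders <- lapply(seq_len(n_trials), function(t)
      ids[((t - 1L) + seq_len(n_participants) - 1L) %% n_participants + 1L])
  cfg <- list(n_participants = n_participants, ids = ids, montage = montage,
              eog_labels = eog_labels, fs = fs, n_trials = n_trials,
              segments_per_trial = segments_per_trial, segment_s = segment_s,
              baseline_s = baseline_s, inter_trial_gap_s = inter_trial_gap_s,
              entry_orders = entry_orders, trial_layout = trial_layout,
              coupling = cpl, component_amp = component_amp,
              noise_sd = noise_sd, noise_exponent = noise_exponent,
              blink_rate = blink_rate, event_schedule = event_schedule,
              event_duration_s = event_duration_s, lead_time_s = lead_time_s,
              epoch_s = epoch_s, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate 1/f^a background noise channels
#'
#' White Gaussian noise is shaped in the frequency domain so that power
#' spectral density is proportional to `1/f^noise_exponent`; each channel is
#' independently generated, exactly zero-mean and scaled to `sd_uv`
#' microvolts.
#'
#' @param n_channels number of channels.
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling frequency in Hz (> 0).
#' @param noise_exponent spectral slope `a` (0 = white).
#' @param seed optional integer seed; `NULL` uses the ambient RNG stream.
#' @param sd_uv per-channel standard deviation in microvolts.
#' @return channels x samples numeric matrix.
#' @export
generate_participant_noise <- function(n_channels, duration_s, fs,
                                       noise_exponent = 1, seed = NULL,
                                       sd_uv = 20) {
  if (duration_s <= 0 || fs <= 0)
    stop("invalid argument: duration_s and fs must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  w <- matrix(rnorm(n * n_channels), nrow = n, ncol = n_channels)
  k <- 0:(n - 1)
  fabs <- pmin(k, n - k) * fs / n
  scale <- ifelse(fabs > 0, fabs^(-noise_exponent / 2), 0)
  x <- Re(mvfft(mvfft(w) * scale, inverse = TRUE)) / n
  x <- sweep(x, 2L, colMeans(x))
  s <- apply(x, 2L, sd)
  s[s == 0] <- 1
  x <- sweep(x, 2L, s / sd_uv, "/")
  t(x)
}

#' Quadratically phase-coupled component pair
#'
#' Low-level generator of the injected waveforms for one channel pair over
#' `n_samples` samples. Phases are redrawn per epoch; the harmonic at `2*f`
#' carries twice the carrier phase, so the pair's diagonal cross-bispectrum
#' at the carrier bin accumulates coherently across windows in proportion to
#' `rho^2`.
#'
#' @param n_samples samples to generate.
#' @param fs sampling frequency (Hz).
#' @param f0 carrier frequency (Hz).
#' @param rho coupled fraction in `[0, 1]`.
#' @param epoch_s phase-redraw epoch (s).
#' @param bandwidth carrier bandwidth (Hz). With `bandwidth = 0` a single
#'   tone at `f0` is injected. With `bandwidth > 0` a comb of carriers on
#'   the `1/epoch_s`-Hz grid spanning `f0 +/- bandwidth/2` is injected
#'   simultaneously, each at amplitude `amp / sqrt(n_carriers)` (total
#'   injected variance independent of bandwidth) with its own per-epoch
#'   phase, so every diagonal bin across the band accumulates quadratic
#'   phase coupling in every window.
#' @param amp total amplitude scale (uV); for a single carrier, the
#'   amplitude of each sinusoid.
#' @return list with numeric vectors `a` and `b`, the `carriers` (Hz) and a
#'   matrix `phases` (epochs x carriers).
#' @export
coupled_component_pair <- function(n_samples, fs, f0, rho, epoch_s = 4,
                                   bandwidth = 0, amp = 6.3) {
  if (rho < 0 || rho > 1) stop("invalid argument: rho must lie in [0, 1]")
  if (2 * f0 >= fs / 2) stop("invalid argument: 2*f0 must be below Nyquist")
  a <- numeric(n_samples)
  b <- numeric(n_samples)
  ep_len <- round(epoch_s * fs)
  starts <- seq(1L, n_samples, by = ep_len)
  grid_res <- 1 / epoch_s
  carriers <- if (bandwidth > 0)
    seq(f0 - bandwidth / 2, f0 + bandwidth / 2, by = grid_res)
  else f0
  nc <- length(carriers)
  ca <- amp / sqrt(nc)
  phases <- matrix(NA_real_, length(starts), nc)
  for (j in seq_along(starts)) {
    i0 <- starts[j]
    i1 <- min(i0 + ep_len - 1L, n_samples)
    tau <- (0:(i1 - i0)) / fs
    phi <- runif(nc, 0, 2 * pi)
    psi1 <- runif(nc, 0, 2 * pi)
    psi2 <- runif(nc, 0, 2 * pi)
    w1 <- outer(tau, 2 * pi * carriers)       # samples x carriers
    w2 <- outer(tau, 2 * pi * 2 * carriers)
    a[i0:i1] <- a[i0:i1] +
      ca * rowSums(cos(sweep(w1, 2L, phi, "+")))
    coh <- rowSums(cos(sweep(w1, 2L, phi, "+"))) +
      rowSums(cos(sweep(w2, 2L, 2 * phi, "+")))
    inc <- rowSums(cos(sweep(w1, 2L, psi1, "+"))) +
      rowSums(cos(sweep(w2, 2L, psi2, "+")))
    ## power-complement mixing: |b|^2 is independent of rho, so the
    ## diagonal bispectrum's rho^2 coherent term is the only rho-dependence
    b[i0:i1] <- b[i0:i1] + ca * (rho * coh + sqrt(1 - rho^2) * inc)
    phases[j, ] <- phi
  }
  list(a = a, b = b, carriers = carriers, phases = phases)
}

#' Inject a phase-coupled component into a session
#'
#' Adds a quadratically phase-coupled component pair (see
#' [coupled_component_pair()]) to one channel of each dyad member over a
#' half-open interval. With `rho = 0` the two participants' additions are
#' statistically independent.
#'
#' @param session a `hyperscan_session`.
#' @param dyad length-2 character vector of participant ids; the first
#'   receives the carrier-only component, the second the carrier + harmonic.
#' @param channel_pair `c(channel of a, channel of b)`.
#' @param f0 carrier frequency (Hz).
#' @param rho coupled fraction in `[0, 1]`.
#' @param interval numeric `c(start, end)` in session seconds.
#' @param seed optional integer seed.
#' @param epoch_s,bandwidth,amp see [coupled_component_pair()].
#' @return the session with components added.
#' @export
inject_coupled_component <- function(session, dyad, channel_pair, f0, rho,
                                     interval, seed = NULL, epoch_s = 4,
                                     bandwidth = 0, amp = 6.3) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(dyad %in% names(session$recordings)))
    stop("missing participant: ", paste(setdiff(dyad, names(session$recordings)),
                                        collapse = ", "))
  fs <- session_fs(session)
  dur <- session_duration(session)
  if (interval[1] < 0 || interval[2] > dur || interval[2] <= interval[1])
    stop("range error: interval [", interval[1], ", ", interval[2],
         ") outside session [0, ", dur, ")")
  ra <- session$recordings[[dyad[1]]]
  rb <- session$recordings[[dyad[2]]]
  ia <- match(channel_pair[1], ra$labels)
  ib <- match(channel_pair[2], rb$labels)
  if (is.na(ia)) stop("missing channel: '", channel_pair[1], "' in ", dyad[1])
  if (is.na(ib)) stop("missing channel: '", channel_pair[2], "' in ", dyad[2])
  i0 <- floor(interval[1] * fs) + 1L
  i1 <- floor(interval[2] * fs)
  comp <- coupled_component_pair(i1 - i0 + 1L, fs, f0, rho,
                                 epoch_s = epoch_s, bandwidth = bandwidth,
                                 amp = amp)
  session$recordings[[dyad[1]]]$data[ia, i0:i1] <-
    session$recordings[[dyad[1]]]$data[ia, i0:i1] + comp$a
  session$recordings[[dyad[2]]]$data[ib, i0:i1] <-
    session$recordings[[dyad[2]]]$data[ib, i0:i1] + comp$b
  session
}

blink_template <- function(fs, amp = 150) {
  t <- seq(0, 0.3, by = 1 / fs)
  amp * (1.2 * exp(-((t - 0.09) / 0.04)^2) - 0.25 * exp(-((t - 0.2) / 0.07)^2))
}

frontal_weight <- function(label) {
  if (grepl("^Fp", label)) return(0.35)
  if (grepl("^AF", label)) return(0.25)
  if (grepl("^(FC|FT)", label)) return(0.08)
  if (grepl("^F", label)) return(0.15)
  if (grepl("^(CP|TP)", label)) return(0.02)
  if (grepl("^(C|T)", label)) return(0.04)
  if (grepl("^(PO|O)", label)) return(0.005)
  if (grepl("^P", label)) return(0.01)
  0.01
}

#' Inject stereotyped eye-blink artifacts
#'
#' Blink onsets follow a Poisson process at `blink_rate` events/min. Each
#' blink adds a ~300 ms biphasic template at full amplitude to the EOG
#' channels and, attenuated by a frontal-weighted mixing vector, to the EEG
#' channels. The mixing ground truth is attached as attribute
#' `"blink_truth"`.
#'
#' @param recording an `eeg_recording` with designated EOG channels.
#' @param blink_rate blinks per minute (>= 0; 0 returns the input unchanged).
#' @param seed optional integer seed.
#' @param amp blink amplitude on the EOG channels (uV).
#' @return the recording with artifacts added.
#' @export
inject_eog_artifacts <- function(recording, blink_rate, seed = NULL,
                                 amp = 150) {
  if (blink_rate < 0) stop("invalid argument: blink_rate must be >= 0")
  if (blink_rate == 0) return(recording)
  if (!is.null(seed)) set.seed(seed)
  eog <- which(recording$kinds == "EOG")
  if (length(eog) == 0L)
    stop("recording has no designated EOG channels")
  fs <- recording$fs
  dur <- rec_duration(recording)
  tpl <- blink_template(fs, amp)
  n_blinks <- rpois(1, blink_rate * dur / 60)
  times <- sort(runif(n_blinks, 0, max(dur - 0.35, 0)))
  w <- vapply(recording$labels, frontal_weight, numeric(1))
  w[eog] <- 1
  for (tt in times) {
    i0 <- floor(tt * fs) + 1L
    idx <- i0:(i0 + length(tpl) - 1L)
    idx <- idx[idx <= ncol(recording$data)]
    recording$data[, idx] <- recording$data[, idx] +
      outer(w, tpl[seq_along(idx)])
  }
  attr(recording, "blink_truth") <- list(times = times, mixing = w)
  recording
}

build_timeline <- function(config) {
  b <- config$baseline_s
  baselines <- data.frame(phase = c("pre", "pre"), condition = c("EO", "EC"),
                          start = c(0, b), end = c(b, 2 * b))
  cur <- 2 * b
  rows <- list()
  if (!is.null(config$trial_layout)) {
    lay <- config$trial_layout
    for (i in seq_len(nrow(lay))) {
      if (i > 1L && lay$trial[i] != lay$trial[i - 1L])
        cur <- cur + config$inter_trial_gap_s
      rows[[length(rows) + 1L]] <-
        data.frame(trial = lay$trial[i], segment = lay$segment[i],
                   start = cur, end = cur + lay$duration_s[i])
      rows[[length(rows)]]$active <- list(lay$active[[i]])
      cur <- cur + lay$duration_s[i]
    }
  } else {
    for (t in seq_len(config$n_trials)) {
      if (t > 1L) cur <- cur + config$inter_trial_gap_s
      order_t <- config$entry_orders[[t]]
      for (s in seq_len(config$segments_per_trial)) {
        rows[[length(rows) + 1L]] <-
          data.frame(trial = t, segment = s,
                     start = cur, end = cur + config$segment_s)
        rows[[length(rows)]]$active <-
          list(order_t[seq_len(min(s, length(order_t)))])
        cur <- cur + config$segment_s
      }
    }
  }
  design <- do.call(rbind, rows)
  baselines <- rbind(baselines,
                     data.frame(phase = c("post", "post"),
                                condition = c("EO", "EC"),
                                start = c(cur, cur + b),
                                end = c(cur + b, cur + 2 * b)))
  list(design = design, baselines = baselines, duration = cur + 2 * b)
}

## Split a coupled interval at event boundaries. Each SP/DP event steps the
## coupled fraction rho by rho_delta AND scales the injected component
## amplitude by (1 + rho_delta) over [time - lead, time + dur): the
## single-window (L = 1) temporal estimator responds to component magnitude,
## not phase coherence, so an amplitude signature is what makes events
## visible in the temporal trace; the rho step is what segment-level
## statistics detect.
piecewise_rho <- function(interval, base_rho, events, lead, dur) {
  pieces <- data.frame(start = interval[1], end = interval[2],
                       rho = base_rho, amp_factor = 1)
  if (is.null(events) || nrow(events) == 0L) return(pieces)
  for (i in seq_len(nrow(events))) {
    e0 <- max(events$time[i] - lead, interval[1])
    e1 <- min(events$time[i] + dur, interval[2])
    if (e1 <= e0) next
    out <- list()
    for (j in seq_len(nrow(pieces))) {
      p <- pieces[j, ]
      lo <- max(p$start, e0); hi <- min(p$end, e1)
      if (hi <= lo) { out[[length(out) + 1L]] <- p; next }
      if (p$start < lo)
        out[[length(out) + 1L]] <- data.frame(start = p$start, end = lo,
                                              rho = p$rho,
                                              amp_factor = p$amp_factor)
      out[[length(out) + 1L]] <-
        data.frame(start = lo, end = hi,
                   rho = min(max(p$rho + events$rho_delta[i], 0), 1),
                   amp_factor = max(p$amp_factor *
                                      (1 + events$rho_delta[i]), 0))
      if (hi < p$end)
        out[[length(out) + 1L]] <- data.frame(start = hi, end = p$end,
                                              rho = p$rho,
                                              amp_factor = p$amp_factor)
    }
    pieces <- do.call(rbind, out)
  }
  pieces
}

#' Generate a synthetic hyperscanning session with ground truth
#'
#' Builds the session timeline (pre EO/EC baselines, staggered-entry trials,
#' post EO/EC), fills every participant's channels with 1/f background noise,
#' optionally injects eye-blink artifacts, and injects quadratically
#' phase-coupled components for every configured dyad and channel pair in
#' each segment where both dyad members are active. SP/DP events modulate the
#' coupled fraction as step changes beginning `lead_time_s` seconds before
#' the annotated time; annotations are emitted on the session clock and
#' exportable in the mm:ss trial-anchored dialect via [annotations_table()].
#'
#' @param config a [synthetic_config()].
#' @return list with elements `session` (a `hyperscan_session`) and `truth`
#'   (per-interval true coupled fraction per dyad, event onsets, coupled
#'   channel pairs).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  tl <- build_timeline(config)
  fs <- config$fs
  ev <- config$event_schedule
  if (!is.null(ev) && nrow(ev) > 0L) {
    if (any(ev$time < 0 | ev$time > tl$duration))
      stop("range error: scheduled event outside session")
    if (is.null(ev$rho_delta))
      ev$rho_delta <- ifelse(ev$type == "SP", 0.5, -0.5)
  }
  kinds <- ifelse(config$montage %in% config$eog_labels, "EOG", "EEG")
  recs <- lapply(config$ids, function(pid) {
    noise <- generate_participant_noise(length(config$montage), tl$duration,
                                        fs, config$noise_exponent,
                                        sd_uv = config$noise_sd)
    r <- new_recording(noise, config$montage, kinds, fs,
                       participant_id = pid,
                       meta = list(reference = "FCz"))
    if (config$blink_rate > 0) r <- inject_eog_artifacts(r, config$blink_rate)
    r
  })
  annotations <- empty_annotations()
  if (!is.null(ev) && nrow(ev) > 0L) {
    labels_by_type <- list(
      SP = c("Players synchronize", "Mirror each other",
             "Performing under a common pulse"),
      DP = c("Discord", "Both play unevenly", "Deviation from the theme"))
    counters <- c(SP = 0L, DP = 0L)
    ann <- lapply(seq_len(nrow(ev)), function(i) {
      ty <- ev$type[i]
      counters[ty] <<- counters[ty] + 1L
      data.frame(event_type = paste0(ty, "_", counters[ty]), type = ty,
                 time = ev$time[i],
                 label = labels_by_type[[ty]][(counters[ty] - 1L) %%
                                                3L + 1L])
    })
    annotations <- do.call(rbind, ann)
  }
  session <- new_session(recs, tl$design, tl$baselines, annotations,
                         provenance = list(list(stage = "simulate",
                                                seed = config$seed)))
  dyads <- session_dyads(session)
  if (!is.null(config$coupling$dyads))
    dyads <- config$coupling$dyads
  rho_rows <- list()
  cpl <- config$coupling
  for (dy in dyads) {
    for (i in seq_len(nrow(tl$design))) {
      iv <- c(tl$design$start[i], tl$design$end[i])
      both_active <- all(dy %in% tl$design$active[[i]])
      base <- if (both_active) cpl$rho else 0
      ev_in <- NULL
      if (both_active && !is.null(ev) && nrow(ev) > 0L)
        ev_in <- ev[ev$time - config$lead_time_s < iv[2] &
                      ev$time + config$event_duration_s > iv[1], ,
                    drop = FALSE]
      pieces <- piecewise_rho(iv, base, ev_in, config$lead_time_s,
                              config$event_duration_s)
      for (j in seq_len(nrow(pieces))) {
        rho_rows[[length(rho_rows) + 1L]] <-
          data.frame(dyad = paste(dy, collapse = "-"),
                     start = pieces$start[j], end = pieces$end[j],
                     rho = pieces$rho[j])
        if (both_active && (base > 0 || pieces$rho[j] > 0)) {
          for (cp in cpl$channel_pairs) {
            session <- inject_coupled_component(
              session, dy, cp, cpl$f0, pieces$rho[j],
              c(pieces$start[j], pieces$end[j]),
              epoch_s = config$epoch_s, bandwidth = cpl$bandwidth,
              amp = config$component_amp * pieces$amp_factor[j])
          }
        }
      }
    }
  }
  truth <- list(rho = do.call(rbind, rho_rows),
                events = if (!is.null(ev) && nrow(ev) > 0L)
                  data.frame(type = ev$type, time = ev$time,
                             onset = ev$time - config$lead_time_s)
                else NULL,
                channel_pairs = cpl$channel_pairs,
                config = config)
  list(session = session, truth = truth)
}
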