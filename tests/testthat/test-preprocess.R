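test_that("resampling preserves passband content and rejects aliases", {
  rec <- tone_recording(c(10, 200), fs = 1000, duration_s = 10)
  out <- resample_recording(rec, 250)
  expect_equal(out$fs, 250)
  expect_equal(ncol(out$data), 2500L)
  # 10 Hz amplitude preserved within 1%
  expect_equal(sine_amp(out$data[1, ], 10, 250), 1, tolerance = 0.01)
  # 200 Hz component (alias target 50 Hz) attenuated > 20 dB
  expect_lt(band_power(out$data[2, ], 45, 55, 250) /
              band_power(rec$data[2, ], 195, 205, 1000) * 4, 0.01)
  # identity and upsampling contracts
  expect_identical(resample_recording(rec, 1000), rec)
  expect_error(resample_recording(rec, 2000), "unsupported")
})

test_that("zero-phase bandpass removes DC, keeps 50 Hz, rejects 120 Hz", {
  n <- 60000                       # 60 s: several high-pass time constants
  t <- (0:(n - 1)) / 1000
  rec <- new_recording(rbind(rep(5, n),
                             sin(2 * pi * 50 * t),
                             sin(2 * pi * 120 * t)),
                       c("dc", "mid", "high"), fs = 1000)
  out <- bandpass_recording(rec, filter_config(low = 0.1, high = 100))
  mid <- 20000:40000               # interior, clear of edge transients
  expect_lt(abs(mean(out$data[1, mid])), 0.05 * 5)
  expect_equal(sine_amp(out$data[2, mid], 50, 1000), 1, tolerance = 0.05)
  expect_lt(sine_amp(out$data[3, mid], 120, 1000), 0.5)
  expect_error(bandpass_recording(
    new_recording(matrix(0, 1, 100), "a", fs = 150), filter_config()),
    "Nyquist")
})

test_that("line-noise removal notches 60 Hz and its harmonic, not neighbors", {
  set.seed(6)
  n <- 20 * 1000
  t <- (0:(n - 1)) / 1000
  pink <- generate_participant_noise(1, 20, 1000, 1, seed = 6)[1, ]
  x <- pink + 20 * sin(2 * pi * 60 * t) + 8 * sin(2 * pi * 120 * t)
  rec <- new_recording(rbind(x, pink), c("noisy", "clean"), fs = 1000)
  out <- remove_line_noise(rec, 60)
  drop60 <- band_power(out$data[1, ], 59.5, 60.5, 1000) /
    band_power(rec$data[1, ], 59.5, 60.5, 1000)
  expect_lt(drop60, 0.01)                          # >= 20 dB
  drop120 <- band_power(out$data[1, ], 119.5, 120.5, 1000) /
    band_power(rec$data[1, ], 119.5, 120.5, 1000)
  expect_lt(drop120, 0.01)
  # neighbors within +/- 2 Hz change < 5%
  for (bb in list(c(57, 58.5), c(61.5, 63))) {
    ratio <- band_power(out$data[1, ], bb[1], bb[2], 1000) /
      band_power(rec$data[1, ], bb[1], bb[2], 1000)
    expect_equal(ratio, 1, tolerance = 0.05)
  }
  # a channel without line content is changed < 2%
  expect_equal(band_power(out$data[2, ], 1, 100, 1000) /
                 band_power(rec$data[2, ], 1, 100, 1000), 1,
               tolerance = 0.02)
})

test_that("median reference removes common offsets and resists artifacts", {
  g <- tiny_session(seed = 8, duration_s = 10,
                    montage = c("C3", "C4", "Cz", "Pz", "PO9"))
  s <- g$session
  s$recordings$P1$kinds[5] <- "EOG"
  eog_before <- s$recordings$P1$data[5, ]
  s$recordings$P1$data[1:4, ] <- s$recordings$P1$data[1:4, ] + 10
  out <- average_reference(s)
  # common +10 uV offset removed from EEG channels
  expect_lt(abs(mean(out$recordings$P1$data[1:4, ])), 0.5)
  # EOG untouched
  expect_identical(out$recordings$P1$data[5, ], eog_before)
  # one huge artifact perturbs others less than under a plain mean
  s2 <- g$session
  s2$recordings$P1$data[1, 50] <- s2$recordings$P1$data[1, 50] + 1e4
  out2 <- average_reference(s2)
  mean_ref_shift <- 1e4 / 5
  shift <- abs(out2$recordings$P1$data[2, 50] -
                 (s2$recordings$P1$data[2, 50] -
                    median(s2$recordings$P1$data[, 50])))
  expect_lt(abs(out2$recordings$P1$data[2, 50] -
                  g$session$recordings$P1$data[2, 50]),
            mean_ref_shift / 10)
  d1 <- data.frame(trial = 1, segment = 1, start = 0, end = 1)
  d1$active <- list(c("P1", "P2"))
  single <- new_session(list(
    new_recording(matrix(0, 1, 10), "a", fs = 10, participant_id = "P1"),
    new_recording(matrix(0, 1, 10), "a", fs = 10, participant_id = "P2")), d1)
  expect_error(average_reference(single), "2 EEG")
})

test_that("H-infinity cancellation removes blinks and bias, keeps brain rhythm", {
  set.seed(5)
  fs <- 250; n <- 60 * fs
  eog <- rnorm(n, sd = 5)
  rec <- new_recording(rbind(rnorm(n, sd = 10), eog), c("C3", "PO9"),
                       c("EEG", "EOG"), fs)
  rec <- inject_eog_artifacts(rec, blink_rate = 12, seed = 9)
  brain <- 8 * sin(2 * pi * 10 * (1:n) / fs)
  rec$data[1, ] <- brain + rnorm(n, sd = 2) + 0.3 * rec$data[2, ] + 15
  data_before <- rec$data
  out <- hinf_eog_removal(rec, store_weights = TRUE)
  keep <- (10 * fs):n                  # post-convergence portion
  resid_before <- rec$data[1, keep] - brain[keep]
  resid_after <- out$recording$data[1, keep] - brain[keep]
  red <- 1 - band_power(resid_after, 0.1, 6, fs) /
    band_power(resid_before, 0.1, 6, fs)
  expect_gt(red, 0.9)
  # co-present 10 Hz oscillation retained within 5%
  expect_equal(sine_amp(out$recording$data[1, keep], 10, fs),
               sine_amp(rec$data[1, keep], 10, fs), tolerance = 0.05)
  # recovered mixing weight near the true 0.3; bias mostly absorbed
  expect_equal(unname(out$weights["PO9", "C3"]), 0.3, tolerance = 0.1)
  # the 15 uV offset is largely absorbed by the bias weight at steady state
  expect_lt(abs(mean(out$recording$data[1, (n - 10 * fs):n])), 0.3 * 15)
  # weight trajectories stay finite
  expect_true(all(is.finite(out$weight_trajectory), na.rm = TRUE))
  # purity: the input recording is untouched
  expect_identical(rec$data, data_before)
})

test_that("H-infinity with no EOG channels is the identity; bad gamma errors", {
  rec <- new_recording(matrix(rnorm(500), 2), c("A", "B"), fs = 250)
  out <- hinf_eog_removal(rec)
  expect_identical(out$recording$data, rec$data)
  expect_null(out$weights)
  expect_error(hinf_config(gamma = 0.9), "gamma")
  # an inadmissibly aggressive bound fails naming the sample
  rec2 <- new_recording(rbind(rnorm(500), 200 * rnorm(500)), c("A", "V"),
                        c("EEG", "EOG"), fs = 250)
  expect_error(hinf_eog_removal(rec2, hinf_config(gamma = 1.0001, p0 = 1e-2)),
               "sample")
})

test_that("the full chain runs in order and logs provenance", {
  g <- tiny_session(seed = 10, duration_s = 12, fs = 1000,
                    montage = c("C3", "C4", "Cz", "PO9"))
  s <- g$session
  for (p in names(s$recordings)) s$recordings[[p]]$kinds[4] <- "EOG"
  out <- preprocess_session(s, preprocess_config())
  expect_equal(session_fs(out), 250)
  stages <- vapply(out$provenance, `[[`, character(1), "stage")
  expect_equal(stages[-1], c("resample", "bandpass", "line_noise",
                             "reference", "hinf"))
  # purity: original session untouched
  expect_equal(session_fs(s), 1000)
})
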