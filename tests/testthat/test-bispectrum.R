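test_that("window extraction counts, arithmetic and DFT peaks", {
  rec <- tone_recording(10, fs = 250, duration_s = 300)
  w <- extract_windows(rec, "ch1")
  expect_equal(w$L, 297L)                       # floor((300-4)/1)+1
  rec4 <- tone_recording(10, fs = 250, duration_s = 4)
  expect_equal(extract_windows(rec4, "ch1")$L, 1L)
  expect_error(extract_windows(tone_recording(10, 250, 2), "ch1"), "window")
  # a pure 10 Hz tone peaks at the 10 Hz bin of every window
  mags <- Mod(w$spectra)
  peak_bin <- apply(mags[2:500, ], 2, which.max) + 1L
  expect_true(all(peak_bin == 10 * 4 + 1))
})

test_that("vectorized estimator matches the naive triple-product oracle", {
  set.seed(21)
  fs <- 128; n <- 512; L <- 6
  xa <- matrix(rnorm(n * L), n, L)
  xb <- matrix(rnorm(n * L), n, L)
  bins <- seq(1, 30, by = 0.25)
  got <- diagonal_cross_bispectrum(as_window_set(xa, fs),
                                   as_window_set(xb, fs), bins)$value
  want <- naive_diagonal_bispectrum(xa, xb, fs, bins)
  expect_lt(max(abs(got - want) / want), 1e-10)
})

test_that("time-shift invariance and participant scaling laws hold", {
  set.seed(22)
  fs <- 250; n <- 1000
  base <- rowSums(vapply(c(5, 10, 20, 35), function(f)
    cos(2 * pi * f * (0:(n - 1)) / fs + runif(1, 0, 2 * pi)),
    numeric(n)))
  xa <- matrix(base + 0.5 * cos(2 * pi * 15 * (0:(n - 1)) / fs), ncol = 1)
  xb <- matrix(rev(base) + cos(2 * pi * 30 * (0:(n - 1)) / fs), ncol = 1)
  bins <- seq(1, 50, 0.25)
  b0 <- diagonal_cross_bispectrum(as_window_set(xa, fs),
                                  as_window_set(xb, fs), bins)$value
  sh <- 137   # same circular shift for both participants
  rot <- function(x) matrix(c(x[-(1:sh), 1], x[1:sh, 1]), ncol = 1)
  b1 <- diagonal_cross_bispectrum(as_window_set(rot(xa), fs),
                                  as_window_set(rot(xb), fs), bins)$value
  sel <- b0 > 1e-9 * max(b0)   # bins that are zero up to roundoff carry no
                               # information about the relative symmetry
  expect_lt(max(abs(b1[sel] - b0[sel]) / b0[sel]), 1e-9)
  # alpha on a scales linearly; beta on b scales quadratically
  b2 <- diagonal_cross_bispectrum(as_window_set(2 * xa, fs),
                                  as_window_set(3 * xb, fs), bins)$value
  expect_lt(max(abs(b2[sel] - 2 * 3^2 * b0[sel]) / b2[sel]), 1e-9)
  # all-zero input gives zero everywhere
  z <- as_window_set(matrix(0, n, 2), fs)
  expect_true(all(diagonal_cross_bispectrum(z, z, bins)$value == 0))
})

test_that("independent Gaussian dyads have vanishing bispectra", {
  set.seed(23)
  fs <- 250; n <- 1000
  coupled <- coupled_component_pair(n * 1000, fs, 10, rho = 1,
                                    epoch_s = 4, bandwidth = 0, amp = 1)
  wa <- as_window_set(matrix(coupled$a, n), fs)
  wb <- as_window_set(matrix(coupled$b, n), fs)
  coupled_val <- diagonal_cross_bispectrum(wa, wb, bins = 10)$value
  # Gaussian noise at matched per-channel power, L = 1000 windows
  pa <- sd(coupled$a); pb <- sd(coupled$b)
  ga <- as_window_set(matrix(rnorm(n * 1000, sd = pa), n), fs)
  gb <- as_window_set(matrix(rnorm(n * 1000, sd = pb), n), fs)
  gauss_val <- diagonal_cross_bispectrum(ga, gb, bins = 10)$value
  expect_lt(gauss_val, 0.1 * coupled_val)
})

test_that("Gaussian-null magnitude decays as 1/sqrt(L)", {
  set.seed(24)
  mean_mag <- function(L) {
    mean(replicate(3, {
      wa <- as_window_set(matrix(rnorm(1000 * L), 1000, L), 250)
      wb <- as_window_set(matrix(rnorm(1000 * L), 1000, L), 250)
      mean(diagonal_cross_bispectrum(wa, wb)$value)
    }))
  }
  Ls <- c(10, 100, 1000)
  m <- vapply(Ls, mean_mag, numeric(1))
  slope <- unname(coef(lm(log(m) ~ log(Ls)))[2])
  expect_equal(slope, -0.5, tolerance = 0.1)
})

test_that("segment representation equals the single-window case at 4 s", {
  g <- tiny_session(seed = 25, duration_s = 60,
                    coupling = list(rho = 1, f0 = 10, bandwidth = 0,
                                    channel_pairs = list(c("C3", "C4"))))
  s <- g$session
  iv <- segment_interval(s, 1, 1)
  seg <- segment_representation(s, c("P1", "P2"), c("C3", "C4"), 1, 1)
  expect_equal(seg$L, 57L)
  # restrict to exactly one window: equals the direct L = 1 computation
  s4 <- s
  s4$design$end <- s4$design$start + 4
  one <- segment_representation(s4, c("P1", "P2"), c("C3", "C4"), 1, 1)
  wa <- extract_windows(s$recordings$P1, "C3", interval = iv + c(0, 4 - diff(iv)))
  wb <- extract_windows(s$recordings$P2, "C4", interval = iv + c(0, 4 - diff(iv)))
  direct <- diagonal_cross_bispectrum(wa, wb)
  expect_equal(one$value, direct$value)
  expect_equal(one$L, 1L)
  # the two dyad orderings give different values (asymmetric convention)
  rev_seg <- segment_representation(s, c("P2", "P1"), c("C4", "C3"), 1, 1)
  expect_false(isTRUE(all.equal(seg$value, rev_seg$value)))
  # fully masked segment errors
  sm <- mask_missing(s, iv)
  expect_error(segment_representation(sm, c("P1", "P2"), c("C3", "C4"), 1, 1),
               "empty segment")
})

test_that("rest normalization obeys the relative-change identities", {
  g <- tiny_session(seed = 26, duration_s = 20)
  eo <- baseline_representation(g$session, c("P1", "P2"), c("C3", "C4"))
  same <- normalize_bispectrum(eo, eo)
  expect_true(all(same$value == 0))
  up <- eo
  up$value <- 1.3 * eo$value
  expect_equal(normalize_bispectrum(up, eo)$value,
               rep(0.3, length(eo$freq)), tolerance = 1e-12)
  # zero-baseline bins are flagged invalid, not divided
  eo0 <- eo
  eo0$value[5] <- 0
  nb <- normalize_bispectrum(up, eo0)
  expect_true(is.na(nb$value[5]))
  expect_false(anyNA(nb$value[-5]))
  # axis mismatch is an alignment error
  short <- eo; short$freq <- eo$freq[-1]; short$value <- eo$value[-1]
  expect_error(normalize_bispectrum(up, short), "alignment")
})

test_that("band sampling counts and averages match the native grid", {
  counts <- vapply(eeg_bands()$band, band_samples, integer(1))
  expect_equal(unname(counts), c(16L, 16L, 20L, 68L, 82L))
  expect_equal(length(native_bins()), 197L)
  # uniform normalized value c averages to c in every band
  nb <- structure(list(freq = native_bins(),
                       value = rep(0.17, 197)),
                  class = "normalized_bispectrum")
  expect_equal(unname(band_average(nb)), rep(0.17, 5))
  expect_equal(band_average(nb, "beta"), 0.17)
  # the 1-Hz summary grid has 50 bins spanning 1-50 Hz
  sb <- summary_bins(nb)
  expect_equal(length(sb$value), 50L)
  expect_equal(range(sb$freq), c(1, 50))
})

test_that("temporal series tracks coupling steps on a 1-s grid", {
  ev <- data.frame(type = "SP", time = 260, rho_delta = 0.8)
  g <- tiny_session(seed = 27, duration_s = 280,
                    coupling = list(rho = 0.1, f0 = 35, bandwidth = 10,
                                    channel_pairs = list(c("C3", "C4"))),
                    event_schedule = ev, event_duration_s = 19)
  tr <- temporal_series(g$session, c("P1", "P2"), c("C3", "C4"), "gamma")
  expect_s3_class(tr, "bispectrum_trace")
  expect_equal(unique(round(diff(tr$time), 9)), 1)
  # mean after the (amplitude-carrying) step exceeds the mean before
  post <- tr$value[tr$time >= 257 & tr$time < 277]
  pre <- tr$value[tr$time >= 150 & tr$time < 250]
  expect_gt(mean(post), mean(pre))
})
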