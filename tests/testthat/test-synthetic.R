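test_that("background noise has the requested spectral slope", {
  # white limit: flat average periodogram
  x <- generate_participant_noise(4, 30, 250, noise_exponent = 0, seed = 1)
  expect_equal(rowMeans(x), rep(0, 4), tolerance = 1e-12)
  lowp <- mean(apply(x, 1, band_power, lo = 2, hi = 20, fs = 250))
  highp <- mean(apply(x, 1, band_power, lo = 100, hi = 118, fs = 250))
  expect_equal(lowp / highp, 18 / 18, tolerance = 0.25)
  # pink: log-log periodogram slope about -1 over 2-40 Hz
  y <- generate_participant_noise(2, 60, 250, noise_exponent = 1, seed = 2)
  slope <- mean(apply(y, 1, function(ch) {
    n <- length(ch)
    P <- Mod(fft(ch))^2
    fr <- (0:(n - 1)) * 250 / n
    sel <- fr >= 2 & fr <= 40
    # smooth periodogram in octave bands before fitting
    lf <- log(fr[sel]); lp <- log(P[sel])
    unname(coef(lm(lp ~ lf))[2])
  }))
  expect_equal(slope, -1, tolerance = 0.2)
})

test_that("identical seeds give bitwise-identical noise and sessions", {
  expect_identical(generate_participant_noise(3, 10, 250, 1, seed = 7),
                   generate_participant_noise(3, 10, 250, 1, seed = 7))
  g1 <- tiny_session(seed = 42, duration_s = 20)
  g2 <- tiny_session(seed = 42, duration_s = 20)
  expect_identical(g1$session, g2$session)
  expect_identical(g1$truth, g2$truth)
  expect_error(generate_participant_noise(2, -1, 250), "invalid")
})

test_that("pure coupled tones reproduce the analytic triple product", {
  set.seed(1)
  comp <- coupled_component_pair(1000, 250, 10, rho = 1, epoch_s = 4,
                                 bandwidth = 0, amp = 2)
  wa <- as_window_set(matrix(comp$a, ncol = 1), 250)
  wb <- as_window_set(matrix(comp$b, ncol = 1), 250)
  b <- diagonal_cross_bispectrum(wa, wb, bins = 10)
  # |X| = amp * N/2 at the exact bin for each of the three factors
  expect_equal(b$value, (2 * 500)^3, tolerance = 1e-9)
})

test_that("coupling strength orders the mean bispectrum (rho monotonicity)", {
  set.seed(7)
  rhos <- c(0, 0.25, 0.5, 0.75, 1)
  one_realization <- function(r, L = 256) {
    comp <- coupled_component_pair(L * 250, 250, 10, r, epoch_s = 1,
                                   bandwidth = 0, amp = 6.3)
    xa <- matrix(comp$a + rnorm(L * 250, sd = 20), 250, L)
    xb <- matrix(comp$b + rnorm(L * 250, sd = 20), 250, L)
    diagonal_cross_bispectrum(as_window_set(xa, 250),
                              as_window_set(xb, 250), bins = 10)$value
  }
  pool <- do.call(rbind, lapply(rhos, function(r)
    data.frame(rho = r, v = replicate(40, one_realization(r)))))
  m <- tapply(pool$v, pool$rho, mean)
  expect_true(all(diff(m) > 0))
  ct <- cor.test(pool$rho, pool$v, method = "spearman",
                 alternative = "greater", exact = FALSE)
  expect_lt(ct$p.value, 0.01)
  # rho = 0.8 beats rho = 0.2 on the same seed family
  set.seed(11)
  v8 <- mean(replicate(20, one_realization(0.8, L = 64)))
  set.seed(11)
  v2 <- mean(replicate(20, one_realization(0.2, L = 64)))
  expect_gt(v8, v2)
})

test_that("with rho 0 participants are statistically independent", {
  # white background: the 3/sqrt(N) bound presumes short-memory noise
  g <- tiny_session(seed = 13, duration_s = 30, noise_exponent = 0)
  a <- g$session$recordings$P1$data[1, ]
  b <- g$session$recordings$P2$data[1, ]
  n <- length(a)
  for (lag in c(0, 1, 5, 25)) {
    r <- cor(a[1:(n - lag)], b[(1 + lag):n])
    expect_lt(abs(r), 3 / sqrt(n - lag))
  }
})

test_that("blink injection matches the Poisson schedule and frontal mixing", {
  rec <- new_recording(matrix(0, 3, 60 * 250), c("Fp1", "O1", "PO9"),
                       c("EEG", "EEG", "EOG"), fs = 250)
  out <- inject_eog_artifacts(rec, blink_rate = 12, seed = 3)
  truth <- attr(out, "blink_truth")
  # threshold oracle on the EOG channel: count template peaks
  above <- out$data[3, ] > 75
  n_detected <- sum(diff(c(FALSE, above)) == 1)
  expect_equal(n_detected, length(truth$times))
  expect_gt(length(truth$times), qpois(0.005, 12))
  expect_lt(length(truth$times), qpois(0.995, 12))
  # frontal channels carry more artifact than occipital
  expect_gt(sum(out$data[1, ]^2), 10 * sum(out$data[2, ]^2))
  # rate 0 is the identity; negative rates are rejected
  expect_identical(inject_eog_artifacts(rec, 0), rec)
  expect_error(inject_eog_artifacts(rec, -1), "invalid")
  expect_error(inject_eog_artifacts(
    new_recording(matrix(0, 1, 100), "Cz", fs = 250), 5), "EOG")
})

test_that("default design has 9 intervals with rotating first entries", {
  cfg <- synthetic_config(fs = 250, segment_s = 10, baseline_s = 5,
                          montage = c("C3", "C4", "T7", "O1"),
                          eog_labels = character(0), seed = 1)
  g <- generate_session(cfg)
  d <- g$session$design
  expect_equal(nrow(d), 9L)
  firsts <- vapply(split(d, d$trial),
                   function(x) x$active[[which.min(x$segment)]][1],
                   character(1))
  expect_setequal(firsts, c("P1", "P2", "P3"))
  # third segment has all three active
  expect_equal(sort(d$active[[3]]), c("P1", "P2", "P3"))
  expect_equal(nrow(g$session$baselines), 4L)
  # dyad conditions follow the staggered entry
  expect_equal(dyad_condition(g$session, c("P1", "P2"), d$start[1] + 1),
               "passive-active")
  expect_equal(dyad_condition(g$session, c("P2", "P3"), d$start[1] + 1),
               "passive-passive")
  expect_equal(dyad_condition(g$session, c("P2", "P3"), d$start[3] + 1),
               "active-active")
})

test_that("SP events step the true coupling lead_time seconds early", {
  ev <- data.frame(type = "SP", time = 440, rho_delta = 0.5)
  g <- tiny_session(seed = 2, duration_s = 400,
                    coupling = list(rho = 0.2, f0 = 10, bandwidth = 0,
                                    channel_pairs = list(c("C3", "C4"))),
                    event_schedule = ev, lead_time_s = 3)
  rho <- g$truth$rho
  step <- rho[rho$rho > 0.2, ]
  expect_equal(step$start, 437)        # 440 - 3
  expect_equal(step$end, 460)          # 440 + event_duration_s
  expect_equal(step$rho, 0.7)
  expect_equal(g$truth$events$onset, 437)
  # truth intervals tile the segment without overlap
  expect_equal(min(rho$start), 120)
  expect_equal(max(rho$end), 520)
  o <- order(rho$start)
  expect_true(all(abs(rho$end[o][-nrow(rho)] - rho$start[o][-1]) < 1e-9))
  # scheduling an event outside the session is a range error
  expect_error(tiny_session(seed = 2, duration_s = 100,
                            event_schedule = data.frame(type = "SP",
                                                        time = 1e4,
                                                        rho_delta = 0.5)),
               "range")
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(coupling = list(rho = 1.2)), "rho")
  expect_error(synthetic_config(coupling = list(rho = 0.5, f0 = 300)),
               "Nyquist")
  expect_error(synthetic_config(segment_s = -5), "positive")
  expect_error(synthetic_config(blink_rate = -1), "blink_rate")
  expect_error(inject_coupled_component(
    tiny_session(seed = 1, duration_s = 20)$session, c("P1", "P2"),
    c("nope", "C4"), 10, 0.5, c(0, 10)), "missing channel")
  expect_error(inject_coupled_component(
    tiny_session(seed = 1, duration_s = 20)$session, c("P1", "P2"),
    c("C3", "C4"), 10, 0.5, c(0, 1e4)), "range")
})
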