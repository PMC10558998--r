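test_that("signed-rank test handles clean shifts, degeneracy and errors", {
  set.seed(31)
  rest <- runif(68)
  w <- wilcoxon_right(rest + 1, rest)
  expect_lt(w$p, 1e-5)                # all 68 differences positive
  expect_equal(w$median_diff, 1)
  same <- wilcoxon_right(rest, rest)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  expect_error(wilcoxon_right(1:5, 1:6), "alignment")
})

test_that("signed-rank type-I error is nominal under the null", {
  set.seed(32)
  n_tests <- 4000
  rej <- mean(replicate(n_tests, {
    a <- rnorm(20); b <- rnorm(20)
    wilcoxon_right(a, b)$p < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("scan bookkeeping reproduces the full design counts", {
  ct <- count_scan_tests()
  expect_equal(ct$per_family, 3600)
  expect_equal(ct$total, 486000)
  # 60 analysis channels = 64-channel montage minus 4 EOG-repurposed
  montage <- acticap64_labels()
  expect_equal(length(montage), 64L)
  expect_equal(length(setdiff(montage, default_eog_labels())), 60L)
})

test_that("a desk-scale scan has one test per ordered channel combination", {
  g <- generate_session(scenario_null_config(101))
  res <- scan_combinations(g$session, 1, 1, c("P1", "P2"), bands = "gamma")
  expect_equal(nrow(res), 16^2)
  expect_equal(unique(res$alpha_corrected), 0.05 / 256)
  expect_equal(unique(res$n), 82L)    # gamma band bins
  expect_true(all(res$significant == (res$p < res$alpha_corrected)))
  # Bonferroni monotonicity: corrected set within the uncorrected set
  expect_true(all(which(res$significant) %in% which(res$p < 0.05)))
})

test_that("planted coupling is recovered and nulls stay quiet", {
  pw <- scenario_power_run(7)
  expect_gte(pw$recovered, 4)
  expect_equal(scenario_null_run(7), 0)
})

test_that("summaries count by group and respect ground-truth ordering", {
  pw <- scenario_power_run(8)
  res <- pw$results
  # fabricate a second band's rows as non-significant to check grouping
  res2 <- res
  res2$band <- "delta"
  res2$significant <- FALSE
  both <- rbind(res, res2)
  class(both) <- class(res)
  sm <- summarize_significance(both, "band")
  expect_equal(sm$n_significant[sm$band == "delta"], 0)
  expect_equal(sm$n_significant[sm$band == "gamma"], sum(res$significant))
  expect_equal(attr(sm, "total"), sum(both$significant))
  expect_error(summarize_significance(both, "nope"), "unknown grouping")
  # all-non-significant input gives all-zero counts
  none <- res; none$significant <- FALSE
  expect_true(all(summarize_significance(none, "band")$n_significant == 0))
})

test_that("top-k ranking is deterministic with documented tie-breaks", {
  df <- data.frame(dyad = "P1-P2", chan_a = c("C3", "C4", "A1", "A2"),
                   chan_b = c("X", "X", "X", "X"),
                   trial = 1, segment = 1, band = "gamma", n = 82,
                   p = c(0.001, 0.001, 0.0005, 0.2),
                   median_diff = c(2, 5, 1, 9),
                   alpha_corrected = 0.01,
                   significant = c(TRUE, TRUE, TRUE, FALSE))
  tk <- top_k(df, 5)
  expect_equal(nrow(tk), 3L)                       # no padding
  expect_equal(tk$chan_a, c("A1", "C4", "C3"))     # p, then larger diff
  expect_equal(nrow(top_k(df[df$p > 0.1, , drop = FALSE], 3)), 0L)
  expect_error(top_k(df, 0), "k must be")
})

test_that("active-musician grouping follows the staggered design", {
  # coupling on all dyads; only active-active segments carry it
  cfg <- synthetic_config(
    n_participants = 3, montage = c("T7", "O1", "Cz", "Pz"),
    eog_labels = character(0), fs = 250, segment_s = 60, baseline_s = 60,
    inter_trial_gap_s = 5, n_trials = 1,
    coupling = list(rho = 0.9, f0 = 35, bandwidth = 10,
                    channel_pairs = list(c("T7", "O1"))),
    seed = 33)
  g <- generate_session(cfg)
  res <- scan_session(g$session, bands = "gamma")
  sm <- summarize_significance(res, "n_active", g$session)
  counts <- setNames(sm$n_significant, sm$n_active)
  # more active musicians, more significant synchrony
  expect_gt(counts[["3"]], counts[["2"]])
  expect_gte(counts[["2"]], counts[["1"]])
})
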