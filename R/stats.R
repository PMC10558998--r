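#' Right-tailed Wilcoxon signed-rank test on paired band bins
#'
#' Tests whether segment values exceed rest values (alternative
#' "segment > rest") across the paired per-bin band samples. Zero
#' differences are dropped per the standard signed-rank convention; if every
#' difference is zero the result is degenerate with p = 1. The normal
#' approximation with continuity correction is used (band samples have
#' 16-82 bins).
#'
#' @param seg_values,rest_values equal-length paired numeric vectors
#'   (per-bin values within one band).
#' @return list with `p` (one-sided p-value), `n` (paired bins used),
#'   `median_diff`, `degenerate`.
#' @export
wilcoxon_right <- function(seg_values, rest_values) {
  if (length(seg_values) != length(rest_values))
    stop("alignment error: paired vectors differ in length")
  ok <- !is.na(seg_values) & !is.na(rest_values)
  seg_values <- seg_values[ok]; rest_values <- rest_values[ok]
  d <- seg_values - rest_values
  if (length(d) == 0L || all(d == 0))
    return(list(p = 1, n = length(d), median_diff = 0, degenerate = TRUE))
  p <- suppressWarnings(
    wilcox.test(seg_values, rest_values, paired = TRUE,
                alternative = "greater", exact = FALSE,
                correct = TRUE)$p.value)
  list(p = p, n = length(d), median_diff = median(d), degenerate = FALSE)
}

## Per-bin magnitude array |B(f; a, b)| for all ordered channel combinations
## of a dyad over one interval: bins x channels_a x channels_b.
scan_bispectra <- function(session, dyad, channels_a, channels_b, interval,
                           bins = native_bins(), window_s = 4, step_s = 1) {
  ra <- session$recordings[[dyad[1]]]
  rb <- session$recordings[[dyad[2]]]
  wsa <- lapply(channels_a, function(ch)
    extract_windows(ra, ch, window_s, step_s, interval = interval,
                    mask = session$mask))
  wsb <- lapply(channels_b, function(ch)
    extract_windows(rb, ch, window_s, step_s, interval = interval,
                    mask = session$mask))
  check_aligned(wsa[[1]], wsb[[1]])
  i1 <- bin_indices(bins, wsa[[1]])
  i2 <- bin_indices(2 * bins, wsa[[1]])
  L <- wsa[[1]]$L
  La <- lapply(wsa, function(w) w$spectra[i1, , drop = FALSE])
  Lb <- lapply(wsb, function(w)
    w$spectra[i1, , drop = FALSE] * Conj(w$spectra[i2, , drop = FALSE]))
  nb <- length(bins)
  out <- array(NA_real_, c(nb, length(channels_a), length(channels_b)),
               dimnames = list(NULL, channels_a, channels_b))
  for (f in seq_len(nb)) {
    Af <- vapply(La, function(m) m[f, ], complex(L))      # L x nchA
    Bf <- vapply(Lb, function(m) m[f, ], complex(L))      # L x nchB
    out[f, , ] <- Mod(crossprod(Af, Bf)) / L
  }
  list(mag = out, L = L)
}

#' Scan all channel combinations of one analysis family
#'
#' Runs one right-tailed Wilcoxon signed-rank test per ordered
#' (channel of a, channel of b) combination over the dyad's scalp analysis
#' channels, comparing the segment's bispectral representation against the
#' pre-trial eyes-open rest baseline across the band's native bins. The
#' Bonferroni family is the set of combinations within one
#' (trial, segment, dyad, band): `alpha_corrected = alpha / n_combinations`
#' (0.05 / 3600 at the full 60-channel montage).
#'
#' @param session a `hyperscan_session`.
#' @param trial,segment design indices.
#' @param dyad length-2 character vector of participant ids.
#' @param bands band names (default all five).
#' @param channels analysis channel labels (default: all EEG-kind channels
#'   present in both recordings).
#' @param alpha family-wise significance level before correction.
#' @param bins,window_s,step_s estimation parameters.
#' @param eo_mag optional precomputed baseline magnitude array (from a
#'   previous scan; saves recomputing the rest representation per trial).
#' @return data.frame of class `significance_results` with one row per
#'   (combination, band): dyad, chan_a, chan_b, trial, segment, band, n, p,
#'   median_diff, alpha_corrected, significant.
#' @export
scan_combinations <- function(session, trial, segment, dyad,
                              bands = eeg_bands()$band, channels = NULL,
                              alpha = 0.05, bins = native_bins(),
                              window_s = 4, step_s = 1, eo_mag = NULL) {
  if (is.null(channels)) {
    channels <- intersect(eeg_channels(session$recordings[[dyad[1]]]),
                          eeg_channels(session$recordings[[dyad[2]]]))
  }
  iv <- segment_interval(session, trial, segment)
  seg <- scan_bispectra(session, dyad, channels, channels, iv, bins,
                        window_s, step_s)
  if (is.null(eo_mag)) {
    eo <- scan_bispectra(session, dyad, channels, channels,
                         baseline_interval(session, "pre", "EO"), bins,
                         window_s, step_s)
    eo_mag <- eo$mag
  }
  bd <- eeg_bands()
  n_comb <- length(channels)^2
  alpha_corrected <- alpha / n_comb
  rows <- vector("list", n_comb * length(bands))
  ri <- 0L
  for (band in bands) {
    bi <- match(band, bd$band)
    if (is.na(bi)) stop("unknown band: ", band)
    sel <- bins >= bd$low[bi] & bins < bd$high[bi]
    for (a in seq_along(channels)) {
      for (b in seq_along(channels)) {
        w <- wilcoxon_right(seg$mag[sel, a, b], eo_mag[sel, a, b])
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          dyad = paste(dyad, collapse = "-"),
          chan_a = channels[a], chan_b = channels[b],
          trial = trial, segment = segment, band = band,
          n = w$n, p = w$p, median_diff = w$median_diff,
          alpha_corrected = alpha_corrected,
          significant = w$p < alpha_corrected,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("significance_results", "data.frame")
  out
}

#' Full-design significance scan
#'
#' Sweeps [scan_combinations()] over trials, segments and dyads, reusing
#' each dyad's rest baseline representation across trials and segments.
#'
#' @param session a `hyperscan_session`.
#' @param dyads list of dyads (default all).
#' @param trials,segments design indices (default all in the design).
#' @param bands,channels,alpha,bins,window_s,step_s see
#'   [scan_combinations()].
#' @return a `significance_results` data.frame.
#' @export
scan_session <- function(session, dyads = NULL, trials = NULL,
                         segments = NULL, bands = eeg_bands()$band,
                         channels = NULL, alpha = 0.05,
                         bins = native_bins(), window_s = 4, step_s = 1) {
  if (is.null(dyads)) dyads <- session_dyads(session)
  if (is.null(trials)) trials <- unique(session$design$trial)
  if (is.null(segments)) segments <- unique(session$design$segment)
  out <- list()
  for (dy in dyads) {
    ch <- channels
    if (is.null(ch))
      ch <- intersect(eeg_channels(session$recordings[[dy[1]]]),
                      eeg_channels(session$recordings[[dy[2]]]))
    eo <- scan_bispectra(session, dy, ch, ch,
                         baseline_interval(session, "pre", "EO"), bins,
                         window_s, step_s)
    for (t in trials) for (s in segments) {
      out[[length(out) + 1L]] <-
        scan_combinations(session, t, s, dy, bands, ch, alpha, bins,
                          window_s, step_s, eo_mag = eo$mag)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("significance_results", "data.frame")
  res
}

#' Count significant combinations by group
#'
#' @param results a `significance_results` data.frame.
#' @param group_by grouping keys among `"band"`, `"dyad"`, `"trial"`,
#'   `"segment"`, `"n_active"` (the last needs `session`).
#' @param session required when grouping by `"n_active"`: the number of
#'   active participants is derived from the segment design.
#' @return data.frame of group counts; the total significant count is
#'   attached as attribute `"total"`.
#' @export
summarize_significance <- function(results, group_by = "band",
                                   session = NULL) {
  if (nrow(results) == 0L) stop("empty results")
  allowed <- c("band", "dyad", "trial", "segment", "n_active")
  if (!all(group_by %in% allowed))
    stop("invalid argument: unknown grouping key '",
         setdiff(group_by, allowed)[1], "'")
  if ("n_active" %in% group_by) {
    if (is.null(session))
      stop("grouping by n_active requires the session design")
    results$n_active <- mapply(function(t, s) n_active(session, t, s),
                               results$trial, results$segment)
  }
  keys <- results[group_by]
  agg <- aggregate(results$significant, by = keys, FUN = sum)
  names(agg) <- c(group_by, "n_significant")
  attr(agg, "total") <- sum(results$significant)
  agg
}

#' Top-k most significant combinations
#'
#' The k smallest p-values among significant results; ties broken by larger
#' median paired difference, then lexicographically by channel labels, so
#' the ranking is deterministic across runs.
#'
#' @param results a `significance_results` data.frame.
#' @param k maximum rows to return (>= 1).
#' @return the ranked subset (possibly shorter than k; no padding).
#' @export
top_k <- function(results, k) {
  if (k < 1) stop("invalid argument: k must be >= 1")
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(sig)
  ord <- order(sig$p, -sig$median_diff, sig$chan_a, sig$chan_b)
  head(sig[ord, , drop = FALSE], k)
}
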