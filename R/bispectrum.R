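## Diagonal cross-bispectrum estimation.
##
## Convention for B(f, f | dyad a->b): factor 1 is participant a's channel at
## f, factors 2 and 3 are participant b's channel at f and (conjugated) 2f:
##   B(f) = | (1/L) sum_l X_al(f) X_bl(f) X*_bl(2f) |
## One factor per "sender", the nonlinear closure on the "receiver". The
## convention is asymmetric: swapping roles changes the value, and scaling
## a's channel by alpha scales B by alpha while scaling b's by beta scales B
## by beta^2.

#' Canonical EEG band definitions
#'
#' Nominal ranges delta 1-4, theta 4-7, alpha 8-12, beta 13-29, gamma
#' 30-50 Hz. The half-open sampling intervals used to collect native
#' 0.25-Hz bins are fixed as delta [1,5), theta [4,8), alpha [8,13),
#' beta [13,30), gamma [29.75,50.25): the unique half-open readings giving
#' the per-band sample counts 16/16/20/68/82 on the 1-50 Hz diagonal grid
#' (note the implied delta/theta and beta/gamma edge overlaps).
#'
#' @return data.frame with columns `band`, `nominal`, `low`, `high`.
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             nominal = c("1-4", "4-7", "8-12", "13-29", "30-50"),
             low = c(1, 4, 8, 13, 29.75),
             high = c(5, 8, 13, 30, 50.25),
             stringsAsFactors = FALSE)
}

#' Native diagonal frequency grid
#'
#' 4-second windows give 0.25 Hz resolution; the analyzed diagonal runs from
#' 1.00 to 50.00 Hz inclusive (197 bins).
#'
#' @param window_s analysis window length in seconds.
#' @param fmin,fmax grid limits in Hz.
#' @return numeric vector of bin frequencies.
#' @export
native_bins <- function(window_s = 4, fmin = 1, fmax = 50) {
  seq(fmin, fmax, by = 1 / window_s)
}

#' Number of native bins sampled by a band
#'
#' @param band band name (see [eeg_bands()]).
#' @param bins frequency grid (default native 0.25 Hz diagonal).
#' @return integer bin count (e.g. 68 for beta, 82 for gamma).
#' @export
band_samples <- function(band, bins = native_bins()) {
  bd <- eeg_bands()
  i <- match(band, bd$band)
  if (is.na(i)) stop("unknown band: ", band)
  sum(bins >= bd$low[i] & bins < bd$high[i])
}

#' Extract sliding spectral windows from one channel
#'
#' Four-second rectangular (untapered) windows advanced in one-second steps
#' (75% overlap); each window's spectrum is its raw discrete Fourier
#' transform. Windows overlapping a masked span are excluded. For an
#' unmasked span of `T` seconds the window count is
#' `floor((T - window_s) / step_s) + 1`.
#'
#' @param recording an `eeg_recording`.
#' @param channel channel label.
#' @param window_s,step_s window length and step in seconds.
#' @param interval optional half-open `c(start, end)` restriction (session
#'   seconds); defaults to the whole recording.
#' @param mask optional data.frame of masked spans (`start`, `end`).
#' @return an object of class `spectral_windows`: list with `starts`
#'   (window start times), `centers`, `spectra` (complex nfft x L matrix),
#'   `fs`, `nfft`, `window_s`, `step_s`, `L`.
#' @export
extract_windows <- function(recording, channel, window_s = 4, step_s = 1,
                            interval = NULL, mask = NULL) {
  fs <- recording$fs
  x <- rec_channel(recording, channel)
  dur <- length(x) / fs
  if (is.null(interval)) interval <- c(0, dur)
  interval <- c(max(interval[1], 0), min(interval[2], dur))
  if (interval[2] - interval[1] < window_s)
    stop("empty window set: span shorter than one window (",
         interval[2] - interval[1], " s < ", window_s, " s)")
  starts <- seq(interval[1], interval[2] - window_s, by = step_s)
  if (!is.null(mask) && nrow(mask) > 0L) {
    keep <- vapply(starts, function(s0)
      !any(mask$start < s0 + window_s & s0 < mask$end), logical(1))
    starts <- starts[keep]
  }
  if (length(starts) == 0L)
    stop("empty window set: all windows fall in masked spans")
  nfft <- round(window_s * fs)
  W <- vapply(starts, function(s0) {
    i0 <- round(s0 * fs) + 1L
    x[i0:(i0 + nfft - 1L)]
  }, numeric(nfft))
  spectra <- mvfft(W)
  structure(list(starts = starts, centers = starts + window_s / 2,
                 spectra = spectra, fs = fs, nfft = nfft,
                 window_s = window_s, step_s = step_s, L = length(starts)),
            class = "spectral_windows")
}

#' Wrap a samples x L matrix as a spectral window set
#'
#' Utility for simulation studies operating directly on independently drawn
#' windows (no sliding extraction).
#'
#' @param x numeric samples x L matrix (each column one window).
#' @param fs sampling frequency in Hz.
#' @param window_s window length in seconds (defaults to `nrow(x)/fs`).
#' @return a `spectral_windows` object.
#' @export
as_window_set <- function(x, fs, window_s = nrow(x) / fs) {
  L <- ncol(x)
  structure(list(starts = seq_len(L) - 1, centers = seq_len(L) - 1 + window_s / 2,
                 spectra = mvfft(x), fs = fs, nfft = nrow(x),
                 window_s = window_s, step_s = NA_real_, L = L),
            class = "spectral_windows")
}

check_aligned <- function(wa, wb) {
  if (wa$L != wb$L || wa$nfft != wb$nfft || wa$fs != wb$fs ||
      max(abs(wa$starts - wb$starts)) > 1e-9)
    stop("alignment error: window sets differ in starts, length or rate")
  invisible(TRUE)
}

bin_indices <- function(bins, ws) {
  res <- ws$fs / ws$nfft
  i1 <- bins / res
  if (max(abs(i1 - round(i1))) > 1e-6)
    stop("requested bins do not lie on the window frequency grid (",
         res, " Hz)")
  round(i1) + 1L
}

#' Diagonal cross-bispectrum of two aligned window sets
#'
#' Implements the windowed diagonal cross-bispectrum
#' `B(f) = |(1/L) sum_l X_al(f) X_bl(f) X*_bl(2f)|` between one channel of
#' participant a (`windows_a`) and one of participant b (`windows_b`). Bins
#' whose doubled frequency exceeds Nyquist are excluded with a warning. The
#' complex mean is retained alongside the magnitude for diagnostics.
#'
#' @param windows_a,windows_b `spectral_windows` objects, time-aligned
#'   (same starts, same L).
#' @param bins diagonal bin frequencies in Hz.
#' @param meta optional named list (dyad, channel_pair, trial, segment, ...)
#'   carried into the result.
#' @return an object of class `bispectrum`: list with `freq`, `value`
#'   (magnitudes, >= 0), `cmplx` (complex means), `L`, `meta`.
#' @export
diagonal_cross_bispectrum <- function(windows_a, windows_b,
                                      bins = native_bins(windows_a$window_s),
                                      meta = list()) {
  check_aligned(windows_a, windows_b)
  nyq <- windows_a$fs / 2
  bad <- bins * 2 > nyq
  if (any(bad)) {
    warning(sum(bad), " bins excluded: doubled frequency above Nyquist")
    bins <- bins[!bad]
  }
  i1 <- bin_indices(bins, windows_a)
  i2 <- bin_indices(2 * bins, windows_a)
  A <- windows_a$spectra[i1, , drop = FALSE]
  B <- windows_b$spectra[i1, , drop = FALSE] *
    Conj(windows_b$spectra[i2, , drop = FALSE])
  cm <- rowMeans(A * B)
  structure(list(freq = bins, value = Mod(cm), cmplx = cm,
                 L = windows_a$L, meta = meta),
            class = "bispectrum")
}

#' @export
print.bispectrum <- function(x, ...) {
  cat(sprintf("<bispectrum> %d bins (%.2f-%.2f Hz), L = %d windows\n",
              length(x$freq), min(x$freq), max(x$freq), x$L))
  invisible(x)
}

#' Bispectral representation of one (trial, segment)
#'
#' Averages the windowed diagonal cross-bispectrum over all four-second
#' windows of the segment (division by L, so intervals of different lengths
#' are comparable). Windows overlapping masked spans are excluded; a fully
#' masked segment is an error.
#'
#' @param session a `hyperscan_session`.
#' @param dyad length-2 character vector `(a, b)`; note the asymmetric
#'   convention (see [diagonal_cross_bispectrum()]).
#' @param channel_pair `c(channel of a, channel of b)`.
#' @param trial,segment design indices.
#' @param bins diagonal frequency grid.
#' @param window_s,step_s window parameters.
#' @return a `bispectrum` with segment metadata.
#' @export
segment_representation <- function(session, dyad, channel_pair, trial,
                                   segment, bins = NULL, window_s = 4,
                                   step_s = 1) {
  iv <- segment_interval(session, trial, segment)
  if (is.null(bins)) bins <- native_bins(window_s)
  wa <- tryCatch(
    extract_windows(session$recordings[[dyad[1]]], channel_pair[1],
                    window_s, step_s, interval = iv, mask = session$mask),
    error = function(e) stop("empty segment: trial ", trial, " segment ",
                             segment, ": ", conditionMessage(e)))
  wb <- extract_windows(session$recordings[[dyad[2]]], channel_pair[2],
                        window_s, step_s, interval = iv, mask = session$mask)
  diagonal_cross_bispectrum(wa, wb, bins,
                            meta = list(dyad = dyad,
                                        channel_pair = channel_pair,
                                        trial = trial, segment = segment))
}

#' Bispectral representation of a baseline block
#'
#' @param session a `hyperscan_session`.
#' @param dyad,channel_pair as in [segment_representation()].
#' @param phase,condition baseline selector; the pre-trial eyes-open block
#'   is the rest condition used for normalization.
#' @param bins,window_s,step_s as in [segment_representation()].
#' @return a `bispectrum` with baseline metadata.
#' @export
baseline_representation <- function(session, dyad, channel_pair,
                                    phase = "pre", condition = "EO",
                                    bins = NULL, window_s = 4, step_s = 1) {
  iv <- baseline_interval(session, phase, condition)
  if (is.null(bins)) bins <- native_bins(window_s)
  wa <- extract_windows(session$recordings[[dyad[1]]], channel_pair[1],
                        window_s, step_s, interval = iv, mask = session$mask)
  wb <- extract_windows(session$recordings[[dyad[2]]], channel_pair[2],
                        window_s, step_s, interval = iv, mask = session$mask)
  diagonal_cross_bispectrum(wa, wb, bins,
                            meta = list(dyad = dyad,
                                        channel_pair = channel_pair,
                                        interval_id = paste0(phase, "-",
                                                             condition)))
}

#' Rest-normalized bispectrum
#'
#' Elementwise relative change of a segment representation against the
#' eyes-open rest baseline of the same channel combination:
#' `BS_N = (BS_Seg - BS_EO) / BS_EO`. Bins whose baseline magnitude falls
#' below a floor (`eps_rel` times the median baseline magnitude) are flagged
#' invalid (`NA`) rather than divided.
#'
#' @param seg,eo `bispectrum` objects on identical frequency axes.
#' @param eps_rel relative floor for the denominator.
#' @return an object of class `normalized_bispectrum`: list with `freq`,
#'   `value` (dimensionless relative change), `baseline_id`, `meta`.
#' @export
normalize_bispectrum <- function(seg, eo, eps_rel = 1e-12) {
  if (length(seg$freq) != length(eo$freq) ||
      max(abs(seg$freq - eo$freq)) > 1e-9)
    stop("alignment error: segment and baseline axes differ")
  floor_ <- eps_rel * median(eo$value)
  v <- ifelse(eo$value > floor_, (seg$value - eo$value) / eo$value, NA_real_)
  structure(list(freq = seg$freq, value = v,
                 baseline_id = eo$meta$interval_id %||% "pre-EO",
                 meta = seg$meta),
            class = "normalized_bispectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Band averages of a normalized bispectrum
#'
#' Mean of the valid normalized bins inside each band's half-open sampling
#' interval (see [eeg_bands()]).
#'
#' @param norm a `normalized_bispectrum` (or plain `bispectrum`).
#' @param band single band name, or `NULL` for all five.
#' @return named numeric vector (or scalar if `band` given); `NA` when every
#'   bin in a band is invalid.
#' @export
band_average <- function(norm, band = NULL) {
  bd <- eeg_bands()
  if (!is.null(band)) bd <- bd[bd$band %in% band, , drop = FALSE]
  if (nrow(bd) == 0L) stop("unknown band: ", band)
  out <- vapply(seq_len(nrow(bd)), function(i) {
    sel <- norm$freq >= bd$low[i] & norm$freq < bd$high[i]
    v <- norm$value[sel]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  names(out) <- bd$band
  if (!is.null(band) && length(band) == 1L) unname(out) else out
}

#' Collapse the native grid to the 50-bin 1-Hz summary grid
#'
#' Summary bin `k` (k = 1..50) averages the native bins with
#' `floor(f) == k`; the 50 Hz edge bin closes the grid.
#'
#' @param b a `bispectrum` or `normalized_bispectrum`.
#' @return list with `freq` (1..50) and `value` (50 averages).
#' @export
summary_bins <- function(b) {
  k <- pmin(floor(b$freq), 50)
  v <- tapply(b$value, k, mean)
  list(freq = as.numeric(names(v)), value = as.numeric(v))
}

#' Temporal bispectrum series of one channel combination
#'
#' One value per sliding window: the single-window (L = 1) diagonal
#' cross-bispectrum, normalized bin-wise to the pre-trial eyes-open
#' baseline, then band-averaged. The time axis steps by `step_s` (window
#' centers); masked windows are absent from the trace.
#'
#' @param session a `hyperscan_session`.
#' @param dyad,channel_pair as in [segment_representation()].
#' @param band band name.
#' @param interval half-open `c(start, end)` to trace; default spans the
#'   whole design (first segment start to last segment end).
#' @param window_s,step_s window parameters.
#' @param eo optional precomputed baseline `bispectrum` (saves recomputation
#'   across events).
#' @return an object of class `bispectrum_trace`: data.frame with columns
#'   `time` (window centers, s) and `value` (band-averaged normalized
#'   bispectrum), with dyad/channel/band attributes.
#' @export
temporal_series <- function(session, dyad, channel_pair, band = "gamma",
                            interval = NULL, window_s = 4, step_s = 1,
                            eo = NULL) {
  if (is.null(interval))
    interval <- c(min(session$design$start), max(session$design$end))
  bins <- native_bins(window_s)
  if (is.null(eo))
    eo <- baseline_representation(session, dyad, channel_pair,
                                  bins = bins, window_s = window_s,
                                  step_s = step_s)
  wa <- extract_windows(session$recordings[[dyad[1]]], channel_pair[1],
                        window_s, step_s, interval = interval,
                        mask = session$mask)
  wb <- extract_windows(session$recordings[[dyad[2]]], channel_pair[2],
                        window_s, step_s, interval = interval,
                        mask = session$mask)
  check_aligned(wa, wb)
  i1 <- bin_indices(bins, wa)
  i2 <- bin_indices(2 * bins, wa)
  P <- wa$spectra[i1, , drop = FALSE] * wb$spectra[i1, , drop = FALSE] *
    Conj(wb$spectra[i2, , drop = FALSE])
  M <- Mod(P)                       # bins x L, each column an L = 1 estimate
  floor_ <- 1e-12 * median(eo$value)
  valid <- eo$value > floor_
  bd <- eeg_bands()
  bi <- match(band, bd$band)
  if (is.na(bi)) stop("unknown band: ", band)
  sel <- bins >= bd$low[bi] & bins < bd$high[bi] & valid
  vals <- colMeans((M[sel, , drop = FALSE] - eo$value[sel]) / eo$value[sel])
  out <- data.frame(time = wa$centers, value = vals)
  attr(out, "dyad") <- dyad
  attr(out, "channel_pair") <- channel_pair
  attr(out, "band") <- band
  attr(out, "step_s") <- step_s
  class(out) <- c("bispectrum_trace", "data.frame")
  out
}

#' Tidy export of a bispectral representation
#'
#' @param b a `bispectrum` or `normalized_bispectrum`.
#' @return data.frame with dyad, channels, trial/segment and one row per bin.
#' @export
bispectrum_to_df <- function(b) {
  m <- b$meta
  data.frame(dyad = paste(m$dyad %||% c(NA, NA), collapse = "-"),
             chan_a = (m$channel_pair %||% c(NA, NA))[1],
             chan_b = (m$channel_pair %||% c(NA, NA))[2],
             trial = m$trial %||% NA,
             segment = m$segment %||% NA,
             bin_Hz = b$freq, value = b$value,
             stringsAsFactors = FALSE)
}
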