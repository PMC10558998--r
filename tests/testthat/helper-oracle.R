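# Independent brute-force oracle: per-window, per-bin triple product with
# explicit DFT sums. Shares no code with the vectorized estimator.
naive_diagonal_bispectrum <- function(xa, xb, fs, bins) {
  n <- nrow(xa); L <- ncol(xa)
  dft1 <- function(x, f) {
    k <- round(f * n / fs)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }
  vapply(bins, function(f) {
    acc <- 0 + 0i
    for (l in seq_len(L)) {
      acc <- acc + dft1(xa[, l], f) * dft1(xb[, l], f) *
        Conj(dft1(xb[, l], 2 * f))
    }
    Mod(acc / L)
  }, numeric(1))
}
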