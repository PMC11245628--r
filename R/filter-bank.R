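#' Default timescale bands
#'
#' The eight period ranges (in words) used to define language timescales:
#' 2-4, 4-8, 8-16, 16-32, 32-64, 64-128, 128-256 and 256+ words. The open
#' top band is closed at 512 words by octave continuation so that it has a
#' nominal timescale like every other band. Each band's nominal timescale
#' is the arithmetic center of its period range.
#'
#' @param top_period period (words) at which the open "256+" band is closed
#'   (default 512).
#' @return A data frame with columns `band`, `p_low`, `p_high`, `t` (the
#'   nominal timescale) and `label`.
#' @export
default_bands <- function(top_period = 512) {
  p_low <- c(2, 4, 8, 16, 32, 64, 128, 256)
  p_high <- c(4, 8, 16, 32, 64, 128, 256, top_period)
  data.frame(band = 1:8, p_low = p_low, p_high = p_high,
             t = (p_low + p_high) / 2,
             label = c(paste0(p_low[-8], "-", p_high[-8], " words"), "256+ words"),
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  need <- c("p_low", "p_high", "t")
  if (!is.data.frame(bands) || nrow(bands) == 0 || !all(need %in% names(bands)))
    stop_invalid("bands must be a non-empty data frame with columns p_low, p_high, t")
  if (any(bands$p_low < 2))
    stop_invalid("band %d has p_low < 2 words (unresolvable at word rate)",
                 which(bands$p_low < 2)[1])
  if (any(bands$p_low >= bands$p_high))
    stop_invalid("band %d has p_low >= p_high", which(bands$p_low >= bands$p_high)[1])
  bands
}

#' Design the timescale filter bank
#'
#' Each band-pass filter is a cosine wave at the band's center frequency
#' multiplied by a Blackman window (the window method of FIR design). Taps
#' are symmetric about their center, so applying the filter centered is
#' zero-phase. Each filter's gain is normalized so that its peak magnitude
#' response equals 1, ensuring that split-performance comparisons across
#' bands are not driven by filter gain.
#'
#' @param bands band table as from [default_bands()].
#' @param n_taps odd filter length in words; must be at least twice the
#'   longest period so the slowest band is resolvable. The default (2049)
#'   is long enough that every filter's DC gain is far below 1% of peak.
#' @param center `"arithmetic"` places the cosine at `1 / t` (the printed
#'   nominal timescale); `"geometric"` uses `1 / sqrt(p_low * p_high)`.
#' @return An object of class `filter_bank`: the band table, a
#'   `n_taps x n_bands` matrix of taps, and the design parameters.
#' @export
design_filter_bank <- function(bands = default_bands(), n_taps = 2049,
                               center = c("arithmetic", "geometric")) {
  center <- match.arg(center)
  bands <- validate_bands(bands)
  if (n_taps %% 2 == 0 || n_taps < 3)
    stop_invalid("n_taps must be odd and >= 3 (got %d)", n_taps)
  widest <- which.max(bands$p_high)
  if (n_taps < 2 * bands$p_high[widest])
    stop_invalid("n_taps = %d is too short to resolve band %d (period up to %d words needs >= %d taps)",
                 n_taps, widest, bands$p_high[widest], 2 * bands$p_high[widest])
  k <- seq_len(n_taps) - (n_taps + 1) / 2
  win <- signal::blackman(n_taps)
  freqs <- switch(center,
                  arithmetic = 1 / bands$t,
                  geometric = 1 / sqrt(bands$p_low * bands$p_high))
  taps <- vapply(freqs, function(f) cos(2 * pi * f * k) * win, numeric(n_taps))
  # normalize peak magnitude response to 1 on a dense frequency grid
  nfft <- max(2^15, nextn(4 * n_taps, 2))
  for (i in seq_len(ncol(taps))) {
    h <- Mod(fft(c(taps[, i], rep(0, nfft - n_taps))))
    taps[, i] <- taps[, i] / max(h)
  }
  structure(list(bands = bands, taps = taps, n_taps = as.integer(n_taps),
                 center = center, freqs = freqs, nfft = as.integer(nfft)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d bands, %d taps (%s centers)\n",
              nrow(x$bands), x$n_taps, x$center))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Mirror-pad a matrix along its columns
#'
#' Symmetric extension with edge repetition: the left pad is the time
#' reversal of the first `pad` columns and the right pad the reversal of
#' the last `pad` columns (`[a,b,c]` with `pad = 2` becomes
#' `[b,a | a,b,c | c,b]`). When `pad` exceeds the width the reflection is
#' repeated (periodic symmetric extension), so padding never fails.
#'
#' @param x matrix (`p x w`) or vector.
#' @param pad number of columns to add on each side (>= 0).
#' @return the padded matrix, `p x (w + 2 * pad)`.
#' @export
mirror_pad <- function(x, pad) {
  if (pad < 0) stop_invalid("pad must be >= 0")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  w <- ncol(x)
  if (w == 0) stop_invalid("cannot mirror-pad an empty matrix")
  if (pad == 0) return(if (vec) drop(x) else x)
  q <- seq.int(1L - pad, w + pad)
  m <- ((q - 1L) %% (2L * w) + 2L * w) %% (2L * w)
  idx <- ifelse(m < w, m + 1L, 2L * w - m)
  out <- x[, idx, drop = FALSE]
  if (vec) drop(out) else out
}

# Centered (zero-phase) convolution of each row of `x` with `taps`,
# FFT-based, mirror-padded by (n_taps - 1) / 2 on each side.
convolve_rows_centered <- function(x, taps) {
  n_taps <- length(taps)
  pad <- (n_taps - 1L) / 2L
  w <- ncol(x)
  xp <- mirror_pad(x, pad)
  L <- ncol(xp)
  nfft <- nextn(L + n_taps - 1L, 2)
  hf <- fft(c(taps, rep(0, nfft - n_taps)))
  Xf <- mvfft(rbind(t(xp), matrix(0, nfft - L, nrow(x))))
  y <- Re(mvfft(Xf * hf, inverse = TRUE)) / nfft
  # row j of the original maps to full-convolution index j + 2 * pad
  t(y[(2L * pad + 1L):(2L * pad + w), , drop = FALSE])
}

#' Apply the filter bank to a stimulus embedding
#'
#' Convolves every embedding dimension with each band's taps, centered
#' (zero phase), after mirror padding by half the filter length. Returns
#' one filtered embedding per band, each the same shape as the input.
#'
#' @param emb a `stimulus_embedding` or a plain `p x w` matrix.
#' @param bank a [design_filter_bank()] result.
#' @return A named list of `p x w` matrices, one per band, with the band
#'   table attached as attribute `"bands"`.
#' @export
apply_filter_bank <- function(emb, bank) {
  M <- if (inherits(emb, "stimulus_embedding")) emb$M else as.matrix(emb)
  if (ncol(M) < 1 || nrow(M) < 1) stop_invalid("embedding is empty")
  out <- lapply(seq_len(ncol(bank$taps)), function(i)
    convolve_rows_centered(M, bank$taps[, i]))
  names(out) <- paste0("timescale_", bank$bands$band)
  attr(out, "bands") <- bank$bands
  out
}

#' Spectral leakage report for a filter bank
#'
#' For each band, reports the maximum magnitude response inside its own
#' period range, the maximum response at frequencies belonging to bands at
#' least two positions away, and the DC gain -- all relative to the unit
#' peak gain. Used as a QC check that the bank separates timescales
#' without substantial leakage.
#'
#' @param bank a [design_filter_bank()] result.
#' @return A data frame with one row per band.
#' @export
leakage_report <- function(bank) {
  nfft <- bank$nfft
  f <- (0:(nfft / 2)) / nfft  # cycles / word
  bands <- bank$bands
  K <- nrow(bands)
  rows <- lapply(seq_len(K), function(i) {
    h <- Mod(fft(c(bank$taps[, i], rep(0, nfft - bank$n_taps))))[seq_along(f)]
    inb <- f >= 1 / bands$p_high[i] & f <= 1 / bands$p_low[i]
    far <- rep(FALSE, length(f))
    for (j in seq_len(K))
      if (abs(j - i) >= 2)
        far <- far | (f >= 1 / bands$p_high[j] & f <= 1 / bands$p_low[j])
    data.frame(band = bands$band[i],
               in_band_max = max(h[inb]),
               far_band_max = if (any(far)) max(h[far]) else NA_real_,
               dc_gain = h[1])
  })
  do.call(rbind, rows)
}
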