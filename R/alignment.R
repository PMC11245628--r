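# Word-rate to TR-rate conversion and response preprocessing.

# Normalized Gaussian-RBF interpolation weights: rows = query times,
# columns = word anchor times. Rows sum to 1; the max-exponent shift keeps
# the partition-of-unity well defined far from any word, where the value
# decays to the nearest word's value rather than to zero.
rbf_weights <- function(query_times, anchor_times, sigma) {
  E <- -0.5 * outer(query_times, anchor_times, "-")^2 / sigma^2
  E <- exp(E - apply(E, 1, max))
  E / rowSums(E)
}

# Dense sample times for a run: `samples_per_tr` uniform points per TR.
dense_times <- function(n_tr, tr, samples_per_tr = 25) {
  (seq_len(n_tr * samples_per_tr) - 0.5) * tr / samples_per_tr
}

# Middle time point of each TR.
tr_times <- function(n_tr, tr) (seq_len(n_tr) - 0.5) * tr

#' Interpolate a word-rate signal onto a dense uniform grid
#'
#' Uses a normalized Gaussian radial-basis-function kernel anchored at the
#' word midpoint times: the value at time `t` is the kernel-weighted mean
#' of the word-rate values. Because word presentation rate is not uniform,
#' this step prevents later downsampling from conflating slow embedding
#' components with the word rate itself. The output has a constant
#' sampling rate of `samples_per_tr` samples per TR.
#'
#' @param x `p x w` matrix (or length-`w` vector) of word-rate values.
#' @param seq the [word_sequence()] of the run (anchors = word midpoints).
#' @param n_tr run length in TRs.
#' @param tr repetition time in seconds.
#' @param samples_per_tr dense samples per TR (default 25).
#' @param sigma Gaussian kernel width in seconds; defaults to the run's
#'   mean inter-word interval.
#' @return `p x (samples_per_tr * n_tr)` matrix with the sample times in
#'   attribute `"times"`.
#' @export
rbf_interpolate <- function(x, seq, n_tr, tr, samples_per_tr = 25, sigma = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  times <- word_times(seq)
  grid <- dense_times(n_tr, tr, samples_per_tr)
  if (length(times) == 0) {
    warning("run has no words; interpolated signal is all zeros")
    out <- matrix(0, nrow(x), length(grid))
    attr(out, "times") <- grid
    return(out)
  }
  if (ncol(x) != length(times))
    stop_invalid("signal width %d does not match word count %d", ncol(x), length(times))
  if (any(times < 0) || any(times > n_tr * tr))
    stop_invalid("word times fall outside the run's time span")
  if (is.null(sigma))
    sigma <- if (length(times) > 1) mean(diff(times)) else tr
  A <- rbf_weights(grid, times, sigma)
  out <- tcrossprod(x, A)
  attr(out, "times") <- grid
  out
}

# Lanczos resampling weights: rows = output (TR-middle) times, columns =
# dense sample times. 3-lobe kernel at the given cutoff, rows normalized
# to sum 1 so DC gain is exactly 1.
lanczos_weights <- function(out_times, in_times, cutoff = 0.25, lobes = 3) {
  dt <- outer(out_times, in_times, "-")
  u <- 2 * cutoff * dt
  s <- function(z) ifelse(z == 0, 1, sin(pi * z) / (pi * z))
  W <- s(u) * s(u / lobes)
  W[abs(u) >= lobes] <- 0
  W / rowSums(W)
}

#' Downsample a dense signal to TR rate with a Lanczos anti-aliasing filter
#'
#' Resamples a dense (`samples_per_tr` per TR) signal to the middle time
#' point of each fMRI volume using a 3-lobe Lanczos kernel with cutoff at
#' the fMRI Nyquist rate. Weights are normalized per output sample so the
#' DC gain is 1.
#'
#' @param dense `p x (samples_per_tr * n_tr)` matrix as produced by
#'   [rbf_interpolate()].
#' @param n_tr run length in TRs.
#' @param tr repetition time in seconds.
#' @param samples_per_tr dense samples per TR.
#' @param cutoff cutoff frequency in Hz (default 0.25, the Nyquist rate of
#'   a 2-second TR).
#' @param lobes number of Lanczos lobes (default 3).
#' @return `n_tr x p` matrix (time by channels).
#' @export
lanczos_downsample <- function(dense, n_tr, tr, samples_per_tr = 25,
                               cutoff = 0.25, lobes = 3) {
  if (cutoff <= 0) stop_invalid("cutoff must be positive")
  if (is.null(dim(dense))) dense <- matrix(dense, nrow = 1)
  if (ncol(dense) != n_tr * samples_per_tr)
    stop_invalid("dense signal has %d samples, expected %d x %d",
                 ncol(dense), n_tr, samples_per_tr)
  W <- lanczos_weights(tr_times(n_tr, tr),
                       dense_times(n_tr, tr, samples_per_tr), cutoff, lobes)
  t(tcrossprod(dense, W))
}

#' Trim TRs from both edges of every run
#'
#' Drops the first and last `trim` TRs of each run (the silent lead-in /
#' lead-out and onset non-stationarity). Must be applied identically to
#' features and responses.
#'
#' @param x `n x d` matrix, rows = TRs of all runs concatenated.
#' @param run_lengths integer vector of run lengths summing to `n`.
#' @param trim TRs to drop at each edge (default 10).
#' @return the trimmed matrix, with attribute `"run_lengths"` giving the
#'   trimmed per-run lengths.
#' @export
trim_runs <- function(x, run_lengths, trim = 10) {
  if (sum(run_lengths) != nrow(x))
    stop_invalid("run lengths sum to %d but x has %d rows", sum(run_lengths), nrow(x))
  if (any(run_lengths <= 2 * trim))
    stop_invalid("run %d (%d TRs) is too short to trim %d TRs per edge",
                 which(run_lengths <= 2 * trim)[1],
                 run_lengths[which(run_lengths <= 2 * trim)[1]], trim)
  if (trim == 0) {
    attr(x, "run_lengths") <- as.integer(run_lengths)
    return(x)
  }
  starts <- run_starts(run_lengths)
  keep <- unlist(lapply(seq_along(run_lengths), function(r)
    (starts[r] + trim):(starts[r] + run_lengths[r] - trim - 1)))
  out <- x[keep, , drop = FALSE]
  attr(out, "run_lengths") <- as.integer(run_lengths - 2 * trim)
  out
}

#' Z-score feature channels using training-set statistics
#'
#' Channel means and standard deviations are computed on the training rows
#' only and applied to all rows, so no test-set statistics leak into the
#' features. Channels with zero variance on the training set are set to 0
#' and flagged rather than producing non-finite values.
#'
#' @param x `n x d` feature matrix.
#' @param center,scale optional precomputed statistics (length `d`); when
#'   `NULL` they are computed from `x` itself (i.e. `x` is the training
#'   set).
#' @return list with `values` (z-scored matrix), `center`, `scale` and
#'   `flagged` (logical, zero-variance channels).
#' @export
zscore_features <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, sd)
  flagged <- !is.finite(scale) | scale < .Machine$double.eps^0.5
  safe <- ifelse(flagged, 1, scale)
  values <- sweep(sweep(x, 2, center, "-"), 2, safe, "/")
  values[, flagged] <- 0
  list(values = values, center = center, scale = scale, flagged = flagged)
}

#' Add FIR delays to a feature matrix
#'
#' Concatenates copies of the features shifted forward in time by each
#' delay (in TRs), to absorb the hemodynamic response lag. Shifts never
#' cross run boundaries: the first `delay` TRs of each run are zero-filled.
#'
#' @param x `n x d` feature matrix.
#' @param run_lengths per-run lengths summing to `n`.
#' @param delays positive integer delays in TRs (default 1:4, i.e. roughly
#'   2, 4, 6 and 8 seconds at a 2-second TR).
#' @return `n x (length(delays) * d)` matrix with attribute `"delay"`
#'   tagging each output channel's delay.
#' @export
add_fir_delays <- function(x, run_lengths, delays = 1:4) {
  if (any(delays < 1) || any(delays != round(delays)))
    stop_invalid("delays must be positive integers (TRs)")
  if (any(delays >= min(run_lengths)))
    stop_invalid("delay %d is not shorter than the shortest run (%d TRs)",
                 max(delays), min(run_lengths))
  if (sum(run_lengths) != nrow(x))
    stop_invalid("run lengths sum to %d but x has %d rows", sum(run_lengths), nrow(x))
  out <- matrix(0, nrow(x), length(delays) * ncol(x))
  starts <- run_starts(run_lengths)
  for (j in seq_along(delays)) {
    dcols <- (j - 1) * ncol(x) + seq_len(ncol(x))
    for (r in seq_along(run_lengths)) {
      rows <- starts[r]:(starts[r] + run_lengths[r] - 1)
      d <- delays[j]
      out[rows[(d + 1):length(rows)], dcols] <-
        x[rows[1:(length(rows) - d)], , drop = FALSE]
    }
  }
  attr(out, "delay") <- rep(delays, each = ncol(x))
  out
}

# Third-order Savitzky-Golay smooth of each column within each run.
sgolay_smooth <- function(x, run_lengths, window_trs, order = 3) {
  starts <- run_starts(run_lengths)
  out <- x
  for (r in seq_along(run_lengths)) {
    rows <- starts[r]:(starts[r] + run_lengths[r] - 1)
    out[rows, ] <- apply(x[rows, , drop = FALSE], 2, signal::sgolayfilt,
                         p = order, n = window_trs)
  }
  out
}

#' Preprocess BOLD responses
#'
#' Optionally removes low-frequency drift by subtracting a third-order
#' Savitzky-Golay smooth with a 120-second window (converted to the
#' nearest odd TR count), then z-scores each voxel across time within each
#' run. Runs shorter than the smoothing window skip detrending with a
#' warning.
#'
#' @param y `n x v` response matrix (TRs by voxels).
#' @param run_lengths per-run lengths summing to `n`.
#' @param tr repetition time in seconds.
#' @param detrend remove drift before z-scoring? (default `TRUE`)
#' @param sg_window_s Savitzky-Golay window in seconds (default 120).
#' @param sg_order polynomial order (default 3).
#' @return `n x v` matrix; per run each voxel has mean 0 and sd 1.
#' @export
preprocess_bold <- function(y, run_lengths, tr, detrend = TRUE,
                            sg_window_s = 120, sg_order = 3) {
  if (sum(run_lengths) != nrow(y))
    stop_invalid("run lengths sum to %d but y has %d rows", sum(run_lengths), nrow(y))
  window_trs <- round(sg_window_s / tr)
  if (window_trs %% 2 == 0)
    window_trs <- window_trs + if (sg_window_s / tr > window_trs) 1L else -1L
  starts <- run_starts(run_lengths)
  out <- y
  for (r in seq_along(run_lengths)) {
    rows <- starts[r]:(starts[r] + run_lengths[r] - 1)
    block <- y[rows, , drop = FALSE]
    if (detrend) {
      if (run_lengths[r] <= window_trs) {
        warning(sprintf("run %d (%d TRs) is shorter than the %d-TR detrending window; skipped",
                        r, run_lengths[r], window_trs))
      } else {
        block <- block - apply(block, 2, signal::sgolayfilt, p = sg_order,
                               n = window_trs)
      }
    }
    mu <- colMeans(block)
    sdv <- apply(block, 2, sd)
    sdv[sdv < .Machine$double.eps^0.5] <- 1
    out[rows, ] <- sweep(sweep(block, 2, mu, "-"), 2, sdv, "/")
  }
  out
}

#' Average repeated presentations of the test run
#'
#' @param reps list of `n x v` response matrices (identical shapes), one
#'   per presentation.
#' @return the elementwise mean, with attribute `"n_repeats"`.
#' @export
average_test_repeats <- function(reps) {
  if (!is.list(reps) || length(reps) < 1)
    stop_invalid("reps must be a non-empty list of response matrices")
  d <- dim(reps[[1]])
  for (r in reps)
    if (!identical(dim(r), d))
      stop_invalid("test repeats have mismatched shapes")
  out <- Reduce(`+`, reps) / length(reps)
  attr(out, "n_repeats") <- length(reps)
  out
}
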