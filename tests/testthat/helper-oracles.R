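# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: FFT-domain filtering, brute-force objective
# minimization, direct step-up FDR, and plain Pearson correlations.

# Dominant frequency (cycles per sample) of a signal via the DFT.
fft_peak_freq <- function(x) {
  n <- length(x)
  mag <- Mod(fft(x - mean(x)))[2:floor(n / 2)]
  (which.max(mag) + 0) / n  # bins 2.. correspond to frequencies 1/n, 2/n, ...
}

# Ideal band-pass filtering in the frequency domain: keep DFT bins whose
# frequency lies in [f_lo, f_hi] (and the mirrored bins).
fft_bandpass <- function(x, f_lo, f_hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)
  keep <- f >= f_lo & f <= f_hi
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

# Brute-force Benjamini-Hochberg step-up: largest k with
# p_(k) <= k * alpha / m is the rejection threshold.
bh_stepup <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= seq_len(m) * alpha / m)
  reject <- rep(FALSE, m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Direct evaluation of the banded-ridge objective for a single voxel.
banded_ridge_objective <- function(beta, X, y, groups, penalties) {
  pen <- 0
  for (g in seq_along(groups)) pen <- pen + penalties[g] * sum(beta[groups[[g]]]^2)
  sum((y - X %*% beta)^2) + pen
}

# Standard ridge via SVD (independent of the package's Cholesky path).
svd_ridge <- function(X, y, lambda) {
  s <- svd(X)
  s$v %*% ((s$d / (s$d^2 + lambda)) * crossprod(s$u, y))
}

# Ridge validation SSE over folds for a scalar penalty (1-D grid oracle).
grid_cv_loss <- function(X, Y, folds, lambda) {
  total <- 0
  for (f in folds) {
    Xt <- X[f$train, , drop = FALSE]
    B <- solve(crossprod(Xt) + lambda * diag(ncol(X)),
               crossprod(Xt, Y[f$train, , drop = FALSE]))
    total <- total + colSums((X[f$val, , drop = FALSE] %*% B -
                                Y[f$val, , drop = FALSE])^2)
  }
  total
}

# A small multi-run synthetic stimulus for alignment tests.
tiny_sequence <- function(n_words, interval = 0.4, seed = 1) {
  generate_word_sequence(n_words, mean_interval = interval, jitter = 0.2,
                         seed = seed)
}
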