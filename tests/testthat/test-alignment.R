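test_that("RBF interpolation is a normalized kernel average", {
  seq <- tiny_sequence(100, interval = 0.5, seed = 2)
  n_tr <- ceiling(max(seq$offsets) / 2) + 2
  # equal word values give a constant interpolant
  dense <- rbf_interpolate(matrix(3, 1, 100), seq, n_tr, tr = 2)
  expect_lt(max(abs(dense - 3)), 1e-12)

  # a single anchor: the normalized kernel is a partition of unity, so the
  # signal equals the word's value everywhere
  one <- word_sequence("wo", 19.8, 20.2, 1L)
  d1 <- rbf_interpolate(matrix(4, 1, 1), one, 20, tr = 2, sigma = 1)
  expect_lt(max(abs(d1 - 4)), 1e-12)
  # two anchors with values (1, 0): the interpolant passes through the
  # word values and crosses 0.5 at the midpoint between them
  two <- word_sequence(c("wo", "na"), c(9.9, 29.9), c(10.1, 30.1), c(1L, 1L))
  d2 <- rbf_interpolate(matrix(c(1, 0), 1), two, 20, tr = 2, sigma = 2)
  tt <- attr(d2, "times")
  expect_gt(d2[1, which.min(abs(tt - 10))], 0.99)
  expect_lt(d2[1, which.min(abs(tt - 30))], 0.01)
  expect_equal(d2[1, which.min(abs(tt - 20))], 0.5, tolerance = 0.15)

  # dense equal-spaced words with sigma = spacing: interpolant at word
  # times within 5% of the word values (direct kernel-sum contract)
  reg <- generate_word_sequence(60, mean_interval = 0.4, jitter = 0, seed = 1)
  vals <- matrix(sin(seq(0, 3, length.out = 60)), 1)
  dr <- rbf_interpolate(vals, reg, ceiling(max(reg$offsets) / 2) + 2, tr = 2,
                        sigma = 0.4)
  t_dense <- attr(dr, "times")
  at_words <- vapply(word_times(reg), function(tw)
    dr[1, which.min(abs(t_dense - tw))], numeric(1))
  expect_lt(max(abs(at_words - vals[1, ])) / max(abs(vals)), 0.05)

  expect_warning(
    z <- rbf_interpolate(matrix(0, 1, 0),
                         word_sequence(character(0), numeric(0), numeric(0),
                                       integer(0)), 5, 2),
    "no words")
  expect_true(all(z == 0))
})

test_that("Lanczos downsampling preserves DC and slow signals, kills fast ones", {
  n_tr <- 150; tr <- 2; spt <- 25
  t_dense <- langscales:::dense_times(n_tr, tr, spt)
  # constant in, constant out
  out_c <- lanczos_downsample(matrix(5, 1, n_tr * spt), n_tr, tr)
  expect_lt(max(abs(out_c - 5)), 1e-9)

  amp_out <- function(f_hz) {
    x <- matrix(sin(2 * pi * f_hz * t_dense), 1)
    y <- lanczos_downsample(x, n_tr, tr)[, 1]
    core <- 20:(n_tr - 20)
    ref <- sin(2 * pi * f_hz * langscales:::tr_times(n_tr, tr))[core]
    max(abs(y[core])) / 1
  }
  # 0.05 Hz (well under the 0.25 Hz cutoff): amplitude preserved within 5%
  expect_lt(abs(amp_out(0.05) - 1), 0.05)
  # 0.45 Hz (above cutoff): attenuated to at most 0.2 of input amplitude
  expect_lt(amp_out(0.45), 0.2)

  expect_error(lanczos_downsample(matrix(0, 1, n_tr * spt), n_tr, tr,
                                  cutoff = 0), "cutoff")
})

test_that("interpolation plus downsampling leaves a constant exactly constant", {
  seq <- tiny_sequence(200, seed = 9)
  n_tr <- ceiling(max(seq$offsets) / 2) + 3
  dense <- rbf_interpolate(matrix(2.5, 2, 200), seq, n_tr, tr = 2)
  out <- lanczos_downsample(dense, n_tr, tr = 2)
  expect_lt(max(abs(out - 2.5)), 1e-6)
})

test_that("run trimming drops exactly trim TRs per edge", {
  x <- matrix(seq_len(620), ncol = 1)
  tr300 <- trim_runs(x[1:300, , drop = FALSE], 300, trim = 10)
  expect_equal(nrow(tr300), 280)
  expect_equal(tr300[1, 1], 11)
  both <- trim_runs(x, c(300, 320), trim = 10)
  expect_equal(nrow(both), 580)
  expect_equal(attr(both, "run_lengths"), c(280L, 300L))
  expect_equal(trim_runs(x, c(300, 320), trim = 0)[, 1], x[, 1])
  expect_error(trim_runs(x, c(300, 320), trim = 160), "run 1")
})

test_that("feature z-scoring uses training statistics only", {
  tr_x <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2)
  zs <- zscore_features(tr_x)
  expect_equal(mean(zs$values[, 1]), 0)
  expect_equal(sd(zs$values[, 1]), 1)
  # constant channel: zeroed and flagged
  expect_true(zs$flagged[2])
  expect_true(all(zs$values[, 2] == 0))
  # test rows transformed with training stats keep a nonzero mean
  te <- zscore_features(matrix(c(10, 11, 12, 1, 2, 3), ncol = 2),
                        center = zs$center, scale = zs$scale)
  expect_gt(abs(mean(te$values[, 1])), 1)
})

test_that("FIR delays shift within runs and never across run boundaries", {
  x <- matrix(0, 20, 2)
  x[1, 1] <- 1   # impulse at TR 1 of run 1
  x[11, 2] <- 7  # impulse at TR 1 of run 2
  d <- add_fir_delays(x, c(10, 10), delays = c(2, 3))
  expect_equal(dim(d), c(20, 4))  # 2 channels x 2 delays
  expect_equal(attr(d, "delay"), c(2, 2, 3, 3))
  expect_equal(d[3, 1], 1)   # delay-2 copy lands at TR 3
  expect_equal(d[4, 3], 1)   # delay-3 copy at TR 4
  expect_equal(d[13, 2], 7)  # run-2 impulse shifts inside run 2
  # the last TRs of run 1 never leak into run 2's first TRs
  x2 <- matrix(0, 20, 1); x2[10, 1] <- 1
  d2 <- add_fir_delays(x2, c(10, 10), delays = 2)
  expect_true(all(d2[11:12, ] == 0))
  # four delays quadruple the channel count
  expect_equal(ncol(add_fir_delays(matrix(rnorm(60), 20), c(10, 10), 1:4)), 12)
  expect_error(add_fir_delays(x, c(10, 10), delays = 10), "shortest run")
  expect_error(add_fir_delays(x, c(10, 10), delays = 0.5), "positive integers")
})

test_that("Savitzky-Golay preprocessing removes slow drift, spares noise", {
  tr <- 2
  n <- 300
  t_s <- (seq_len(n) - 0.5) * tr
  slow <- cos(2 * pi * t_s / 400)  # period 400 s
  y <- matrix(slow, ncol = 1)
  # oracle: local cubic fits reproduce the smooth, so the residual of the
  # pure slow cosine is tiny relative to its own scale
  detr <- y - langscales:::sgolay_smooth(y, n, 59, 3)
  expect_lt(sd(detr), 0.1 * sd(slow))
  # cross-check the smooth at a few interior points against lm()
  w <- 59; half <- (w - 1) / 2
  for (i in c(100, 200)) {
    idx <- (i - half):(i + half)
    fit <- lm(slow[idx] ~ poly(idx, 3, raw = TRUE))
    expect_equal(unname(fitted(fit)[half + 1]),
                 langscales:::sgolay_smooth(y, n, 59, 3)[i, 1],
                 tolerance = 1e-6)
  }

  # white noise passes nearly untouched
  set.seed(3)
  wn <- matrix(rnorm(n * 3), n)
  detr_wn <- wn - langscales:::sgolay_smooth(wn, n, 59, 3)
  expect_lt(abs(var(as.vector(detr_wn)) / var(as.vector(wn)) - 1), 0.15)

  # z-scoring contract: per-run voxel columns have mean 0, sd 1
  y2 <- matrix(rnorm(200 * 4, mean = 3, sd = 5), 200)
  pre2 <- preprocess_bold(y2, c(100, 100), tr, detrend = FALSE)
  for (rows in list(1:100, 101:200)) {
    expect_lt(max(abs(colMeans(pre2[rows, ]))), 1e-9)
    expect_lt(max(abs(apply(pre2[rows, ], 2, sd) - 1)), 1e-9)
  }
  expect_warning(preprocess_bold(matrix(rnorm(40), 40, 1), 40, tr,
                                 detrend = TRUE), "shorter")
})

test_that("test-repeat averaging is the elementwise mean", {
  y <- matrix(rnorm(20), 5)
  expect_equal(average_test_repeats(list(y, y)), y, ignore_attr = TRUE)
  expect_equal(average_test_repeats(list(y, -y)), matrix(0, 5, 4),
               ignore_attr = TRUE)
  set.seed(4)
  s <- matrix(rnorm(2000), 500)
  r1 <- s + matrix(rnorm(2000), 500)
  r2 <- s + matrix(rnorm(2000), 500)
  avg <- average_test_repeats(list(r1, r2))
  ratio <- var(as.vector(r1 - s)) / var(as.vector(avg - s))
  expect_gt(ratio, 1.7); expect_lt(ratio, 2.3)
  expect_error(average_test_repeats(list(y, y[1:3, ])), "mismatched")
})
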