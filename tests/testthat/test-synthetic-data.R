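test_that("generated word sequences respect timing and grouping contracts", {
  expect_length(generate_word_sequence(0)$words, 0)

  # zero jitter degenerates to exactly arithmetic onsets
  s0 <- generate_word_sequence(100, mean_interval = 0.5, jitter = 0, seed = 3)
  expect_equal(diff(s0$onsets), rep(0.5, 99))

  s <- generate_word_sequence(1000, mean_interval = 0.4, jitter = 0.3, seed = 1)
  expect_true(all(diff(s$onsets) > 0))
  expect_true(all(s$offsets >= s$onsets))
  expect_true(all(s$offsets[-1000] <= s$onsets[-1]))
  # empirical mean interval close to the requested mean
  expect_lt(abs(mean(diff(s$onsets)) - 0.4) / 0.4, 0.05)
  # sentence ids partition words contiguously
  expect_true(all(diff(s$sentence_ids) %in% c(0L, 1L)))
  # determinism
  expect_identical(s, generate_word_sequence(1000, 0.4, 0.3, seed = 1))

  expect_error(generate_word_sequence(-1), "n_words")
  expect_error(generate_word_sequence(10, mean_interval = 0), "positive")
  expect_error(generate_word_sequence(10, jitter = 1), "jitter")
})

test_that("band-limited embedding dimensions carry their assigned frequency", {
  seq <- tiny_sequence(2048)
  one_band <- data.frame(p_low = 16, p_high = 32, t = 24)
  g1 <- generate_band_limited_embedding(seq, one_band, dims_per_band = 1,
                                        noise = 0, seed = 5)
  expect_equal(dim(g1$embedding$M), c(1, 2048))
  expect_true(g1$periods >= 16 && g1$periods <= 32)
  # FFT oracle: dominant frequency inside the assigned band
  f <- fft_peak_freq(g1$embedding$M[1, ])
  expect_true(f >= 1 / 32 - 1 / 2048 && f <= 1 / 16 + 1 / 2048)

  # determinism: bit-identical matrices under a fixed seed
  g2 <- generate_band_limited_embedding(seq, default_bands(), 2, seed = 7)
  g3 <- generate_band_limited_embedding(seq, default_bands(), 2, seed = 7)
  expect_identical(g2$embedding$M, g3$embedding$M)

  expect_error(generate_band_limited_embedding(seq, data.frame()), "bands")
  expect_error(generate_band_limited_embedding(seq, one_band, dims_per_band = 0),
               "dims_per_band")
})

test_that("FFT peaks of noiseless dimensions land inside their assigned bands", {
  seq <- tiny_sequence(4096, seed = 2)
  gen <- generate_band_limited_embedding(seq, default_bands(),
                                         dims_per_band = 6, noise = 0,
                                         seed = 11)
  bands <- default_bands()
  n <- 4096
  hits <- vapply(seq_len(nrow(gen$embedding$M)), function(d) {
    f <- fft_peak_freq(gen$embedding$M[d, ])
    b <- gen$band_assignment[d]
    f >= 1 / bands$p_high[b] - 1 / n && f <= 1 / bands$p_low[b] + 1 / n
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("voxel responses are linear in their band's features", {
  n_tr <- 60
  run_lengths <- c(n_tr, n_tr)
  p <- 3
  set.seed(42)
  band_features <- lapply(1:3, function(i) matrix(rnorm(2 * n_tr * p), ncol = p))
  W <- matrix(0, 5, 3); W[, 2] <- 1  # every voxel one-hot on band 2
  truth <- synthetic_ground_truth(W, timescales = c(3, 6, 12),
                                  noise_sigma = 0, drift_amplitude = 0)
  gen <- generate_voxel_responses(band_features, truth, run_lengths,
                                  tr = 2, lag = 1, seed = 8)
  # noiseless one-hot responses lie in the column space of the lagged
  # band-2 features: projection residual is numerically zero
  lagged <- add_fir_delays(band_features[[2]], run_lengths, delays = 1)
  resid <- gen$Y - lagged %*% qr.solve(lagged, gen$Y)
  expect_lt(max(abs(resid)), 1e-8)

  # two iid-noise repeats: averaging halves the noise variance
  truth_n <- synthetic_ground_truth(W, c(3, 6, 12), noise_sigma = 1,
                                    drift_amplitude = 0)
  base <- generate_voxel_responses(band_features, truth_n, run_lengths, 2,
                                   lag = 1, seed = 9)
  rep2 <- generate_voxel_responses(band_features, truth_n, run_lengths, 2,
                                   lag = 1,
                                   channel_weights = base$channel_weights,
                                   signal_scale = base$signal_scale, seed = 10)
  noise1 <- base$Y - base$signal
  noise_avg <- (base$Y + rep2$Y) / 2 - base$signal
  ratio <- var(as.vector(noise1)) / var(as.vector(noise_avg))
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)

  # all-zero weight rows are rejected
  expect_error(synthetic_ground_truth(matrix(0, 2, 3), c(3, 6, 12)),
               "all-zero")
  # shape mismatch rejected
  expect_error(generate_voxel_responses(band_features[1:2], truth,
                                        run_lengths, 2),
               "band feature")
})

test_that("ground truth timescale is the weighted log-mean of its weights", {
  W <- rbind(c(1, 0, 0), c(0, 0, 2), c(1, 1, 0))
  t <- c(4, 8, 16)
  truth <- synthetic_ground_truth(W, t)
  expect_equal(truth$true_timescale, c(4, 16, sqrt(4 * 8)))
  expect_equal(truth$true_band, c(1L, 3L, 1L))
})

test_that("simulated datasets are reproducible and structurally sound", {
  ds1 <- simulate_timescale_dataset(n_train_runs = 2, run_length_trs = 40,
                                    n_voxels = 6, n_taps = 1025,
                                    drift_amplitude = 0.5, seed = 21)
  ds2 <- simulate_timescale_dataset(n_train_runs = 2, run_length_trs = 40,
                                    n_voxels = 6, n_taps = 1025,
                                    drift_amplitude = 0.5, seed = 21)
  expect_identical(ds1$Y_train, ds2$Y_train)
  expect_identical(ds1$Y_test_reps, ds2$Y_test_reps)
  expect_equal(dim(ds1$Y_train), c(80, 6))
  expect_length(ds1$Y_test_reps, 2)
  expect_false(identical(ds1$Y_test_reps[[1]], ds1$Y_test_reps[[2]]))
  # every voxel's one-hot truth matches its stated timescale
  expect_equal(ds1$truth$true_timescale,
               default_bands()$t[ds1$truth$true_band])
})
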