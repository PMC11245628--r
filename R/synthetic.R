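# Synthetic data with known per-voxel timescale ground truth. The
# generator emulates the structure of a narrative fMRI session: several
# 10-15 minute training runs plus one test run presented twice, a variable
# word rate, and voxel responses that are linear in timescale-specific
# embedding features plus slow drift and Gaussian noise.

#' Generate a band-limited synthetic stimulus embedding
#'
#' Each embedding dimension is a sinusoid in word index whose period is
#' drawn uniformly inside its assigned timescale band (periods are
#' measured in words, matching the definition of language timescales),
#' with amplitude `amp` plus white Gaussian noise of s.d. `noise`. The
#' band assignment of every dimension is recorded, so the spectral content
#' of the embedding is known exactly.
#'
#' @param seq a [word_sequence()].
#' @param bands band table (see [default_bands()]).
#' @param dims_per_band embedding dimensions per band (>= 1).
#' @param amp sinusoid amplitude (default 1).
#' @param noise white-noise s.d. added to every dimension (default 0.3).
#' @param seed optional integer seed.
#' @return list with `embedding` (a [stimulus_embedding()], `p x w` with
#'   `p = nrow(bands) * dims_per_band`), `band_assignment` (band index per
#'   dimension) and `periods` (the drawn period per dimension, in words).
#' @export
generate_band_limited_embedding <- function(seq, bands = default_bands(),
                                            dims_per_band = 2, amp = 1,
                                            noise = 0.3, seed = NULL) {
  bands <- validate_bands(bands)
  if (dims_per_band < 1) stop_invalid("dims_per_band must be >= 1")
  w <- length(seq)
  K <- nrow(bands)
  p <- K * dims_per_band
  with_seed_or_current(seed, {
    assignment <- rep(seq_len(K), each = dims_per_band)
    periods <- runif(p, bands$p_low[assignment], bands$p_high[assignment])
    phases <- runif(p, 0, 2 * pi)
    k <- seq_len(w)
    M <- matrix(0, p, w)
    for (d in seq_len(p))
      M[d, ] <- amp * sin(2 * pi * k / periods[d] + phases[d]) +
        rnorm(w, 0, noise)
    list(embedding = stimulus_embedding(M, list(synthetic = seq_len(p)),
                                        context_mode = "synthetic",
                                        words = seq$words),
         band_assignment = assignment, periods = periods)
  })
}

#' Synthetic per-voxel timescale ground truth
#'
#' Non-negative per-voxel band weights together with the implied true
#' timescale of each voxel, defined self-consistently as the weighted
#' geometric mean of the band timescales under the (normalized) weight
#' row -- the same weighted log-timescale average the analysis estimates.
#'
#' @param band_weights `v x K` non-negative matrix; each row must have at
#'   least one positive entry.
#' @param timescales the `K` nominal band timescales in words.
#' @param noise_sigma response noise s.d., in units of the (unit-variance)
#'   signal; `1` gives an SNR of 1.
#' @param drift_amplitude s.d. of the slow drift component, same units.
#' @param seed integer seed used when the responses were generated.
#' @return An object of class `synthetic_ground_truth`, including
#'   `true_timescale` and `true_band` (the argmax band per voxel).
#' @export
synthetic_ground_truth <- function(band_weights, timescales = default_bands()$t,
                                   noise_sigma = 1, drift_amplitude = 1,
                                   seed = NA_integer_) {
  band_weights <- as.matrix(band_weights)
  if (ncol(band_weights) != length(timescales))
    stop_invalid("band_weights has %d columns but %d timescales were given",
                 ncol(band_weights), length(timescales))
  if (any(band_weights < 0)) stop_invalid("band weights must be non-negative")
  if (any(rowSums(band_weights) <= 0))
    stop_invalid("voxel %d has an all-zero weight row",
                 which(rowSums(band_weights) <= 0)[1])
  wn <- band_weights / rowSums(band_weights)
  structure(list(band_weights = band_weights,
                 timescales = timescales,
                 true_timescale = 2^drop(wn %*% log2(timescales)),
                 true_band = apply(band_weights, 1, which.max),
                 noise_sigma = noise_sigma,
                 drift_amplitude = drift_amplitude, seed = seed),
            class = "synthetic_ground_truth")
}

# Slow drift for one run: a sum of low-order cosines with periods longer
# than the detrending window (240-600 s), scaled to unit s.d., so the
# Savitzky-Golay preprocessing has a removable target.
run_drift <- function(n_tr, tr, n_components = 3) {
  t_s <- tr_times(n_tr, tr)
  d <- rowSums(vapply(seq_len(n_components), function(i)
    cos(2 * pi * t_s / runif(1, 240, 600) + runif(1, 0, 2 * pi)),
    numeric(n_tr)))
  s <- sd(d)
  if (s < .Machine$double.eps^0.5) return(rep(0, n_tr))
  d / s
}

#' Generate voxel responses linear in timescale-specific features
#'
#' Each voxel's response is a weighted sum, over bands, of that band's
#' TR-rate features projected through random channel weights and scaled by
#' the voxel's band weight, lagged by `lag` TRs to emulate the
#' hemodynamic delay, normalized to unit signal s.d., plus slow cosine
#' drift and white Gaussian noise.
#'
#' @param band_features list of `n x p` TR-rate feature matrices, one per
#'   band (`n` = total TRs across the runs being generated).
#' @param truth a [synthetic_ground_truth()].
#' @param run_lengths per-run lengths summing to `n`.
#' @param tr repetition time in seconds.
#' @param lag hemodynamic lag in TRs (default 2, about 4 s at a 2-s TR);
#'   shifts are zero-filled at each run start.
#' @param channel_weights optional list of `p x v` matrices (one per band)
#'   reusing weights from a previous call, so test runs share the training
#'   runs' ground truth; drawn `N(0, 1)` when `NULL`.
#' @param signal_scale optional per-voxel scale reusing the normalization
#'   of a previous call.
#' @param seed optional integer seed.
#' @return list with `Y` (`n x v`), `signal` (noise- and drift-free part),
#'   `channel_weights` and `signal_scale` (for reuse on test runs).
#' @export
generate_voxel_responses <- function(band_features, truth, run_lengths, tr,
                                     lag = 2, channel_weights = NULL,
                                     signal_scale = NULL, seed = NULL) {
  K <- length(band_features)
  if (K != ncol(truth$band_weights))
    stop_invalid("got %d band feature matrices for %d weight columns",
                 K, ncol(truth$band_weights))
  n <- sum(run_lengths)
  for (bf in band_features)
    if (nrow(bf) != n)
      stop_invalid("feature time length %d does not match run lengths (sum %d)",
                   nrow(bf), n)
  v <- nrow(truth$band_weights)
  p <- ncol(band_features[[1]])
  with_seed_or_current(seed, {
    if (is.null(channel_weights))
      channel_weights <- lapply(seq_len(K), function(i)
        matrix(rnorm(p * v), p, v))
    signal <- matrix(0, n, v)
    for (i in seq_len(K)) {
      lagged <- if (lag > 0) {
        add_fir_delays(band_features[[i]], run_lengths, delays = lag)
      } else {
        band_features[[i]]
      }
      S <- lagged %*% channel_weights[[i]]
      signal <- signal + sweep(S, 2, truth$band_weights[, i], "*")
    }
    if (is.null(signal_scale)) {
      signal_scale <- apply(signal, 2, sd)
      signal_scale[signal_scale < .Machine$double.eps^0.5] <- 1
    }
    signal <- sweep(signal, 2, signal_scale, "/")
    drift <- truth$drift_amplitude *
      do.call(rbind, lapply(run_lengths, function(nr)
        vapply(seq_len(v), function(j) run_drift(nr, tr), numeric(nr))))
    Y <- signal + drift + matrix(rnorm(n * v, 0, truth$noise_sigma), n, v)
    list(Y = Y, signal = signal, channel_weights = channel_weights,
         signal_scale = signal_scale)
  })
}

#' Simulate a full synthetic timescale experiment
#'
#' Builds a complete dataset mirroring one participant x condition of a
#' narrative session: `n_train_runs` training runs and one test run
#' presented `test_repeats` times, each run with its own word sequence and
#' band-limited synthetic embedding; voxel responses are linear in the
#' timescale-specific features derived from those embeddings (filter bank,
#' RBF interpolation, Lanczos downsampling -- the same operations the
#' analysis applies), plus drift and noise. Ground truth is one-hot over
#' bands by default, cycling through all eight bands across voxels.
#'
#' @param n_train_runs number of training runs (default 6).
#' @param run_length_trs TRs per run (default 300, about 10 minutes).
#' @param n_voxels number of voxels (default 200).
#' @param tr repetition time in seconds (default 2.0045).
#' @param mean_interval mean inter-word interval in seconds (default 0.4,
#'   about 150 words per minute).
#' @param jitter coefficient of variation of word intervals (default 0.3).
#' @param dims_per_band embedding dimensions per band (default 2).
#' @param emb_noise white-noise s.d. in the embedding (default 0.3).
#' @param snr per-voxel signal-to-noise variance ratio (default 1).
#' @param drift_amplitude drift s.d. in signal units (default 1).
#' @param bands band table (default [default_bands()]).
#' @param n_taps filter length used to build the generating features
#'   (default 2049, matching the analysis default).
#' @param band_assignment optional band index per voxel; share this across
#'   two simulated conditions to emulate one participant measured twice.
#' @param seed integer seed for full reproducibility.
#' @return An object of class `timescale_dataset`: per-run word sequences
#'   and embeddings (`$runs`, `$test`), raw train/test responses, the run
#'   layout, and the [synthetic_ground_truth()].
#' @export
simulate_timescale_dataset <- function(n_train_runs = 6, run_length_trs = 300,
                                       n_voxels = 200, tr = 2.0045,
                                       mean_interval = 0.4, jitter = 0.3,
                                       dims_per_band = 2, emb_noise = 0.3,
                                       snr = 1, drift_amplitude = 1,
                                       bands = default_bands(), n_taps = 2049,
                                       band_assignment = NULL, seed = 1) {
  K <- nrow(bands)
  if (is.null(band_assignment))
    band_assignment <- rep_len(seq_len(K), n_voxels)
  W <- matrix(0, n_voxels, K)
  W[cbind(seq_len(n_voxels), band_assignment)] <- 1
  truth <- synthetic_ground_truth(W, bands$t, noise_sigma = 1 / sqrt(snr),
                                  drift_amplitude = drift_amplitude,
                                  seed = seed)
  bank <- design_filter_bank(bands, n_taps = n_taps)
  run_secs <- run_length_trs * tr
  n_words <- floor((run_secs - 20) / mean_interval)

  with_seed_or_current(seed, {
    make_run <- function() {
      seq <- generate_word_sequence(n_words, mean_interval, jitter)
      gen <- generate_band_limited_embedding(seq, bands, dims_per_band,
                                             noise = emb_noise)
      list(words = seq, embedding = gen$embedding,
           band_assignment = gen$band_assignment, periods = gen$periods)
    }
    runs <- lapply(seq_len(n_train_runs), function(r) make_run())
    test <- make_run()

    feats <- function(run) {
      filtered <- apply_filter_bank(run$embedding, bank)
      lapply(filtered, function(Fi) {
        dense <- rbf_interpolate(Fi, run$words, run_length_trs, tr)
        lanczos_downsample(dense, run_length_trs, tr)
      })
    }
    train_feats <- lapply(runs, feats)
    band_train <- lapply(seq_len(K), function(i)
      do.call(rbind, lapply(train_feats, `[[`, i)))
    band_test <- feats(test)

    run_lengths <- rep(run_length_trs, n_train_runs)
    gen_train <- generate_voxel_responses(band_train, truth, run_lengths, tr)
    test_reps <- lapply(1:2, function(r)
      generate_voxel_responses(band_test, truth, run_length_trs, tr,
                               channel_weights = gen_train$channel_weights,
                               signal_scale = gen_train$signal_scale)$Y)

    structure(list(runs = runs, test = test,
                   Y_train = gen_train$Y, Y_test_reps = test_reps,
                   layout = run_layout(run_lengths, tr = tr),
                   test_length = run_length_trs,
                   truth = truth, bands = bands,
                   params = list(n_train_runs = n_train_runs,
                                 run_length_trs = run_length_trs,
                                 n_voxels = n_voxels, tr = tr,
                                 mean_interval = mean_interval,
                                 jitter = jitter,
                                 dims_per_band = dims_per_band,
                                 emb_noise = emb_noise, snr = snr,
                                 drift_amplitude = drift_amplitude,
                                 n_taps = n_taps, seed = seed)),
              class = "timescale_dataset")
  })
}

#' @export
print.timescale_dataset <- function(x, ...) {
  cat(sprintf("<timescale_dataset> %d train runs x %d TRs, test run x %d, %d voxels, %d bands\n",
              x$params$n_train_runs, x$params$run_length_trs,
              length(x$Y_test_reps), x$params$n_voxels, nrow(x$bands)))
  invisible(x)
}
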