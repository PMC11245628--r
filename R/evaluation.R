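# Held-out prediction, joint / split prediction performance, and
# language-selective voxel identification.

#' Predict held-out responses, jointly and per feature space
#'
#' The per-space prediction uses only that space's columns of the weight
#' matrix, so the joint prediction equals the sum of the per-space
#' predictions exactly.
#'
#' @param model an [solve_banded_ridge()] encoding model.
#' @param X `n x D` test design, z-scored with training statistics.
#' @return list with `joint` (`n x v`) and `spaces` (named list of
#'   `n x v` per-space predictions).
#' @export
predict_encoding <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$D)
    stop_invalid("test design has %d columns, model expects %d", ncol(X), model$D)
  spaces <- lapply(model$spaces, function(idx)
    X[, idx, drop = FALSE] %*% model$B[idx, , drop = FALSE])
  list(joint = Reduce(`+`, spaces), spaces = spaces)
}

#' Joint prediction performance
#'
#' Pearson correlation per voxel between predicted and recorded responses.
#' Zero-variance predictions get `r = 0` and a flag instead of `NA`.
#'
#' @param yhat,y `n x v` matrices.
#' @return numeric vector of correlations with attribute `"flagged"`.
#' @export
joint_r <- function(yhat, y) {
  if (!identical(dim(yhat), dim(y))) stop_invalid("yhat and y shapes differ")
  if (nrow(y) < 3) stop_invalid("need at least 3 time points")
  sd_h <- apply(yhat, 2, sd)
  sd_y <- apply(y, 2, sd)
  flagged <- sd_h < .Machine$double.eps^0.5 | sd_y < .Machine$double.eps^0.5
  r <- numeric(ncol(y))
  ok <- !flagged
  if (any(ok)) {
    yh <- scale(yhat[, ok, drop = FALSE], scale = FALSE)
    yc <- scale(y[, ok, drop = FALSE], scale = FALSE)
    r[ok] <- colSums(yh * yc) / sqrt(colSums(yh^2) * colSums(yc^2))
  }
  attr(r, "flagged") <- flagged
  r
}

# Internal centered split-performance kernel. yhat_c: list of centered
# per-space predictions; joint_ss: per-voxel sum of squares of the
# centered joint prediction; y_c: centered responses; y_ss: per-voxel sum
# of squares of y_c. Returns v x m matrix.
split_r_centered <- function(yhat_c, joint_ss, y_c, y_ss) {
  denom <- sqrt(joint_ss * y_ss)
  bad <- denom < .Machine$double.eps
  denom[bad] <- 1
  out <- vapply(yhat_c, function(h) {
    val <- colSums(h * y_c) / denom
    val[bad] <- 0
    val
  }, numeric(ncol(y_c)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

#' Split prediction performance per feature space
#'
#' Decomposes the joint prediction performance `r` into one contribution
#' per feature space: the cross-moment of that space's prediction with the
#' recorded response, normalized by the product of the *joint* prediction
#' norm and the response norm. Signals are mean-centered per voxel before
#' the sums, so the split performances always sum to the joint Pearson
#' correlation. Individual contributions may be negative.
#'
#' @param yhat_spaces named list of `n x v` per-space predictions.
#' @param y `n x v` recorded responses.
#' @return `v x m` matrix of split performances (columns named by space)
#'   with the joint correlation in attribute `"joint_r"`.
#' @export
split_r <- function(yhat_spaces, y) {
  y_c <- scale(y, scale = FALSE)
  yhat_c <- lapply(yhat_spaces, function(h) scale(h, scale = FALSE))
  joint_c <- Reduce(`+`, yhat_c)
  joint_ss <- colSums(joint_c^2)
  y_ss <- colSums(y_c^2)
  out <- split_r_centered(yhat_c, joint_ss, y_c, y_ss)
  colnames(out) <- names(yhat_spaces)
  attr(out, "joint_r") <- rowSums(out)
  out
}

#' Total split performance of the language timescale bands
#'
#' Sums the split-prediction performance over exactly the eight language
#' timescale spaces, excluding any nuisance (sensory) spaces; negative
#' contributions are retained.
#'
#' @param split `v x m` split-performance matrix from [split_r()].
#' @param language names (or indices) of the eight timescale spaces.
#' @return numeric vector, one value per voxel.
#' @export
r_all_timescales <- function(split, language) {
  if (is.character(language)) {
    missing <- setdiff(language, colnames(split))
    if (length(missing))
      stop_invalid("split matrix is missing language band(s): %s",
                   paste(missing, collapse = ", "))
  }
  sel <- split[, language, drop = FALSE]
  if (ncol(sel) != 8)
    stop_invalid("exactly 8 language timescale bands are required (got %d)", ncol(sel))
  rowSums(sel)
}

# Partition 1:n into consecutive blocks of `block` TRs (final short block
# kept intact) and return the row order induced by a random reordering of
# the blocks.
block_permutation <- function(n, block) {
  starts <- seq(1, n, by = block)
  blocks <- lapply(starts, function(s) s:min(s + block - 1, n))
  unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
}

#' Blockwise permutation test of the language split performance
#'
#' Tests, per voxel, whether the summed split performance of the eight
#' timescale bands exceeds chance. At each iteration the held-out response
#' timecourse is partitioned into consecutive blocks of `block` TRs (the
#' final short block kept intact), the blocks are randomly reordered, and
#' the statistic is recomputed, yielding an empirical null. Blocks rather
#' than single TRs are shuffled to respect the autocorrelation of BOLD
#' responses. The one-sided p-value uses add-one smoothing:
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param yhat_spaces named list of per-space test predictions.
#' @param y `n x v` recorded test responses.
#' @param language names of the eight timescale spaces.
#' @param n_perm permutation iterations (default 1000).
#' @param block block length in TRs (default 10).
#' @param seed optional integer seed.
#' @return list with `p` (per-voxel p-values), `observed` statistics, and
#'   the `null` matrix (`n_perm x v`).
#' @export
blockwise_permutation_test <- function(yhat_spaces, y, language,
                                       n_perm = 1000, block = 10,
                                       seed = NULL) {
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  n <- nrow(y)
  if (n < 2 * block) stop_invalid("test timecourse must span at least 2 blocks")
  y_c <- scale(y, scale = FALSE)
  yhat_c <- lapply(yhat_spaces, function(h) scale(h, scale = FALSE))
  joint_ss <- colSums(Reduce(`+`, yhat_c)^2)
  y_ss <- colSums(y_c^2)
  lang_c <- Reduce(`+`, yhat_c[language])
  denom <- sqrt(joint_ss * y_ss)
  bad <- denom < .Machine$double.eps
  denom[bad] <- 1
  stat <- function(yp) {
    val <- colSums(lang_c * yp) / denom
    val[bad] <- 0
    val
  }
  observed <- stat(y_c)
  null <- with_seed_or_current(seed, {
    t(vapply(seq_len(n_perm), function(i)
      stat(y_c[block_permutation(n, block), , drop = FALSE]),
      numeric(ncol(y))))
  })
  p <- (1 + colSums(null >= rep(observed, each = n_perm))) / (1 + n_perm)
  list(p = p, observed = observed, null = null)
}

#' Benjamini-Hochberg FDR correction and selectivity mask
#'
#' @param p vector of p-values in `(0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (BH-adjusted values) and `selective`
#'   (`q < alpha`); empty input gives empty outputs.
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(list(q = numeric(0), selective = logical(0)))
  if (any(p <= 0 | p > 1)) stop_invalid("p-values must lie in (0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, selective = q < alpha)
}
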