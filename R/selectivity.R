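# Timescale selectivity profiles, scalar selectivity, and cross-condition
# comparison.

#' Timescale selectivity profile
#'
#' Normalizes each voxel's vector of split-prediction performances over
#' the eight timescale bands into a proper set of proportions: negative
#' entries are clipped to zero and the vector is rescaled to sum to one.
#' Voxels whose split performances are all non-positive have no defined
#' profile and are flagged (and excluded from downstream selectivity
#' analyses) rather than assigned an arbitrary value.
#'
#' @param split `v x 8` matrix of split performances for the language
#'   bands (see [split_r()] and [r_all_timescales()]).
#' @return list with `profile` (`v x 8`, rows summing to 1 or all `NA`)
#'   and `defined` (logical per voxel).
#' @export
selectivity_profile <- function(split) {
  split <- as.matrix(split)
  if (ncol(split) != 8)
    stop_invalid("selectivity profiles are defined over exactly 8 bands (got %d)",
                 ncol(split))
  clipped <- pmax(split, 0)
  tot <- rowSums(clipped)
  defined <- tot > 0
  profile <- clipped / ifelse(defined, tot, 1)
  profile[!defined, ] <- NA_real_
  list(profile = profile, defined = defined)
}

#' Scalar timescale selectivity
#'
#' The profile-weighted mean of the log2 nominal band timescales, mapped
#' back through `2^x`: a weighted geometric mean of the band timescales,
#' in words. A weighted average is used rather than the argmax so that
#' small changes in prediction accuracy cannot produce large jumps in the
#' estimate. Undefined profiles propagate `NA`.
#'
#' @param profile `v x 8` selectivity profile (rows sum to 1).
#' @param timescales the 8 nominal band timescales `t_i` in words.
#' @return numeric vector of selectivities, bounded by `range(timescales)`
#'   wherever defined.
#' @export
timescale_selectivity <- function(profile, timescales = default_bands()$t) {
  profile <- as.matrix(profile)
  if (ncol(profile) != length(timescales))
    stop_invalid("profile has %d bands but %d timescales were given",
                 ncol(profile), length(timescales))
  if (any(timescales <= 0)) stop_invalid("timescales must be positive")
  2^drop(profile %*% log2(timescales))
}

#' Bundle one condition's evaluation for cross-condition comparison
#'
#' @param yhat_spaces named list of per-space test predictions.
#' @param y test responses (`n x v`).
#' @param language names of the eight timescale spaces.
#' @param timescales nominal band timescales (words).
#' @return An object of class `condition_eval`.
#' @export
condition_eval <- function(yhat_spaces, y, language,
                           timescales = default_bands()$t) {
  stopifnot(length(language) == 8, length(timescales) == 8)
  structure(list(yhat_spaces = yhat_spaces, y = y, language = language,
                 timescales = timescales),
            class = "condition_eval")
}

# Split performances of the language bands for (possibly permuted)
# responses, from precomputed centered pieces.
cond_precompute <- function(cond) {
  y_c <- scale(cond$y, scale = FALSE)
  yhat_c <- lapply(cond$yhat_spaces, function(h) scale(h, scale = FALSE))
  list(y_c = y_c, yhat_lang_c = yhat_c[cond$language],
       joint_ss = colSums(Reduce(`+`, yhat_c)^2), y_ss = colSums(y_c^2))
}

cond_split <- function(pc, perm = NULL) {
  y <- if (is.null(perm)) pc$y_c else pc$y_c[perm, , drop = FALSE]
  split_r_centered(pc$yhat_lang_c, pc$joint_ss, y, pc$y_ss)
}

cond_tbar <- function(pc, timescales, perm = NULL) {
  prof <- selectivity_profile(cond_split(pc, perm))
  list(tbar = timescale_selectivity(prof$profile, timescales),
       defined = prof$defined, profile = prof$profile)
}

masked_cor <- function(a, b, mask) {
  ok <- mask & is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NA_real_)
  cor(a[ok], b[ok])
}

#' Compare timescale selectivity between two conditions
#'
#' Correlates per-voxel timescale selectivity between two stimulus
#' conditions across the voxels selective in both, and assesses
#' significance with a blockwise permutation test: at each iteration the
#' test responses of each condition are independently shuffled in blocks,
#' null selectivities are recomputed for both conditions from the shuffled
#' responses, and the null selectivities are correlated to form the null
#' distribution. The p-value is one-sided with add-one smoothing.
#'
#' @param cond_a,cond_b [condition_eval()] objects for the two conditions.
#' @param mask logical per voxel, selective in both conditions; at least 3
#'   voxels required.
#' @param n_perm permutation iterations (default 1000).
#' @param block block length in TRs (default 10).
#' @param seed optional integer seed.
#' @return list with `r` (Pearson correlation of selectivity over the
#'   mask), `p`, the `null` correlations, and per-condition selectivity.
#' @export
compare_selectivity <- function(cond_a, cond_b, mask, n_perm = 1000,
                                block = 10, seed = NULL) {
  if (sum(mask) < 3) stop_invalid("joint selective mask must contain >= 3 voxels")
  pa <- cond_precompute(cond_a)
  pb <- cond_precompute(cond_b)
  obs_a <- cond_tbar(pa, cond_a$timescales)
  obs_b <- cond_tbar(pb, cond_b$timescales)
  r_obs <- masked_cor(obs_a$tbar, obs_b$tbar, mask)
  null <- with_seed_or_current(seed, {
    vapply(seq_len(n_perm), function(i) {
      na <- cond_tbar(pa, cond_a$timescales,
                      block_permutation(nrow(cond_a$y), block))
      nb <- cond_tbar(pb, cond_b$timescales,
                      block_permutation(nrow(cond_b$y), block))
      masked_cor(na$tbar, nb$tbar, mask)
    }, numeric(1))
  })
  p <- (1 + sum(null >= r_obs, na.rm = TRUE)) / (1 + n_perm)
  list(r = r_obs, p = p, null = null,
       tbar_a = obs_a$tbar, tbar_b = obs_b$tbar)
}

#' Compare selectivity for each timescale band separately
#'
#' For each of the eight bands, correlates that band's selectivity-profile
#' entry between the two conditions across masked voxels, with a blockwise
#' permutation null built exactly as in [compare_selectivity()].
#'
#' @inheritParams compare_selectivity
#' @return data frame with one row per band: `r` and `p`.
#' @export
per_band_comparison <- function(cond_a, cond_b, mask, n_perm = 1000,
                                block = 10, seed = NULL) {
  if (sum(mask) < 3) stop_invalid("joint selective mask must contain >= 3 voxels")
  pa <- cond_precompute(cond_a)
  pb <- cond_precompute(cond_b)
  obs_a <- cond_tbar(pa, cond_a$timescales)
  obs_b <- cond_tbar(pb, cond_b$timescales)
  r_obs <- vapply(1:8, function(i)
    masked_cor(obs_a$profile[, i], obs_b$profile[, i], mask), numeric(1))
  null <- with_seed_or_current(seed, {
    t(vapply(seq_len(n_perm), function(it) {
      na <- cond_tbar(pa, cond_a$timescales,
                      block_permutation(nrow(cond_a$y), block))
      nb <- cond_tbar(pb, cond_b$timescales,
                      block_permutation(nrow(cond_b$y), block))
      vapply(1:8, function(i)
        masked_cor(na$profile[, i], nb$profile[, i], mask), numeric(1))
    }, numeric(8)))
  })
  p <- vapply(1:8, function(i)
    (1 + sum(null[, i] >= r_obs[i], na.rm = TRUE)) / (1 + n_perm), numeric(1))
  data.frame(band = 1:8, r = r_obs, p = p)
}

#' Per-voxel correlation of selectivity profiles between conditions
#'
#' Pearson correlation of the two 8-band profiles within each voxel.
#' Voxels with an undefined profile in either condition, or a constant
#' profile (zero variance across bands), are returned as `NA`.
#'
#' @param profile_a,profile_b `v x 8` selectivity profiles.
#' @param mask optional logical per voxel; unmasked voxels return `NA`.
#' @return numeric vector of per-voxel correlations.
#' @export
profile_correlation <- function(profile_a, profile_b, mask = NULL) {
  v <- nrow(profile_a)
  if (!identical(dim(profile_a), dim(profile_b)))
    stop_invalid("profiles have mismatched shapes")
  if (is.null(mask)) mask <- rep(TRUE, v)
  out <- rep(NA_real_, v)
  for (i in which(mask)) {
    a <- profile_a[i, ]; b <- profile_b[i, ]
    if (anyNA(a) || anyNA(b) || sd(a) == 0 || sd(b) == 0) next
    out[i] <- cor(a, b)
  }
  out
}

#' Aggregate per-subject values on a shared vertex grid
#'
#' For each vertex, averages the value over the subjects in whom the
#' vertex is selective, and builds a group mask of vertices selective in
#' at least `ceiling(min_fraction * n_subjects)` subjects. All subjects
#' must share the vertex grid (surface projection is assumed upstream).
#'
#' @param values `n_subjects x n_vertices` matrix of per-subject values.
#' @param masks `n_subjects x n_vertices` logical matrix of per-subject
#'   selectivity.
#' @param min_fraction minimum fraction of subjects (default 1/3).
#' @return list with `values` (group mean, `NA` where no subject is
#'   selective), `mask`, and `n_selective` per vertex.
#' @export
group_aggregate <- function(values, masks, min_fraction = 1 / 3) {
  values <- as.matrix(values); masks <- as.matrix(masks)
  if (!identical(dim(values), dim(masks)))
    stop_invalid("values and masks must share the subject x vertex grid")
  n_subj <- nrow(values)
  n_sel <- colSums(masks)
  masked <- values
  masked[!masks] <- NA
  group <- colMeans(masked, na.rm = TRUE)
  group[n_sel == 0] <- NA_real_
  list(values = group, mask = n_sel >= ceiling(min_fraction * n_subj),
       n_selective = n_sel)
}
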