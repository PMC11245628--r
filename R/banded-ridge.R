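# Banded ridge regression: closed-form solve with per-group penalties and
# the two-stage hyperparameter search (Dirichlet random search over the
# penalty simplex, then backtracking gradient descent on log-penalties).

validate_groups <- function(groups, D) {
  idx <- sort(unlist(groups, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(D)))
    stop_invalid("groups must partition the %d design columns exactly once", D)
  groups
}

# Expand per-group penalties to per-column penalties.
column_penalties <- function(penalties, groups, D) {
  out <- numeric(D)
  for (g in seq_along(groups)) out[groups[[g]]] <- penalties[g]
  out
}

#' Solve banded ridge regression in closed form
#'
#' Minimizes `||Y - X B||^2 + sum_g lambda_g ||B_g||^2` per voxel, where
#' the design columns are partitioned into groups (feature spaces,
#' optionally crossed with FIR delay) and each group has its own
#' regularization penalty. Penalties may be shared across voxels (a vector)
#' or voxel-specific (a `v x G` matrix); voxels sharing a penalty row are
#' solved together through one Cholesky factorization.
#'
#' @param X `n x D` design matrix.
#' @param Y `n x v` response matrix.
#' @param groups list of integer vectors partitioning the `D` columns.
#' @param penalties numeric vector of length `G = length(groups)`, or a
#'   `v x G` matrix of per-voxel penalties; all values must be finite and
#'   `>= 0`.
#' @param spaces optional named list mapping feature-space name to column
#'   indices (defaults to `groups`); used later to split predictions.
#' @return An object of class `encoding_model`: weights `B` (`D x v`),
#'   the group partition, spaces, and the penalties used.
#' @export
solve_banded_ridge <- function(X, Y, groups, penalties, spaces = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop_invalid("design and responses must be finite")
  n <- nrow(X); D <- ncol(X); v <- ncol(Y)
  if (nrow(Y) != n) stop_invalid("X and Y must have the same number of rows")
  validate_groups(groups, D)
  G <- length(groups)
  if (is.null(dim(penalties))) {
    if (length(penalties) != G)
      stop_invalid("penalties must have one value per group (%d)", G)
    penalties <- matrix(penalties, v, G, byrow = TRUE)
  }
  if (nrow(penalties) != v || ncol(penalties) != G)
    stop_invalid("penalty matrix must be v x G = %d x %d", v, G)
  if (any(!is.finite(penalties)) || any(penalties < 0))
    stop_invalid("penalties must be finite and >= 0")

  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  B <- matrix(0, D, v)
  key <- apply(penalties, 1, paste, collapse = ",")
  for (k in unique(key)) {
    vox <- which(key == k)
    lam <- column_penalties(penalties[vox[1], ], groups, D)
    A <- XtX
    diag(A) <- diag(A) + lam
    R <- chol(A)
    B[, vox] <- backsolve(R, backsolve(R, XtY[, vox, drop = FALSE],
                                       transpose = TRUE))
  }
  if (is.null(spaces)) {
    spaces <- groups
    if (is.null(names(spaces))) names(spaces) <- paste0("space_", seq_along(spaces))
  }
  structure(list(B = B, groups = groups, spaces = spaces,
                 penalties = penalties, D = D, n_train = n),
            class = "encoding_model")
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf("<encoding_model> %d columns x %d voxels, %d penalty groups, %d spaces\n",
              x$D, ncol(x$B), length(x$groups), length(x$spaces)))
  invisible(x)
}

#' Leave-one-run-out cross-validation folds
#'
#' Each fold holds out exactly one training run for validation; folds are
#' disjoint and cover every run, so the number of folds equals the number
#' of training runs (ten runs give the standard tenfold scheme).
#'
#' @param run_lengths per-run lengths (TRs) of the training runs.
#' @param n_folds number of folds; must equal the number of runs (the
#'   default).
#' @return list of folds, each with `train` and `val` row indices and the
#'   held-out `run` index.
#' @export
make_cv_folds <- function(run_lengths, n_folds = length(run_lengths)) {
  n_runs <- length(run_lengths)
  if (n_runs < n_folds)
    stop_invalid("cannot make %d folds from %d runs", n_folds, n_runs)
  if (n_folds != n_runs)
    stop_invalid("leave-one-run-out requires n_folds == number of runs (%d)", n_runs)
  starts <- run_starts(run_lengths)
  all_rows <- seq_len(sum(run_lengths))
  lapply(seq_len(n_runs), function(r) {
    val <- starts[r]:(starts[r] + run_lengths[r] - 1)
    list(train = setdiff(all_rows, val), val = val, run = r)
  })
}

# Per-fold precomputations shared by the search stages.
fold_precompute <- function(X, Y, folds) {
  lapply(folds, function(f) {
    Xt <- X[f$train, , drop = FALSE]
    list(G = crossprod(Xt),
         XtY = crossprod(Xt, Y[f$train, , drop = FALSE]),
         Xv = X[f$val, , drop = FALSE],
         Yv = Y[f$val, , drop = FALSE])
  })
}

#' Random hyperparameter search for banded ridge
#'
#' Stage one of hyperparameter selection. Normalized per-group penalty
#' candidates are sampled from a Dirichlet distribution and each candidate
#' is scaled by `n_scales` log-spaced overall scales; every combination is
#' evaluated by leave-one-run-out cross-validation, and for each voxel the
#' combination minimizing the summed validation squared error across folds
#' is kept. Because ridge solutions along the scale axis share one
#' eigendecomposition per candidate and fold, the grid costs little more
#' than the candidates alone.
#'
#' @param X `n x D` training design.
#' @param Y `n x v` training responses.
#' @param folds folds from [make_cv_folds()].
#' @param groups column partition (penalty groups).
#' @param n_candidates Dirichlet samples (default 1000).
#' @param n_scales log-spaced overall scales (default 10).
#' @param scale_range range of the overall scale (default `c(1e-5, 1e5)`).
#' @param dirichlet_alpha concentration of the Dirichlet (default 1,
#'   uniform on the simplex).
#' @param combinations `"grid"` evaluates every candidate at every scale
#'   (`n_candidates * n_scales` fits); `"paired"` recycles the scales
#'   across candidates for `n_candidates` total fits.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return list with `penalties` (`v x G` selected penalties), `cv_loss`
#'   (per-voxel summed validation SSE of the selected combination),
#'   `candidate` and `scale` indices per voxel, and the sampled simplex
#'   `weights` and `scales`.
#' @export
random_search <- function(X, Y, folds, groups, n_candidates = 1000,
                          n_scales = 10, scale_range = c(1e-5, 1e5),
                          dirichlet_alpha = 1,
                          combinations = c("grid", "paired"), seed = NULL) {
  combinations <- match.arg(combinations)
  X <- as.matrix(X); Y <- as.matrix(Y)
  D <- ncol(X); v <- ncol(Y); G <- length(groups)
  validate_groups(groups, D)
  if (any(scale_range <= 0)) stop_invalid("scale_range must be positive")
  if (n_candidates < 1) stop_invalid("n_candidates must be >= 1")
  scales <- 10^seq(log10(scale_range[1]), log10(scale_range[2]),
                   length.out = n_scales)
  W <- with_seed_or_current(seed, {
    raw <- matrix(rgamma(n_candidates * G, shape = dirichlet_alpha),
                  n_candidates, G)
    raw / rowSums(raw)
  })
  W <- pmax(W, 1e-12)

  pre <- fold_precompute(X, Y, folds)
  loss <- matrix(0, n_candidates * n_scales, v)
  scale_sets <- if (combinations == "grid") {
    rep(list(seq_len(n_scales)), n_candidates)
  } else {
    split(rep_len(seq_len(n_scales), n_candidates), seq_len(n_candidates))
  }
  for (f in pre) {
    for (c in seq_len(n_candidates)) {
      dvec <- 1 / sqrt(column_penalties(W[c, ], groups, D))
      Gc <- f$G * tcrossprod(dvec)
      eg <- eigen(Gc, symmetric = TRUE)
      A <- (f$Xv * rep(dvec, each = nrow(f$Xv))) %*% eg$vectors
      Z <- crossprod(eg$vectors, f$XtY * dvec)
      ev <- pmax(eg$values, 0)
      for (s in scale_sets[[c]]) {
        P <- A %*% (Z / (ev + scales[s]))
        loss[(c - 1) * n_scales + s, ] <-
          loss[(c - 1) * n_scales + s, ] + colSums((P - f$Yv)^2)
      }
    }
  }
  if (combinations == "paired") {
    used <- unlist(lapply(seq_len(n_candidates), function(c)
      (c - 1) * n_scales + scale_sets[[c]]))
    loss[setdiff(seq_len(nrow(loss)), used), ] <- Inf
  }
  best <- apply(loss, 2, which.min)
  cand <- (best - 1) %/% n_scales + 1
  sc <- (best - 1) %% n_scales + 1
  penalties <- W[cand, , drop = FALSE] * scales[sc]
  list(penalties = penalties, cv_loss = loss[cbind(best, seq_len(v))],
       candidate = cand, scale = scales[sc], weights = W, scales = scales,
       groups = groups)
}

# Summed validation SSE across folds for one voxel at penalties lam (per
# group), with optional gradient wrt log-penalties. `pre` as from
# fold_precompute, restricted to one voxel's XtY / Yv columns.
voxel_cv_loss <- function(lam, groups, pre_v, grad = FALSE) {
  D <- nrow(pre_v[[1]]$G)
  lam_col <- column_penalties(lam, groups, D)
  total <- 0
  gvec <- numeric(length(groups))
  for (f in pre_v) {
    A <- f$G
    diag(A) <- diag(A) + lam_col
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(list(loss = Inf, grad = gvec))
    wts <- backsolve(R, backsolve(R, f$Xty, transpose = TRUE))
    resid <- drop(f$Xv %*% wts) - f$yv
    total <- total + sum(resid^2)
    if (grad) {
      u <- backsolve(R, backsolve(R, crossprod(f$Xv, resid), transpose = TRUE))
      for (g in seq_along(groups)) {
        idx <- groups[[g]]
        gvec[g] <- gvec[g] - 2 * lam[g] * sum(u[idx] * wts[idx])
      }
    }
  }
  list(loss = total, grad = gvec)
}

#' Gradient refinement of banded-ridge hyperparameters
#'
#' Stage two of hyperparameter selection. For the voxels with the lowest
#' `top_frac` fraction of stage-one cross-validated loss, the log-penalties
#' are refined by backtracking gradient descent on the leave-one-run-out
#' validation loss. Steps that do not decrease the loss are halved and
#' eventually rejected, so the refined loss is never worse than the
#' stage-one loss; all other voxels keep their stage-one penalties.
#'
#' @param X,Y,folds,groups as in [random_search()].
#' @param start the list returned by [random_search()].
#' @param top_frac fraction of voxels (lowest CV loss) to refine
#'   (default 0.2).
#' @param n_iter maximum gradient iterations per voxel (default 1000).
#' @param step initial step size on log-penalties (default 0.5).
#' @param tol stop a voxel when the accepted relative improvement falls
#'   below this (default 1e-10).
#' @return list with refined `penalties`, `cv_loss`, and `refined` (the
#'   voxel indices that entered stage two).
#' @export
gradient_refine <- function(X, Y, folds, groups, start, top_frac = 0.2,
                            n_iter = 1000, step = 0.5, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  v <- ncol(Y)
  penalties <- start$penalties
  cv_loss <- start$cv_loss
  n_refine <- max(1L, floor(top_frac * v))
  refined <- order(cv_loss)[seq_len(n_refine)]
  pre <- fold_precompute(X, Y, folds)
  for (vox in refined) {
    pre_v <- lapply(seq_along(pre), function(i)
      list(G = pre[[i]]$G, Xty = pre[[i]]$XtY[, vox],
           Xv = pre[[i]]$Xv, yv = pre[[i]]$Yv[, vox]))
    theta <- log(pmax(penalties[vox, ], 1e-12))
    cur <- voxel_cv_loss(exp(theta), groups, pre_v, grad = TRUE)
    if (!is.finite(cur$loss)) next
    st <- step
    for (it in seq_len(n_iter)) {
      gnorm <- sqrt(sum(cur$grad^2))
      if (gnorm < 1e-14) break
      accepted <- FALSE
      for (half in seq_len(30)) {
        cand_theta <- theta - st * cur$grad / gnorm
        cand <- voxel_cv_loss(exp(cand_theta), groups, pre_v, grad = FALSE)
        if (cand$loss <= cur$loss) { accepted <- TRUE; break }
        st <- st / 2
      }
      if (!accepted) break
      improved <- (cur$loss - cand$loss) / max(cur$loss, .Machine$double.eps)
      theta <- cand_theta
      cur <- voxel_cv_loss(exp(theta), groups, pre_v, grad = TRUE)
      st <- min(st * 1.5, 10)
      if (improved < tol) break
    }
    if (cur$loss <= cv_loss[vox] + 1e-9 * max(1, cv_loss[vox])) {
      penalties[vox, ] <- exp(theta)
      cv_loss[vox] <- min(cur$loss, cv_loss[vox])
    }
  }
  list(penalties = penalties, cv_loss = cv_loss, refined = refined,
       groups = groups)
}
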