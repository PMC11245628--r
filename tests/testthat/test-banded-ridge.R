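make_instance <- function(n, sizes, v = 2, seed = 1) {
  set.seed(seed)
  D <- sum(sizes)
  groups <- split(seq_len(D), rep(seq_along(sizes), sizes))
  list(X = matrix(rnorm(n * D), n), Y = matrix(rnorm(n * v), n),
       groups = unname(groups))
}

test_that("banded ridge reduces to standard ridge and OLS in the limits", {
  inst <- make_instance(30, c(3, 4), seed = 2)
  lam <- 2.5
  fit <- solve_banded_ridge(inst$X, inst$Y, inst$groups, c(lam, lam))
  for (j in 1:2)
    expect_equal(fit$B[, j], drop(svd_ridge(inst$X, inst$Y[, j], lam)),
                 tolerance = 1e-10)
  # vanishing penalties on a tall full-rank design: OLS
  fit0 <- solve_banded_ridge(inst$X, inst$Y, inst$groups, c(1e-12, 1e-12))
  ols <- qr.solve(inst$X, inst$Y)
  expect_lt(max(abs(fit0$B - ols)), 1e-6)
  expect_error(solve_banded_ridge(inst$X * NA, inst$Y, inst$groups, c(1, 1)),
               "finite")
  expect_error(solve_banded_ridge(inst$X, inst$Y, inst$groups, c(-1, 1)),
               "penalties")
})

test_that("closed-form solutions minimize the banded objective (optimizer oracle)", {
  inst <- make_instance(20, c(2, 2), v = 1, seed = 3)
  pen <- c(1, 100)
  fit <- solve_banded_ridge(inst$X, inst$Y, inst$groups, pen)
  opt <- optim(rep(0, 4), banded_ridge_objective, X = inst$X,
               y = inst$Y[, 1], groups = inst$groups, penalties = pen,
               method = "BFGS", control = list(reltol = 1e-14, maxit = 5000))
  expect_lt(max(abs(fit$B[, 1] - opt$par)), 1e-6)
  # the closed form never scores worse than the optimizer
  expect_lte(banded_ridge_objective(fit$B[, 1], inst$X, inst$Y[, 1],
                                    inst$groups, pen),
             opt$value + 1e-8)
})

test_that("scaling a band's columns by s and its penalty by s^2 leaves predictions unchanged", {
  inst <- make_instance(25, c(3, 3), seed = 4)
  pen <- c(0.7, 12)
  fit1 <- solve_banded_ridge(inst$X, inst$Y, inst$groups, pen)
  s <- 5
  X2 <- inst$X
  X2[, inst$groups[[2]]] <- X2[, inst$groups[[2]]] * s
  fit2 <- solve_banded_ridge(X2, inst$Y, inst$groups, c(pen[1], pen[2] * s^2))
  expect_lt(max(abs(inst$X %*% fit1$B - X2 %*% fit2$B)), 1e-8)
})

test_that("per-voxel penalty matrices solve each voxel at its own penalties", {
  inst <- make_instance(30, c(2, 3), v = 3, seed = 5)
  P <- rbind(c(1, 2), c(10, 0.1), c(1, 2))
  fit <- solve_banded_ridge(inst$X, inst$Y, inst$groups, P)
  for (j in 1:3) {
    single <- solve_banded_ridge(inst$X, inst$Y[, j, drop = FALSE],
                                 inst$groups, P[j, ])
    expect_equal(fit$B[, j], single$B[, 1], tolerance = 1e-12)
  }
})

test_that("cross-validation folds hold out exactly one run each", {
  folds <- make_cv_folds(c(90, 100, 110))
  expect_length(folds, 3)
  vals <- lapply(folds, `[[`, "val")
  expect_equal(sort(unlist(vals)), 1:300)
  for (i in 1:3) {
    expect_length(intersect(folds[[i]]$train, folds[[i]]$val), 0)
    expect_equal(sort(c(folds[[i]]$train, folds[[i]]$val)), 1:300)
  }
  expect_error(make_cv_folds(c(90, 100), n_folds = 3), "folds")
})

test_that("random search with one band equals an exhaustive 1-D grid", {
  set.seed(6)
  n_run <- 30
  X <- matrix(rnorm(3 * n_run * 5), 3 * n_run)
  beta <- rnorm(5)
  Y <- cbind(X %*% beta + rnorm(3 * n_run, 0, 2),
             X %*% (beta * 0.2) + rnorm(3 * n_run, 0, 0.5))
  folds <- make_cv_folds(rep(n_run, 3))
  groups <- list(1:5)
  rs <- random_search(X, Y, folds, groups, n_candidates = 7, n_scales = 10,
                      seed = 11)
  scales <- 10^seq(-5, 5, length.out = 10)
  grid_losses <- vapply(scales, function(l) grid_cv_loss(X, Y, folds, l),
                        numeric(2))
  for (j in 1:2) {
    expect_equal(rs$penalties[j, 1], scales[which.min(grid_losses[j, ])],
                 tolerance = 1e-9)
    expect_equal(rs$cv_loss[j], min(grid_losses[j, ]), tolerance = 1e-6)
  }
  # determinism under a fixed seed
  rs2 <- random_search(X, Y, folds, groups, n_candidates = 7, n_scales = 10,
                       seed = 11)
  expect_identical(rs$penalties, rs2$penalties)
  expect_error(random_search(X, Y, folds, groups, scale_range = c(0, 1)),
               "scale_range")
})

test_that("on null data the best CV loss cannot beat the response variance by much", {
  set.seed(7)
  n_run <- 40
  X <- matrix(rnorm(3 * n_run * 6), 3 * n_run)
  Y <- matrix(rnorm(3 * n_run * 4), 3 * n_run)  # independent of X
  folds <- make_cv_folds(rep(n_run, 3))
  rs <- random_search(X, Y, folds, list(1:3, 4:6), n_candidates = 30,
                      seed = 12)
  # total SSE of predicting an independent response is at least about the
  # total sum of squares of Y (a ridge cannot find real structure)
  tss <- colSums(Y^2)
  expect_true(all(rs$cv_loss > 0.7 * tss))
})

test_that("gradient refinement is monotone and finds the analytic CV optimum", {
  # designed toy: identity designs in both runs, shared signal; the
  # leave-one-run-out loss has a closed-form optimal penalty
  set.seed(8)
  n <- 12
  beta <- rnorm(n, 0, 2)
  a <- beta + rnorm(n, 0, 0.5)
  b <- beta + rnorm(n, 0, 0.5)
  X <- rbind(diag(n), diag(n))
  Y <- matrix(c(a, b), ncol = 1)
  folds <- make_cv_folds(c(n, n))
  groups <- list(1:n)
  c_star <- 2 * sum(a * b) / (sum(a^2) + sum(b^2))
  lambda_star <- 1 / c_star - 1
  rs <- random_search(X, Y, folds, groups, n_candidates = 3, n_scales = 10,
                      seed = 13)
  ref <- gradient_refine(X, Y, folds, groups, rs, top_frac = 1,
                         n_iter = 200, step = 0.5)
  expect_lte(ref$cv_loss[1], rs$cv_loss[1] + 1e-9)
  expect_lt(abs(ref$penalties[1, 1] - lambda_star) / lambda_star, 0.1)

  # starting at the optimum, refinement must not move the loss
  start <- rs
  start$penalties <- matrix(lambda_star, 1, 1)
  start$cv_loss <- langscales:::voxel_cv_loss(
    lambda_star, groups,
    lapply(langscales:::fold_precompute(X, Y, folds), function(f)
      list(G = f$G, Xty = f$XtY[, 1], Xv = f$Xv, yv = f$Yv[, 1])))$loss
  ref2 <- gradient_refine(X, Y, folds, groups, start, top_frac = 1,
                          n_iter = 50)
  expect_lt(abs(ref2$cv_loss[1] - start$cv_loss), 1e-8)
})

test_that("refinement never worsens any refined voxel on random problems", {
  set.seed(9)
  n_run <- 25
  X <- matrix(rnorm(2 * n_run * 8), 2 * n_run)
  B <- matrix(rnorm(8 * 5), 8)
  Y <- X %*% B + matrix(rnorm(2 * n_run * 5, 0, 3), 2 * n_run)
  folds <- make_cv_folds(rep(n_run, 2))
  groups <- list(1:4, 5:8)
  rs <- random_search(X, Y, folds, groups, n_candidates = 10, seed = 14)
  ref <- gradient_refine(X, Y, folds, groups, rs, top_frac = 0.5, n_iter = 30)
  expect_true(all(ref$cv_loss[ref$refined] <= rs$cv_loss[ref$refined] + 1e-9))
  # unrefined voxels keep their stage-one penalties
  keep <- setdiff(seq_len(5), ref$refined)
  expect_identical(ref$penalties[keep, ], rs$penalties[keep, ])
})
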