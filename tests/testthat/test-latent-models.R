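# NIPALS PCA/PLS2, the ptPLS2 post-transformation contract, and VIP.

test_that("a rank-1 matrix is explained entirely by the first component", {
  u <- rnorm(8)
  v <- rnorm(5)
  x <- tcrossprod(u - mean(u), v)
  fit <- suppressWarnings(fit_pca(x, 2))
  expect_equal(fit$explained_variance[1], 1, tolerance = 1e-10)
})

test_that("NIPALS PCA matches the SVD oracle up to column signs", {
  for (seed in 1:10) {
    x <- rand_scaled(8, 5, seed)
    fit <- fit_pca(x, 3)
    sv <- svd(x)
    t_oracle <- sv$u[, 1:3] %*% diag(sv$d[1:3])
    p_oracle <- sv$v[, 1:3]
    expect_lt(max(abs(sign_align(fit$t, t_oracle) - t_oracle)), 1e-6)
    expect_lt(max(abs(sign_align(fit$p, p_oracle) - p_oracle)), 1e-6)
    expect_true(all(diff(fit$explained_variance) <= 1e-12))
    expect_lte(sum(fit$explained_variance), 1 + 1e-9)
    # Loadings orthonormal.
    expect_equal(crossprod(fit$p), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("PC1 separates two well-shifted clusters perfectly", {
  dat <- two_class_data(n_per = 10, p = 6, shift = 5, noise = 1, seed = 4)
  x <- suppressWarnings(scale_features(dat$x, "mean_center"))$x
  fit <- fit_pca(x, 2)
  side <- sign(fit$t[, 1])
  expect_true(all(side == side[1] * rep(c(1, -1), each = 10)) ||
    all(side == -side[1] * rep(c(1, -1), each = 10)))
})

test_that("PLS2 is exact on a rank-1 problem and matches the regression oracle", {
  # Rank-1 X with y equal to its first column: one component, R2Y = 1.
  u <- rnorm(10)
  v <- c(1, 0.5, -0.2)
  x <- tcrossprod(u - mean(u), v)
  fit <- suppressWarnings(fit_pls2(x, x[, 1], 1))
  expect_equal(tail(fit$r2y, 1), 1, tolerance = 1e-10)

  # p = q = 1: the PLS coefficient equals the least-squares slope.
  for (seed in 1:10) {
    set.seed(seed)
    xs <- scale_features(matrix(rnorm(25), 25, 1))$x
    ys <- 1.7 * xs[, 1] + rnorm(25, 0, 0.3)
    ys <- ys - mean(ys)
    fit <- fit_pls2(xs, ys, 1)
    expect_equal(fit$b[1, 1], unname(coef(lm(ys ~ xs - 1))[1]), tolerance = 1e-10)
  }
})

test_that("R2Y is non-decreasing in the component count and T = X W*", {
  for (seed in 1:5) {
    x <- rand_scaled(15, 8, seed)
    set.seed(seed + 100)
    y <- cbind(x[, 1] + rnorm(15, 0, 0.5), rnorm(15))
    y <- sweep(y, 2, colMeans(y))
    fit <- fit_pls2(x, y, 4)
    expect_true(all(diff(fit$r2y) >= -1e-12))
    expect_equal(x %*% fit$w_star, fit$t, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(x %*% fit$b, fit$t %*% t(fit$q), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("constant response columns are rejected", {
  x <- rand_scaled(10, 4, 1)
  expect_error(fit_pls2(x, rep(2, 10), 1), "constant")
})

test_that("ptPLS2 preserves predictions and kills response correlation", {
  for (seed in 1:10) {
    x <- rand_scaled(20, 10, seed)
    set.seed(seed + 50)
    y <- cbind(x[, 1] + rnorm(20, 0, 0.3), rnorm(20))
    y <- sweep(y, 2, colMeans(y))
    fit <- fit_pls2(x, y, 3)
    pt <- post_transform(fit)
    y_parent <- x %*% fit$b
    y_pt <- predict(pt, x)
    expect_lt(max(abs(y_parent - y_pt)), 1e-8)
    if (pt$n_orthogonal > 0) {
      expect_lt(max(abs(cor(pt$to, y_parent))), 1e-8)
    }
    expect_equal(pt$n_predictive + pt$n_orthogonal, fit$n_comp)
    # The rotation is orthogonal.
    expect_equal(crossprod(pt$rotation), diag(fit$n_comp),
      tolerance = 1e-10, ignore_attr = TRUE
    )
  }
})

test_that("a single-column response yields one predictive component", {
  dat <- two_class_data(n_per = 8, p = 10, shift = 3, seed = 2)
  x <- suppressWarnings(scale_features(dat$x, "pareto"))$x
  fit <- fit_pls2(x, dat$y - mean(dat$y), 3)
  pt <- post_transform(fit)
  expect_equal(pt$n_predictive, 1L)
  expect_equal(glance(pt)$structure, "A = 1 + 2")
})

test_that("with a full-rank response there is no orthogonal part", {
  x <- rand_scaled(20, 6, 9)
  set.seed(9)
  y <- cbind(x[, 1] + rnorm(20, 0, 0.2), x[, 2] + rnorm(20, 0, 0.2))
  y <- sweep(y, 2, colMeans(y))
  fit <- fit_pls2(x, y, 2)
  pt <- post_transform(fit)
  expect_equal(pt$n_predictive, 2L)
  expect_equal(ncol(pt$to), 0)
  # Tp spans the same space as T: projecting T onto Tp loses nothing.
  proj <- pt$tp %*% solve(crossprod(pt$tp), crossprod(pt$tp, fit$t))
  expect_equal(proj, fit$t, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("n_predictive can be forced by the analyst", {
  x <- rand_scaled(20, 8, 12)
  set.seed(12)
  y <- cbind(x[, 1] + rnorm(20, 0, 0.2), x[, 2] + rnorm(20, 0, 0.2))
  y <- sweep(y, 2, colMeans(y))
  fit <- fit_pls2(x, y, 3)
  pt <- post_transform(fit, n_predictive = 1)
  expect_equal(pt$n_predictive, 1L)
  expect_lt(max(abs(x %*% fit$b - predict(pt, x))), 1e-8)
})

test_that("VIP satisfies the mean-square identity and flags information", {
  # Identical columns: all VIP exactly 1.
  set.seed(5)
  col <- rnorm(12)
  x <- matrix(rep(col - mean(col), 4), 12, 4)
  fit <- suppressWarnings(fit_pls2(x, col - mean(col), 1))
  v <- vip(fit)
  expect_true(all(abs(v$vip - 1) < 1e-9))

  # Identity holds on arbitrary fits.
  for (seed in 1:8) {
    x <- rand_scaled(15, 7, seed)
    set.seed(seed)
    y <- x[, 2] + rnorm(15, 0, 0.6)
    fit <- fit_pls2(x, y - mean(y), 2)
    expect_equal(mean(vip(fit)$vip^2), 1, tolerance = 1e-9)
  }

  # One strongly informative variable among noise ranks top with VIP > 1.
  hits <- 0
  for (seed in 1:20) {
    dat <- two_class_data(n_per = 10, p = 21, shift = 10, n_inform = 1, noise = 1, seed = seed)
    x <- suppressWarnings(scale_features(dat$x, "pareto"))$x
    fit <- fit_pls2(x, dat$y - mean(dat$y), 2)
    v <- vip(fit)$vip
    if (which.max(v) == 1 && v[1] > 1) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("design_matrix encodes class contrasts and centred time", {
  md <- data.frame(
    group = c("ACA", "ACA", "VFCA", "VFCA"),
    minute = c(1, 2, 1, 2)
  )
  y <- design_matrix(md, "group", "minute")
  expect_equal(unname(y[, 1]), c(1, 1, -1, -1))
  expect_equal(mean(y[, 2]), 0)
  expect_equal(attr(y, "positive_level"), "ACA")
  expect_error(design_matrix(data.frame(group = "A"), "group"), "2 levels")
})

test_that("NIPALS PLS predictions agree with an independent implementation", {
  # mixOmics as the external oracle on a univariate response (the two
  # NIPALS variants coincide for q = 1).
  dat <- two_class_data(n_per = 10, p = 8, shift = 2, seed = 21)
  x <- scale_features(dat$x, "mean_center")$x
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  y <- dat$y - mean(dat$y)
  ours <- fit_pls2(x, y, 2)
  theirs <- mixOmics::pls(x, y, ncomp = 2, mode = "regression", scale = FALSE)
  pred_theirs <- predict(theirs, x)$predict[, 1, 2]
  expect_equal(unname(x %*% ours$b)[, 1], unname(pred_theirs), tolerance = 1e-6)
})
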