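# Cross-validated Q2, permutation inference, VIP selection and stability
# selection.

test_that("noiseless linear signal gives Q2 near 1", {
  set.seed(1)
  x <- matrix(rnorm(70 * 6), 70, 6)
  y <- x %*% c(1, -2, 0.5, 0, 0, 0)
  cv <- cross_validate_q2(x, y, 3, n_folds = 7)
  expect_gte(tail(cv$q2, 1), 0.99)
})

test_that("independent noise responses give non-positive Q2 almost always", {
  neg <- 0
  for (seed in 1:50) {
    set.seed(seed)
    x <- matrix(rnorm(80 * 8), 80, 8)
    y <- rnorm(80)
    q2 <- tail(cross_validate_q2(x, y, 2, n_folds = 7)$q2, 1)
    if (q2 <= 0) neg <- neg + 1
  }
  expect_gte(neg, 45) # >= 90%
})

test_that("Q2 never exceeds R2", {
  for (seed in 1:30) {
    set.seed(seed)
    x <- matrix(rnorm(28 * 6), 28, 6)
    beta <- if (seed %% 2) c(2, rep(0, 5)) else rep(0, 6)
    y <- x %*% beta + rnorm(28)
    q2 <- tail(cross_validate_q2(x, y, 2, n_folds = 7)$q2, 1)
    r2 <- tail(fit_pls2(
      scale_features(x, "pareto")$x, y - mean(y), 2
    )$r2y, 1)
    expect_lte(q2, r2 + 1e-9)
  }
})

test_that("fold schemes are deterministic and respect animal grouping", {
  cv <- cross_validate_q2(matrix(rnorm(140), 28, 5), rnorm(28), 1, n_folds = 7)
  expect_equal(attr(cv, "folds"), rep(1:7, 4))
  animals <- rep(sprintf("A%02d", 1:14), each = 2)
  cvg <- cross_validate_q2(matrix(rnorm(140), 28, 5), rnorm(28), 1,
    n_folds = 7, scheme = "grouped", group_ids = animals
  )
  folds <- attr(cvg, "folds")
  expect_true(all(tapply(folds, animals, function(f) length(unique(f))) == 1))
  expect_error(
    cross_validate_q2(matrix(rnorm(140), 28, 5), rnorm(28), 1,
      n_folds = 7, scheme = "grouped"
    ),
    "group_ids"
  )
  expect_error(make_folds <- cross_validate_q2(matrix(rnorm(30), 6, 5), rnorm(6), 1, n_folds = 5), "fewer than 2")
})

test_that("component selection follows the Q2 increment rule", {
  # One latent direction in X and Y: A = 1 almost always at SNR 5.
  ones <- 0
  for (seed in 1:40) {
    set.seed(seed)
    n <- 40
    p <- 10
    t1 <- rnorm(n)
    load <- runif(p, -1, 1)
    x <- tcrossprod(t1, load) + matrix(rnorm(n * p, 0, 0.2), n, p)
    y <- t1 + rnorm(n, 0, 0.2)
    if (select_components(x, y, 3, n_folds = 5) == 1L) ones <- ones + 1
  }
  expect_gte(ones, 36) # >= 90%

  # Pure noise: floors at 1 with the no-signal flag raised.
  set.seed(99)
  x <- matrix(rnorm(30 * 6), 30, 6)
  a <- select_components(x, rnorm(30), 3, n_folds = 5)
  expect_equal(as.integer(a), 1L)
  expect_true(attr(a, "no_signal"))

  # Two orthogonal latent directions driving a two-column response: A = 2.
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    p <- 10
    t1 <- rnorm(n)
    t2 <- rnorm(n)
    l1 <- runif(p, -1, 1)
    l2 <- runif(p, -1, 1)
    l2 <- l2 - sum(l2 * l1) / sum(l1^2) * l1
    x <- tcrossprod(t1, l1) + tcrossprod(t2, l2) + matrix(rnorm(n * p, 0, 0.2), n, p)
    y <- cbind(t1 + rnorm(n, 0, 0.2), t2 + rnorm(n, 0, 0.2))
    if (select_components(x, y, 4, n_folds = 5) == 2L) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("permutation p-values obey the add-one formula and determinism", {
  dat <- two_class_data(n_per = 12, p = 6, shift = 6, seed = 3)
  pt <- permutation_test(dat$x, dat$y, 2,
    n_perm = 99, seed = 5,
    statistics = "R2", n_folds = 7
  )
  # Strong separation: the observed statistic beats every permutation.
  expect_equal(pt$p_r2, 1 / 100)
  pt2 <- permutation_test(dat$x, dat$y, 2, n_perm = 99, seed = 5, statistics = "R2")
  expect_identical(pt$null_r2, pt2$null_r2)
  expect_gte(pt$p_r2, 1 / (pt$n_perm + 1))
  expect_lte(pt$p_r2, 1)
})

test_that("animal-level permutation needs balanced blocks", {
  x <- matrix(rnorm(60), 12, 5)
  y <- rep(c(1, -1), each = 6)
  animals <- rep(sprintf("A%d", 1:4), each = 3)
  pt <- permutation_test(x, y, 1,
    n_perm = 19, seed = 1, statistics = "R2",
    group_ids = animals
  )
  expect_true(is.finite(pt$p_r2))
  unbalanced <- c(rep("A1", 4), rep("A2", 2), rep("A3", 3), rep("A4", 3))
  expect_error(
    permutation_test(x, y, 1,
      n_perm = 5, seed = 1, statistics = "R2",
      group_ids = unbalanced
    ),
    "same number of samples"
  )
})

test_that("vip_select never falls below the full model and recovers signal", {
  # Argmax property on a generic dataset.
  dat <- two_class_data(n_per = 10, p = 12, shift = 2, n_inform = 3, seed = 8)
  sel <- vip_select(dat$x, dat$y, 2, n_folds = 5)
  expect_gte(sel$q2, sel$full_q2 - 1e-9)
  expect_gte(sel$q2, max(sel$trace$q2) - 1e-9)

  # Recovery: informative variables survive selection.
  recovered <- 0
  for (seed in 1:20) {
    dat <- two_class_data(n_per = 10, p = 55, shift = 4, n_inform = 5, noise = 1, seed = seed)
    sel <- vip_select(dat$x, dat$y, 2, n_folds = 5)
    if (all(1:5 %in% sel$selected)) recovered <- recovered + 1
  }
  expect_gte(recovered, 18) # >= 90%
})

test_that("exchangeable variables are not pruned", {
  # Perfectly exchangeable columns have VIP exactly 1: no threshold below
  # 1 removes anything, and Q2 cannot improve.
  set.seed(4)
  base <- rnorm(20)
  x <- matrix(rep(base, 6), 20, 6)
  y <- base + rnorm(20, 0, 0.1)
  sel <- vip_select(x, y, 1, n_folds = 5)
  expect_equal(sort(sel$selected), 1:6)
  expect_equal(sel$q2, sel$full_q2)
})

test_that("stability selection is deterministic and ranks signal above noise", {
  dat <- two_class_data(n_per = 12, p = 11, shift = 10, n_inform = 1, seed = 6)
  s1 <- stability_selection(dat$x, dat$y, 2, n_subsets = 50, seed = 9)
  s2 <- stability_selection(dat$x, dat$y, 2, n_subsets = 50, seed = 9)
  expect_identical(s1$frequencies, s2$frequencies)
  freq <- s1$frequencies$frequency
  expect_equal(freq[1], 1.0) # dominant informative variable always selected
  expect_lt(mean(freq[-1]), 0.5)
  expect_true(1 %in% s1$stable_set)
  expect_true(all(freq >= 0 & freq <= 1))
  expect_error(
    stability_selection(dat$x, dat$y, 2, n_subsets = 1),
    ">= 2"
  )
  expect_error(
    stability_selection(dat$x, dat$y, 2, inclusion_probability = 1),
    "0, 1"
  )
})

test_that("the validation report assembles R2, Q2 and p-values coherently", {
  dat <- two_class_data(n_per = 10, p = 6, shift = 4, seed = 11)
  val <- validate_pls(dat$x, dat$y, 2, n_folds = 5, n_perm = 49, seed = 2)
  expect_lte(val$q2, val$r2 + 1e-9)
  expect_gte(val$permutation_p_r2, 1 / 50)
  expect_lte(val$permutation_p_q2, 1)
  g <- glance(val)
  expect_named(g, c(
    "r2", "q2", "n_comp", "fold_scheme", "n_folds",
    "permutation_p_r2", "permutation_p_q2", "n_permutations", "seed"
  ))
})
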