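# Resampling-based evidence layer: cross-validated Q2, permutation p-values,
# Q2-maximising VIP selection and Monte-Carlo stability selection.

# Fold assignment. Interleaved ("venetian blind") is deterministic by sample
# order; grouped keeps all samples of one animal in the same fold.
make_folds <- function(n, n_folds, scheme = c("interleaved", "grouped"),
                       group_ids = NULL) {
  scheme <- match.arg(scheme)
  if (n_folds < 2) abort("`n_folds` must be >= 2.")
  if (scheme == "interleaved") {
    folds <- ((seq_len(n) - 1L) %% n_folds) + 1L
  } else {
    if (is.null(group_ids)) abort("grouped scheme needs `group_ids`.")
    if (length(group_ids) != n) abort("`group_ids` length must match rows.")
    uid <- unique(group_ids)
    if (length(uid) < n_folds) {
      abort("grouped scheme needs at least as many groups as folds.")
    }
    gf <- setNames(((seq_along(uid) - 1L) %% n_folds) + 1L, uid)
    folds <- unname(gf[as.character(group_ids)])
  }
  sizes <- tabulate(folds, n_folds)
  if (any(sizes < 2)) {
    abort(sprintf("fold(s) with fewer than 2 samples: %s", paste(which(sizes < 2), collapse = ", ")))
  }
  folds
}

# Fit a PLS model on column-scaled x and centred y; scaling estimated here.
fit_scaled_pls <- function(x, y, n_comp, x_scale = "pareto") {
  sx <- suppressWarnings(scale_features(x, x_scale))
  y <- as_y_matrix(y)
  y_center <- colMeans(y)
  yc <- sweep(y, 2, y_center, "-")
  fit <- suppressWarnings(fit_pls2(sx$x, yc, n_comp))
  list(fit = fit, scaling = sx, y_center = y_center)
}

#' Cross-validated Q2 of a PLS model
#'
#' Estimates predictive ability by k-fold full cross-validation:
#' `Q2(A) = 1 - PRESS(A) / SS_tot`, with the column scaling of X and the
#' centring of Y re-estimated on each training fold (no information from
#' held-out samples leaks into the preprocessing), and PRESS accumulated
#' for every cumulative component count up to `n_comp`.
#'
#' @param x Unscaled feature matrix (samples x variables).
#' @param y Response matrix or vector.
#' @param n_comp Maximum number of latent components.
#' @param n_folds Number of folds (default 7).
#' @param scheme `"interleaved"` assigns sample i to fold `i mod k`
#'   (deterministic, the default); `"grouped"` keeps each animal's samples
#'   in a single fold and needs `group_ids`.
#' @param group_ids Animal identifiers for the grouped scheme.
#' @param x_scale Scaling re-estimated per training fold
#'   (default `"pareto"`).
#' @return A tibble with `n_comp`, `press` and `q2` per cumulative
#'   component count; attributes carry the fold assignment and `ss_tot`.
#' @export
cross_validate_q2 <- function(x, y, n_comp, n_folds = 7,
                              scheme = c("interleaved", "grouped"),
                              group_ids = NULL, x_scale = "pareto") {
  x <- as_x_matrix(x)
  y <- as_y_matrix(y)
  scheme <- match.arg(scheme)
  n <- nrow(x)
  folds <- make_folds(n, n_folds, scheme, group_ids)
  press <- numeric(n_comp)
  ss_tot <- 0
  for (k in sort(unique(folds))) {
    test <- folds == k
    train <- !test
    fs <- fit_scaled_pls(x[train, , drop = FALSE], y[train, , drop = FALSE],
      n_comp,
      x_scale = x_scale
    )
    xt <- apply_scaling(x[test, , drop = FALSE], fs$scaling)
    y_test <- y[test, , drop = FALSE]
    ss_tot <- ss_tot + sum(sweep(y_test, 2, fs$y_center, "-")^2)
    for (a in seq_len(n_comp)) {
      a_use <- min(a, fs$fit$n_comp)
      pred <- sweep(predict(fs$fit, xt, n_comp = a_use), 2, fs$y_center, "+")
      press[a] <- press[a] + sum((y_test - pred)^2)
    }
  }
  out <- tibble(n_comp = seq_len(n_comp), press = press, q2 = 1 - press / ss_tot)
  attr(out, "ss_tot") <- ss_tot
  attr(out, "folds") <- folds
  attr(out, "scheme") <- scheme
  out
}

#' Choose the number of latent components by cross-validation
#'
#' Starts at one component and adds another only while the cross-validated
#' Q2 improves by more than `delta` (default 0.01) — a parsimonious,
#' deterministic increment rule. When even the one-component model has
#' `Q2 <= 0` the return value is flagged with attribute `no_signal`.
#'
#' @inheritParams cross_validate_q2
#' @param max_comp Largest component count considered.
#' @param delta Minimum Q2 improvement to accept a further component.
#' @return An integer, with attributes `q2_trace` (the Q2 per component)
#'   and `no_signal`.
#' @export
select_components <- function(x, y, max_comp, n_folds = 7, delta = 0.01,
                              scheme = "interleaved", group_ids = NULL,
                              x_scale = "pareto") {
  if (max_comp < 1) abort("`max_comp` must be >= 1.")
  cv <- cross_validate_q2(x, y, max_comp,
    n_folds = n_folds, scheme = scheme,
    group_ids = group_ids, x_scale = x_scale
  )
  q2 <- cv$q2
  a <- 1L
  while (a < length(q2) && q2[a + 1] > q2[a] + delta) a <- a + 1L
  out <- a
  attr(out, "q2_trace") <- q2
  attr(out, "no_signal") <- q2[a] <= 0
  out
}

# Row order for one permutation, optionally exchanging whole animals.
permute_rows <- function(n, group_ids = NULL) {
  if (is.null(group_ids)) {
    return(sample(n))
  }
  rows <- split(seq_len(n), factor(group_ids, levels = unique(group_ids)))
  sizes <- lengths(rows)
  if (length(unique(sizes)) != 1) {
    abort(paste(
      "animal-level permutation needs the same number of samples per animal;",
      "use sample-level permutation for unbalanced designs."
    ))
  }
  unlist(rows[sample(length(rows))], use.names = FALSE)
}

#' Permutation test of a PLS model
#'
#' Permutes the rows of the response block jointly (keeping the X
#' covariance structure intact), refits the model per permutation and
#' compares the observed R2 — and, when requested, the cross-validated
#' Q2 — with the null distribution. P-values use the add-one formula
#' `p = (1 + #[null >= observed]) / (1 + n_permutations)`, so the smallest
#' attainable p with 1000 permutations is 1/1001. When `group_ids` is
#' supplied, whole animals are exchanged instead of single samples
#' (repeated measures stay together).
#'
#' @inheritParams cross_validate_q2
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the permutation stream.
#' @param statistics Which statistics to test: `"R2"`, `"Q2"` or both
#'   (default both; Q2 implies a full cross-validation per permutation).
#' @return An object of class `permutation_test`: observed statistics,
#'   p-values, null distributions, `n_perm` and `seed`.
#' @export
permutation_test <- function(x, y, n_comp, n_perm = 1000, seed = 1,
                             statistics = c("R2", "Q2"), n_folds = 7,
                             scheme = "interleaved", group_ids = NULL,
                             x_scale = "pareto") {
  x <- as_x_matrix(x)
  y <- as_y_matrix(y)
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  want_q2 <- "Q2" %in% statistics
  want_r2 <- "R2" %in% statistics
  obs_r2 <- tail(fit_scaled_pls(x, y, n_comp, x_scale)$fit$r2y, 1)
  obs_q2 <- if (want_q2) {
    tail(cross_validate_q2(x, y, n_comp,
      n_folds = n_folds, scheme = scheme,
      group_ids = group_ids, x_scale = x_scale
    )$q2, 1)
  } else {
    NA_real_
  }
  null_r2 <- rep(NA_real_, n_perm)
  null_q2 <- rep(NA_real_, n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    idx <- permute_rows(nrow(y), group_ids)
    yp <- y[idx, , drop = FALSE]
    if (want_r2) {
      null_r2[b] <- tail(fit_scaled_pls(x, yp, n_comp, x_scale)$fit$r2y, 1)
    }
    if (want_q2) {
      null_q2[b] <- tail(cross_validate_q2(x, yp, n_comp,
        n_folds = n_folds,
        scheme = scheme, group_ids = group_ids, x_scale = x_scale
      )$q2, 1)
    }
  }
  p_r2 <- if (want_r2) (1 + sum(null_r2 >= obs_r2)) / (1 + n_perm) else NA_real_
  p_q2 <- if (want_q2) (1 + sum(null_q2 >= obs_q2)) / (1 + n_perm) else NA_real_
  structure(
    list(
      observed_r2 = obs_r2, observed_q2 = obs_q2,
      p_r2 = p_r2, p_q2 = p_q2,
      null_r2 = null_r2, null_q2 = null_q2,
      n_perm = as.integer(n_perm), seed = as.integer(seed),
      statistics = statistics
    ),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "<permutation_test> %d permutations; R2 = %.3f (p = %.4g), Q2 = %.3f (p = %.4g)\n",
    x$n_perm, x$observed_r2, x$p_r2, x$observed_q2, x$p_q2
  ))
  invisible(x)
}

#' @export
tidy.permutation_test <- function(x, ...) {
  bind_rows(
    tibble(statistic = "R2", value = x$null_r2),
    tibble(statistic = "Q2", value = x$null_q2)
  ) |> filter(!is.na(.data$value))
}

#' @export
glance.permutation_test <- function(x, ...) {
  tibble(
    observed_r2 = x$observed_r2, p_r2 = x$p_r2,
    observed_q2 = x$observed_q2, p_q2 = x$p_q2,
    n_perm = x$n_perm, seed = x$seed
  )
}

#' Validate a PLS model: R2, Q2 and permutation p-values
#'
#' Convenience wrapper assembling the full validation report for a fitted
#' latent model: training R2, k-fold cross-validated Q2, and permutation
#' p-values for both.
#'
#' @inheritParams permutation_test
#' @return An object of class `pls_validation` (see [glance()]).
#' @export
validate_pls <- function(x, y, n_comp, n_folds = 7, n_perm = 1000, seed = 1,
                         scheme = "interleaved", group_ids = NULL,
                         x_scale = "pareto") {
  cv <- cross_validate_q2(x, y, n_comp,
    n_folds = n_folds, scheme = scheme,
    group_ids = group_ids, x_scale = x_scale
  )
  pt <- permutation_test(x, y, n_comp,
    n_perm = n_perm, seed = seed,
    statistics = c("R2", "Q2"), n_folds = n_folds,
    scheme = scheme, group_ids = group_ids, x_scale = x_scale
  )
  structure(
    list(
      r2 = pt$observed_r2, q2 = tail(cv$q2, 1), n_comp = as.integer(n_comp),
      fold_scheme = attr(cv, "scheme"), n_folds = as.integer(n_folds),
      permutation_p_r2 = pt$p_r2, permutation_p_q2 = pt$p_q2,
      n_permutations = pt$n_perm, seed = as.integer(seed),
      q2_trace = cv$q2, permutation = pt
    ),
    class = "pls_validation"
  )
}

#' @export
print.pls_validation <- function(x, ...) {
  cat(sprintf(
    "<pls_validation> A = %d: R2 = %.3f (p = %.4g), Q2 = %.3f (p = %.4g), %d-fold %s CV, %d permutations\n",
    x$n_comp, x$r2, x$permutation_p_r2, x$q2, x$permutation_p_q2,
    x$n_folds, x$fold_scheme, x$n_permutations
  ))
  invisible(x)
}

#' @export
glance.pls_validation <- function(x, ...) {
  tibble(
    r2 = x$r2, q2 = x$q2, n_comp = x$n_comp,
    fold_scheme = x$fold_scheme, n_folds = x$n_folds,
    permutation_p_r2 = x$permutation_p_r2,
    permutation_p_q2 = x$permutation_p_q2,
    n_permutations = x$n_permutations, seed = x$seed
  )
}

#' VIP-driven variable selection maximising Q2
#'
#' Iterative backward elimination: compute VIP on the current variable set,
#' form one candidate subset per threshold in `thresholds` (variables with
#' VIP below the threshold dropped), re-fit and re-cross-validate each, and
#' move to the best candidate while the cross-validated Q2 improves. The
#' returned subset is the best over the whole trace, so its Q2 is never
#' below the full model's.
#'
#' @inheritParams cross_validate_q2
#' @param thresholds VIP threshold grid swept at every step.
#' @param max_steps Safety bound on elimination rounds.
#' @return A list of class `vip_selection`: integer `selected` (column
#'   indices), `variables` (names), `q2`, `full_q2` and the search `trace`
#'   tibble.
#' @export
vip_select <- function(x, y, n_comp, n_folds = 7,
                       thresholds = c(0.8, 0.9, 1.0, 1.1, 1.2),
                       scheme = "interleaved", group_ids = NULL,
                       x_scale = "pareto", max_steps = 20) {
  x <- as_x_matrix(x)
  y <- as_y_matrix(y)
  if (ncol(x) < 2) abort("variable selection needs at least 2 variables.")
  vars <- colnames(x) %||% as.character(seq_len(ncol(x)))
  cv_q2 <- function(cols) {
    a <- min(n_comp, length(cols))
    tail(cross_validate_q2(x[, cols, drop = FALSE], y, a,
      n_folds = n_folds,
      scheme = scheme, group_ids = group_ids, x_scale = x_scale
    )$q2, 1)
  }
  current <- seq_len(ncol(x))
  q2_current <- cv_q2(current)
  trace <- list(tibble(
    step = 0L, threshold = NA_real_, n_vars = length(current),
    q2 = q2_current, vars = list(current)
  ))
  best <- list(cols = current, q2 = q2_current)
  for (step in seq_len(max_steps)) {
    a_eff <- min(n_comp, length(current))
    fit <- fit_scaled_pls(x[, current, drop = FALSE], y, a_eff, x_scale)$fit
    v <- vip(fit)$vip
    cands <- list()
    for (thr in thresholds) {
      keep <- current[v >= thr]
      if (length(keep) >= 2 && length(keep) < length(current)) {
        cands[[length(cands) + 1]] <- list(thr = thr, cols = keep)
      }
    }
    if (length(cands) == 0) {
      if (step == 1L && all(v < min(thresholds))) {
        warn("every threshold would eliminate all variables; keeping the best subset seen.")
      }
      break
    }
    q2s <- vapply(cands, function(cd) cv_q2(cd$cols), numeric(1))
    for (i in seq_along(cands)) {
      trace[[length(trace) + 1]] <- tibble(
        step = step, threshold = cands[[i]]$thr,
        n_vars = length(cands[[i]]$cols), q2 = q2s[i], vars = list(cands[[i]]$cols)
      )
    }
    i_best <- which.max(q2s)
    if (q2s[i_best] > best$q2) {
      best <- list(cols = cands[[i_best]]$cols, q2 = q2s[i_best])
    }
    if (q2s[i_best] > q2_current) {
      current <- cands[[i_best]]$cols
      q2_current <- q2s[i_best]
    } else {
      break
    }
  }
  structure(
    list(
      selected = best$cols, variables = vars[best$cols],
      q2 = best$q2, full_q2 = trace[[1]]$q2,
      trace = bind_rows(trace)
    ),
    class = "vip_selection"
  )
}

#' @export
print.vip_selection <- function(x, ...) {
  cat(sprintf(
    "<vip_selection> %d variable(s) selected, Q2 = %.3f (full model %.3f)\n",
    length(x$selected), x$q2, x$full_q2
  ))
  invisible(x)
}

#' Monte-Carlo stability selection of discriminant variables
#'
#' Draws `n_subsets` random sample subsets (each sample included
#' independently with probability `inclusion_probability`), fits a PLS
#' model with VIP on each, and scores every variable by the fraction of
#' subsets in which its VIP exceeds `vip_threshold`. Variables whose
#' selection frequency reaches `stability_threshold` form the stable set.
#' Subsets too small for the model (or with a constant response) are
#' redrawn, at most 10 times each.
#'
#' @inheritParams cross_validate_q2
#' @param n_subsets Number of Monte-Carlo subsets (default 50).
#' @param inclusion_probability Per-sample inclusion probability
#'   (default 0.7).
#' @param vip_threshold VIP cut-off counting a variable as selected in one
#'   subset (default 1.0).
#' @param stability_threshold Selection frequency defining the stable set
#'   (default 0.8).
#' @param seed Integer seed.
#' @return A list of class `stability_selection`: a `frequencies` tibble
#'   (`variable`, `frequency`, `stable`), the `stable_set` indices, and the
#'   sampling parameters.
#' @export
stability_selection <- function(x, y, n_comp, n_subsets = 50,
                                inclusion_probability = 0.7,
                                vip_threshold = 1.0, seed = 1,
                                stability_threshold = 0.8,
                                x_scale = "pareto") {
  x <- as_x_matrix(x)
  y <- as_y_matrix(y)
  if (n_subsets < 2) abort("`n_subsets` must be >= 2.")
  if (inclusion_probability <= 0 || inclusion_probability >= 1) {
    abort("`inclusion_probability` must lie in (0, 1).")
  }
  n <- nrow(x)
  counts <- numeric(ncol(x))
  redraws <- 0L
  set.seed(seed)
  for (b in seq_len(n_subsets)) {
    attempt <- 0L
    repeat {
      incl <- runif(n) < inclusion_probability
      ok <- sum(incl) >= n_comp + 2 &&
        all(apply(as_y_matrix(y)[incl, , drop = FALSE], 2, sd) > 0)
      if (ok) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (attempt > 10L) {
        abort("subset redraw limit reached; increase the inclusion probability or sample size.")
      }
    }
    fit <- fit_scaled_pls(x[incl, , drop = FALSE], y[incl, , drop = FALSE],
      min(n_comp, sum(incl) - 1),
      x_scale = x_scale
    )$fit
    counts <- counts + (vip(fit)$vip > vip_threshold)
  }
  freq <- counts / n_subsets
  vars <- colnames(x) %||% as.character(seq_len(ncol(x)))
  structure(
    list(
      frequencies = tibble(
        variable = vars, frequency = freq,
        stable = freq >= stability_threshold
      ),
      stable_set = which(freq >= stability_threshold),
      n_subsets = as.integer(n_subsets),
      inclusion_probability = inclusion_probability,
      vip_threshold = vip_threshold,
      stability_threshold = stability_threshold,
      seed = as.integer(seed), n_redraws = redraws
    ),
    class = "stability_selection"
  )
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf(
    "<stability_selection> %d subsets at p = %.2f: %d stable variable(s) (frequency >= %.2f)\n",
    x$n_subsets, x$inclusion_probability, length(x$stable_set), x$stability_threshold
  ))
  invisible(x)
}

#' @export
tidy.stability_selection <- function(x, ...) {
  x$frequencies
}
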