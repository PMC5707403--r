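#' Build a discriminant design matrix
#'
#' Encodes the response block for PLS2 discriminant analysis: one +/-1
#' contrast column per two-level class factor (the first level in sort
#' order is +1) and, optionally, a centred continuous time column — the
#' "class and time" design used to drive discriminant latent-variable
#' models on longitudinal cohorts.
#'
#' @param data Data frame of sample metadata, one row per sample.
#' @param class Column name (string) of the two-level class label.
#' @param time Optional column name of a continuous time covariate to
#'   append, centred.
#' @return A numeric matrix with named columns, rows aligned with `data`.
#' @export
design_matrix <- function(data, class, time = NULL) {
  stopifnot(is.data.frame(data))
  cls <- as.character(data[[class]])
  levels <- sort(unique(cls))
  if (length(levels) != 2) {
    abort(sprintf("`%s` must have exactly 2 levels, found %d.", class, length(levels)))
  }
  y <- matrix(ifelse(cls == levels[1], 1, -1), ncol = 1)
  colnames(y) <- sprintf("%s_%s_vs_%s", class, levels[1], levels[2])
  if (!is.null(time)) {
    tm <- as.numeric(data[[time]])
    y <- cbind(y, matrix(tm - mean(tm), ncol = 1))
    colnames(y)[2] <- paste0(time, "_centered")
  }
  attr(y, "positive_level") <- levels[1]
  y
}

#' Two-block PLS regression by NIPALS
#'
#' Fits a PLS2 model of a (centred/scaled) feature matrix on a multi-column
#' response by the NIPALS algorithm: X is deflated per component, Y is not
#' (the classic PLS2 variant), weights are unit-norm with the first
#' non-zero element positive. The regression matrix `b` satisfies
#' `Y_hat = X b` and reproduces the NIPALS score predictions exactly.
#'
#' @param x Numeric matrix, samples x variables, centred (and scaled).
#' @param y Response matrix or vector; constant columns are an error.
#' @param n_comp Number of latent components (>= 1). If the X block runs
#'   out of rank, fewer components are returned with a warning.
#' @param tol Relative convergence tolerance on the score vector.
#' @param max_iter Maximum NIPALS iterations per component. A component
#'   still loosely unconverged (relative change above 1e-4) at the cap is
#'   an error naming it; between the cap tolerance and `tol` the solution
#'   is accepted with a warning (nearly degenerate residual directions
#'   converge geometrically slowly and are prediction-equivalent).
#' @return An object of class `pls_model` with weights `w`, rotated weights
#'   `w_star` (so that `t = x %*% w_star`), X-loadings `p`, Y-loadings `q`,
#'   scores `t`, coefficients `b`, per-component explained Y-variance
#'   `ssy`, cumulative `r2y`, and the training `x`/`y` dimensions.
#' @examples
#' x <- scale_features(matrix(rnorm(60), 12, 5))$x
#' y <- x[, 1] + rnorm(12, 0, 0.1)
#' fit <- fit_pls2(x, y, 2)
#' fit$r2y
#' @export
fit_pls2 <- function(x, y, n_comp, tol = 1e-10, max_iter = 500L) {
  x <- as_x_matrix(x)
  y <- as_y_matrix(y)
  if (nrow(x) != nrow(y)) abort("`x` and `y` must have the same number of rows.")
  if (n_comp < 1) abort("`n_comp` must be >= 1.")
  y_sd <- apply(y, 2, sd)
  if (any(y_sd == 0)) {
    abort(sprintf(
      "constant response column(s): %s",
      paste(colnames(y)[y_sd == 0] %||% which(y_sd == 0), collapse = ", ")
    ))
  }
  n <- nrow(x)
  p <- ncol(x)
  q <- ncol(y)
  ss_x <- sum(x^2)
  e <- x
  w_mat <- matrix(0, p, n_comp)
  p_mat <- matrix(0, p, n_comp)
  q_mat <- matrix(0, q, n_comp)
  t_mat <- matrix(0, n, n_comp)
  a_done <- 0L
  for (a in seq_len(n_comp)) {
    if (sum(e^2) < ss_x * 1e-14) {
      warn(sprintf("X rank exhausted: returning %d of %d components.", a_done, n_comp))
      break
    }
    u <- y[, which.max(apply(y, 2, var))]
    t_vec <- rep(0, n)
    converged <- FALSE
    delta <- Inf
    for (it in seq_len(max_iter)) {
      w_vec <- crossprod(e, u)[, 1]
      w_norm <- sqrt(sum(w_vec^2))
      if (w_norm < 1e-300) {
        abort(sprintf("degenerate weight vector at component %d.", a))
      }
      w_vec <- w_vec / w_norm
      t_new <- (e %*% w_vec)[, 1]
      q_vec <- crossprod(y, t_new)[, 1] / sum(t_new^2)
      u <- (y %*% q_vec)[, 1] / sum(q_vec^2)
      delta <- sqrt(sum((t_new - t_vec)^2)) / sqrt(sum(t_new^2))
      t_vec <- t_new
      if (delta < tol || q == 1) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      # Nearly degenerate residual eigenvalues converge geometrically slowly;
      # accept a loosely converged solution at the cap, error otherwise.
      if (delta < 1e-4) {
        warn(sprintf(
          "component %d stopped at the iteration cap (relative change %.1e).",
          a, delta
        ))
      } else {
        abort(sprintf(
          "NIPALS did not converge within %d iterations at component %d.",
          max_iter, a
        ))
      }
    }
    nz <- which(abs(w_vec) > 1e-12)[1]
    if (!is.na(nz) && w_vec[nz] < 0) {
      w_vec <- -w_vec
      t_vec <- -t_vec
      q_vec <- -q_vec
    }
    p_vec <- crossprod(e, t_vec)[, 1] / sum(t_vec^2)
    e <- e - tcrossprod(t_vec, p_vec)
    w_mat[, a] <- w_vec
    p_mat[, a] <- p_vec
    q_mat[, a] <- q_vec
    t_mat[, a] <- t_vec
    a_done <- a
  }
  if (a_done == 0L) abort("no PLS components could be extracted.")
  keep <- seq_len(a_done)
  w_mat <- w_mat[, keep, drop = FALSE]
  p_mat <- p_mat[, keep, drop = FALSE]
  q_mat <- q_mat[, keep, drop = FALSE]
  t_mat <- t_mat[, keep, drop = FALSE]
  w_star <- w_mat %*% solve(crossprod(p_mat, w_mat))
  b <- w_star %*% t(q_mat)
  ss_tot <- sum(y^2)
  ssy <- colSums(t_mat^2) * colSums(q_mat^2)
  if (ss_tot <= 0) abort("response has zero total sum of squares.")
  r2y <- cumsum(ssy) / ss_tot
  dimnames(b) <- list(colnames(x), colnames(y))
  structure(
    list(
      n_comp = a_done, w = w_mat, w_star = w_star, p = p_mat, q = q_mat,
      t = t_mat, b = b, ssy = ssy, r2y = r2y,
      x_dim = dim(x), y_dim = dim(y), y = y,
      variable_names = colnames(x), sample_ids = rownames(x),
      response_names = colnames(y)
    ),
    class = "pls_model"
  )
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix in the same (centred/scaled) units as the training
#'   X block.
#' @param n_comp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return A numeric matrix of fitted responses.
#' @export
predict.pls_model <- function(object, newdata, n_comp = object$n_comp, ...) {
  newdata <- as_x_matrix(newdata)
  if (n_comp > object$n_comp) abort("`n_comp` exceeds the fitted components.")
  keep <- seq_len(n_comp)
  b <- object$w_star[, keep, drop = FALSE] %*% t(object$q[, keep, drop = FALSE])
  newdata %*% b
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf(
    "<pls_model> A = %d, %d x %d -> %d response(s), R2Y = %.3f\n",
    x$n_comp, x$x_dim[1], x$x_dim[2], x$y_dim[2], tail(x$r2y, 1)
  ))
  invisible(x)
}

#' @export
tidy.pls_model <- function(x, ...) {
  tibble(
    component = seq_len(x$n_comp),
    ssy = x$ssy,
    r2y_cumulative = x$r2y
  )
}

#' @export
glance.pls_model <- function(x, ...) {
  tibble(
    n_comp = x$n_comp, r2y = tail(x$r2y, 1),
    n = x$x_dim[1], p = x$x_dim[2], q = x$y_dim[2]
  )
}

#' Post-transform a PLS2 model into predictive and orthogonal parts
#'
#' Rotates the A-dimensional latent score space of a fitted PLS2 model with
#' an orthogonal matrix built from the singular value decomposition of
#' `t(T) %*% Y`: left singular vectors with non-negligible singular values
#' span the predictive subspace (`tp` scores), the remainder the
#' response-orthogonal subspace (`to` scores). Predictions are invariant
#' under the rotation, and every orthogonal score column has exactly zero
#' covariance with every fitted response column — the model's defining
#' contract. The component structure is reported in the conventional
#' "A = predictive + orthogonal" form.
#'
#' @param model A fitted [fit_pls2()] model (on centred data, so that
#'   scores have zero mean and covariance equals cross-product).
#' @param rank_tol Relative singular-value threshold for the predictive
#'   rank (default 1e-8 of the largest).
#' @param n_predictive Optionally force the number of predictive
#'   components (e.g. when a response column is retained in the design but
#'   judged non-significant).
#' @return An object of class `ptpls2_model` with the `parent` model, the
#'   orthogonal `rotation` matrix G, predictive scores `tp`, orthogonal
#'   scores `to`, and `n_predictive`/`n_orthogonal`.
#' @export
post_transform <- function(model, rank_tol = 1e-8, n_predictive = NULL) {
  stopifnot(inherits(model, "pls_model"))
  a <- model$n_comp
  m <- crossprod(model$t, model$y)
  sv <- svd(m, nu = a)
  if (max(sv$d) <= 0 || all(sv$d < .Machine$double.eps * max(dim(m)))) {
    abort("degenerate response: t(T) Y has no non-zero singular values.")
  }
  rank <- sum(sv$d > rank_tol * sv$d[1])
  if (is.null(n_predictive)) {
    n_predictive <- rank
  } else {
    if (n_predictive < 1 || n_predictive > a) {
      abort("`n_predictive` must lie between 1 and the component count.")
    }
  }
  g <- sv$u # full A x A orthogonal basis (nu = a)
  tp <- model$t %*% g[, seq_len(n_predictive), drop = FALSE]
  to <- model$t %*% g[, setdiff(seq_len(a), seq_len(n_predictive)), drop = FALSE]
  colnames(tp) <- paste0("tp", seq_len(ncol(tp)))
  if (ncol(to) > 0) colnames(to) <- paste0("to", seq_len(ncol(to)))
  structure(
    list(
      parent = model, rotation = g, tp = tp, to = to,
      n_predictive = as.integer(n_predictive),
      n_orthogonal = a - as.integer(n_predictive),
      singular_values = sv$d
    ),
    class = "ptpls2_model"
  )
}

#' @export
predict.ptpls2_model <- function(object, newdata, ...) {
  # Rotation leaves predictions unchanged; reconstruct through the rotated
  # scores to make the invariance explicit.
  newdata <- as_x_matrix(newdata)
  parent <- object$parent
  t_rot <- newdata %*% parent$w_star %*% object$rotation
  t_rot %*% t(object$rotation) %*% t(parent$q)
}

#' @export
print.ptpls2_model <- function(x, ...) {
  cat(sprintf(
    "<ptpls2_model> A = %d + %d components, R2Y = %.3f\n",
    x$n_predictive, x$n_orthogonal, tail(x$parent$r2y, 1)
  ))
  invisible(x)
}

#' @export
tidy.ptpls2_model <- function(x, ...) {
  scores <- cbind(x$tp, x$to)
  bind_cols(
    tibble(sample_id = x$parent$sample_ids %||% as.character(seq_len(nrow(scores)))),
    as_tibble(scores)
  )
}

#' @export
glance.ptpls2_model <- function(x, ...) {
  tibble(
    n_predictive = x$n_predictive,
    n_orthogonal = x$n_orthogonal,
    structure = sprintf("A = %d + %d", x$n_predictive, x$n_orthogonal),
    r2y = tail(x$parent$r2y, 1)
  )
}

#' Variable influence on projection
#'
#' Computes VIP scores for a fitted PLS model:
#' `VIP_j = sqrt(p * sum_a(SSY_a * (w_ja / ||w_a||)^2) / sum_a(SSY_a))`
#' where `SSY_a` is the response variance explained by component `a` and
#' `p` the number of variables. The squared scores average to exactly 1, so
#' VIP > 1 marks above-average influence.
#'
#' @param model A `pls_model`.
#' @return A tibble with `variable` and `vip`, plus attribute `n_comp`.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (sum(model$ssy) <= 0) abort("model explains no response variance; VIP undefined.")
  p <- nrow(model$w)
  w2 <- sweep(model$w, 2, sqrt(colSums(model$w^2)), "/")^2
  v <- sqrt(p * as.numeric(w2 %*% model$ssy) / sum(model$ssy))
  out <- tibble(
    variable = model$variable_names %||% as.character(seq_len(p)),
    vip = v
  )
  attr(out, "n_comp") <- model$n_comp
  out
}
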