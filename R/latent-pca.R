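#' Principal component analysis by NIPALS
#'
#' Extracts principal components sequentially by the NIPALS algorithm with
#' deflation, the standard chemometric route (equivalent to the singular
#' value decomposition on full-rank data). The input is expected to be
#' centred (and scaled) already, e.g. via [scale_features()]. Loadings
#' follow the sign convention that the first non-zero element of each
#' loading vector is positive, so score plots are reproducible.
#'
#' @param x Numeric matrix (samples x variables), centred/scaled.
#' @param n_comp Number of components; must not exceed
#'   `min(nrow(x) - 1, ncol(x))`. If the matrix runs out of rank earlier,
#'   fewer components are returned with a warning.
#' @param tol Relative convergence tolerance on the score vector.
#' @param max_iter Maximum NIPALS iterations per component.
#' @return An object of class `pca_model`: scores `t` (samples x A),
#'   loadings `p` (variables x A), `explained_variance` fraction per
#'   component, and `n_comp`.
#' @examples
#' x <- scale_features(matrix(rnorm(40), 8, 5))$x
#' fit <- fit_pca(x, 2)
#' fit$explained_variance
#' @export
fit_pca <- function(x, n_comp, tol = 1e-10, max_iter = 500L) {
  x <- as_x_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n_comp > min(n - 1, p)) {
    abort(sprintf("`n_comp` must be <= min(rows - 1, cols) = %d.", min(n - 1, p)))
  }
  ss_total <- sum(x^2)
  if (ss_total <= 0) abort("`x` has zero total variance; nothing to decompose.")
  e <- x
  scores <- matrix(0, n, n_comp)
  loadings <- matrix(0, p, n_comp)
  expl <- numeric(n_comp)
  a_done <- 0L
  for (a in seq_len(n_comp)) {
    start <- which.max(colSums(e^2))
    t_vec <- e[, start]
    if (sum(t_vec^2) < ss_total * 1e-14) {
      warn(sprintf("rank exhausted: returning %d of %d components.", a_done, n_comp))
      break
    }
    for (it in seq_len(max_iter)) {
      p_vec <- crossprod(e, t_vec)[, 1] / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- (e %*% p_vec)[, 1]
      delta <- sqrt(sum((t_new - t_vec)^2)) / sqrt(sum(t_new^2))
      t_vec <- t_new
      if (delta < tol) break
    }
    nz <- which(abs(p_vec) > 1e-12)[1]
    if (!is.na(nz) && p_vec[nz] < 0) {
      p_vec <- -p_vec
      t_vec <- -t_vec
    }
    scores[, a] <- t_vec
    loadings[, a] <- p_vec
    expl[a] <- sum(t_vec^2) / ss_total
    e <- e - tcrossprod(t_vec, p_vec)
    a_done <- a
  }
  keep <- seq_len(a_done)
  structure(
    list(
      t = scores[, keep, drop = FALSE],
      p = loadings[, keep, drop = FALSE],
      explained_variance = expl[keep],
      n_comp = a_done,
      variable_names = colnames(x),
      sample_ids = rownames(x)
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "<pca_model> A = %d, explained variance: %s\n",
    x$n_comp, paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")
  ))
  invisible(x)
}

#' @describeIn fit_pca `tidy()` returns per-component explained variance
#'   (`matrix = "variance"`, default), scores (`"scores"`), or loadings
#'   (`"loadings"`) as a tibble.
#' @param matrix Which quantity to tidy.
#' @param ... Unused.
#' @export
tidy.pca_model <- function(x, matrix = c("variance", "scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "variance") {
    return(tibble(
      component = seq_len(x$n_comp),
      explained_variance = x$explained_variance,
      cumulative = cumsum(x$explained_variance)
    ))
  }
  if (matrix == "scores") {
    out <- as_tibble(x$t, .name_repair = ~ paste0("PC", seq_len(x$n_comp)))
    return(bind_cols(
      tibble(sample_id = x$sample_ids %||% as.character(seq_len(nrow(x$t)))), out
    ))
  }
  out <- as_tibble(x$p, .name_repair = ~ paste0("PC", seq_len(x$n_comp)))
  bind_cols(
    tibble(variable = x$variable_names %||% as.character(seq_len(nrow(x$p)))), out
  )
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble(
    n_comp = x$n_comp,
    explained_variance_total = sum(x$explained_variance),
    n = nrow(x$t),
    p = nrow(x$p)
  )
}
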