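#' Column scaling for multivariate models
#'
#' Centre and scale the columns of a feature matrix the way chemometric
#' latent-variable models expect. `mean_center` subtracts the column mean;
#' `pareto` additionally divides by the square root of the column standard
#' deviation (damping dominant peaks less aggressively than unit-variance
#' scaling); `unit_variance` divides by the standard deviation itself.
#' Standard deviations are the sample (n - 1) estimates. Columns with zero
#' standard deviation are centred only and flagged in `zero_variance`.
#'
#' @param x A numeric matrix or data frame (samples in rows), or a
#'   [bin_spectra()] result.
#' @param method One of `"mean_center"`, `"pareto"`, `"unit_variance"` or
#'   `"none"`.
#' @param ... Passed between methods.
#'
#' @return For matrices, an object of class `feature_scaling`: a list with
#'   the scaled matrix `x`, the column means `center`, the divisors `scale`,
#'   the `method`, and a logical `zero_variance` flag per column. For
#'   `spectra_matrix` input, the same object with the binned-spectra metadata
#'   carried along in `spectra`.
#'
#' @examples
#' s <- scale_features(matrix(c(0, 2, 4, 1, 1, 1), ncol = 2), "pareto")
#' s$x
#' s$zero_variance
#' @export
scale_features <- function(x, method = c("mean_center", "pareto", "unit_variance", "none"), ...) {
  UseMethod("scale_features")
}

#' @export
scale_features.default <- function(x, method = c("mean_center", "pareto", "unit_variance", "none"), ...) {
  method <- match.arg(method)
  x <- as_x_matrix(x)
  if (nrow(x) < 2 && method != "none") {
    abort("scaling needs at least 2 rows to estimate column statistics.")
  }
  p <- ncol(x)
  if (method == "none") {
    out <- list(
      x = x, center = rep(0, p), scale = rep(1, p),
      method = method, zero_variance = rep(FALSE, p)
    )
    class(out) <- "feature_scaling"
    return(out)
  }
  ctr <- colMeans(x)
  sds <- apply(x, 2, sd)
  zero <- sds <= .Machine$double.eps * 10
  div <- switch(method,
    mean_center = rep(1, p),
    pareto = sqrt(sds),
    unit_variance = sds
  )
  div[zero] <- 1
  if (any(zero) && method != "mean_center") {
    warn(sprintf(
      "%d constant column(s) centred only (zero standard deviation).",
      sum(zero)
    ))
  }
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, div, "/")
  out <- list(
    x = xs, center = ctr, scale = div,
    method = method, zero_variance = zero
  )
  class(out) <- "feature_scaling"
  out
}

#' @export
scale_features.spectra_matrix <- function(x, method = c("mean_center", "pareto", "unit_variance", "none"), ...) {
  sm <- x
  out <- scale_features(sm$x, method = method)
  sm$x <- out$x
  sm$scaling <- out$method
  out$spectra <- sm
  out
}

#' Apply or invert a stored scaling
#'
#' `apply_scaling()` projects new rows through the centring and divisors
#' estimated by [scale_features()] (the leakage-free way to scale test folds
#' in cross-validation). `invert_scaling()` maps a scaled matrix back to the
#' original units.
#'
#' @param x A numeric matrix with the same columns as the training matrix.
#' @param scaling A `feature_scaling` object.
#' @return A numeric matrix.
#' @export
apply_scaling <- function(x, scaling) {
  stopifnot(inherits(scaling, "feature_scaling"))
  x <- as_x_matrix(x)
  if (ncol(x) != length(scaling$center)) {
    abort("`x` has a different number of columns than the stored scaling.")
  }
  sweep(sweep(x, 2, scaling$center, "-"), 2, scaling$scale, "/")
}

#' @rdname apply_scaling
#' @export
invert_scaling <- function(x, scaling) {
  stopifnot(inherits(scaling, "feature_scaling"))
  x <- as_x_matrix(x)
  sweep(sweep(x, 2, scaling$scale, "*"), 2, scaling$center, "+")
}

#' @export
print.feature_scaling <- function(x, ...) {
  cat(sprintf(
    "<feature_scaling> %s, %d x %d, %d constant column(s)\n",
    x$method, nrow(x$x), ncol(x$x), sum(x$zero_variance)
  ))
  invisible(x)
}
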