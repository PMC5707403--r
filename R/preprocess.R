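#' Raw spectra container
#'
#' Bundle an intensity-versus-ppm trace per sample. The ppm axis must be
#' strictly monotone; decreasing axes (the usual NMR display order) are
#' stored increasing with intensities reordered to match.
#'
#' @param ppm Numeric vector, strictly monotone chemical-shift axis.
#' @param intensities Numeric matrix, samples x ppm points, all finite.
#' @param sample_ids Character vector of sample identifiers.
#' @return An object of class `raw_spectra`.
#' @export
raw_spectra <- function(ppm, intensities, sample_ids = rownames(intensities)) {
  ppm <- as.numeric(ppm)
  intensities <- as_x_matrix(intensities)
  if (length(ppm) != ncol(intensities)) {
    abort("`ppm` length must equal the number of intensity columns.")
  }
  d <- diff(ppm)
  if (all(d < 0)) {
    ppm <- rev(ppm)
    intensities <- intensities[, rev(seq_along(ppm)), drop = FALSE]
  } else if (any(d <= 0)) {
    abort("`ppm` must be strictly monotone.")
  }
  if (!all(is.finite(intensities))) abort("intensities must all be finite.")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(intensities)))
  rownames(intensities) <- sample_ids
  structure(
    list(ppm = ppm, intensities = intensities, sample_ids = as.character(sample_ids)),
    class = "raw_spectra"
  )
}

#' @export
print.raw_spectra <- function(x, ...) {
  cat(sprintf(
    "<raw_spectra> %d samples, %d points, %.3f-%.3f ppm\n",
    nrow(x$intensities), length(x$ppm), min(x$ppm), max(x$ppm)
  ))
  invisible(x)
}

# Cumulative trapezoidal integral of each spectrum, evaluated at arbitrary
# ppm positions by linear interpolation. Rows = samples.
cum_trapz_at <- function(ppm, intensities, at) {
  dx <- diff(ppm)
  mids <- (intensities[, -1, drop = FALSE] + intensities[, -ncol(intensities), drop = FALSE]) / 2
  seg <- sweep(mids, 2, dx, "*")
  cum <- cbind(0, t(apply(seg, 1, cumsum)))
  t(apply(cum, 1, function(f) approx(ppm, f, xout = at, rule = 2)$y))
}

#' Bin spectra into fixed-width ppm windows
#'
#' Reduces intensity-versus-ppm traces to a samples x bins matrix by
#' trapezoidal integration over half-open windows `[lo, hi)` of constant
#' width (the last bin is closed). Any bin overlapping an exclusion region
#' is dropped — including bins that merely straddle a boundary — which is
#' the conservative treatment of artefact regions such as residual water.
#'
#' @param raw A [raw_spectra()] object.
#' @param ppm_min,ppm_max Range to bin over; the axis must cover it.
#' @param width Bin width in ppm (default 0.01).
#' @param exclusions List of `c(lo, hi)` ppm intervals to exclude.
#' @return An object of class `spectra_matrix`: list with the binned matrix
#'   `x` (columns named by bin centre), a `bins` tibble (`lo`, `hi`,
#'   `center`), `excluded_regions`, `removed_regions`, and the
#'   `normalization` and `scaling` states.
#' @examples
#' rs <- raw_spectra(seq(0, 1, 0.001), matrix(1, 1, 1001))
#' bin_spectra(rs, 0, 1, width = 0.1)$x
#' @export
bin_spectra <- function(raw, ppm_min = 0.80, ppm_max = 9.00, width = 0.01,
                        exclusions = list()) {
  stopifnot(inherits(raw, "raw_spectra"))
  stopifnot_scalar_number(width, "width", positive = TRUE)
  if (!(ppm_min < ppm_max)) abort("`ppm_min` must be less than `ppm_max`.")
  tol <- 1e-9
  if (min(raw$ppm) > ppm_min + tol || max(raw$ppm) < ppm_max - tol) {
    abort(sprintf(
      "ppm axis (%.3f-%.3f) does not cover the requested range %.3f-%.3f.",
      min(raw$ppm), max(raw$ppm), ppm_min, ppm_max
    ))
  }
  exclusions <- check_intervals(exclusions, "exclusions")
  for (ex in exclusions) {
    if (ex[2] < ppm_min - tol || ex[1] > ppm_max + tol) {
      abort(sprintf("exclusion [%.3f, %.3f] lies outside the binned range.", ex[1], ex[2]))
    }
  }
  n_bins <- floor((ppm_max - ppm_min) / width + tol)
  if (n_bins < 1) abort("bin width larger than the ppm range.")
  lo <- ppm_min + width * (seq_len(n_bins) - 1)
  hi <- lo + width
  edges <- c(lo, hi[n_bins])
  integrals <- cum_trapz_at(raw$ppm, raw$intensities, edges)
  vals <- integrals[, -1, drop = FALSE] - integrals[, -(n_bins + 1), drop = FALSE]
  keep <- rep(TRUE, n_bins)
  for (ex in exclusions) {
    keep <- keep & !(lo < ex[2] - tol & hi > ex[1] + tol)
  }
  if (!any(keep)) abort("exclusions removed every bin.")
  bins <- tibble(
    lo = lo[keep], hi = hi[keep], center = (lo[keep] + hi[keep]) / 2
  )
  x <- vals[, keep, drop = FALSE]
  dimnames(x) <- list(raw$sample_ids, sprintf("ppm_%.4f", bins$center))
  structure(
    list(
      x = x, bins = bins,
      excluded_regions = exclusions, removed_regions = list(),
      normalization = "none", scaling = "none"
    ),
    class = "spectra_matrix"
  )
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf(
    "<spectra_matrix> %d samples x %d bins (%.3f-%.3f ppm), normalization: %s, scaling: %s\n",
    nrow(x$x), ncol(x$x), min(x$bins$lo), max(x$bins$hi), x$normalization, x$scaling
  ))
  invisible(x)
}

#' @export
as_tibble.spectra_matrix <- function(x, ...) {
  bind_cols(tibble(sample_id = rownames(x$x)), as_tibble(x$x))
}

#' Remove bins overlapping given ppm regions
#'
#' Used after binning to discard windows containing exogenous signals (for
#' example anaesthetic or drug resonances). An empty region list is the
#' identity. Removals are logged in `removed_regions`.
#'
#' @param matrix A `spectra_matrix`.
#' @param regions List of `c(lo, hi)` ppm intervals.
#' @return The `spectra_matrix` with overlapping bins dropped.
#' @export
remove_bins <- function(matrix, regions = list()) {
  stopifnot(inherits(matrix, "spectra_matrix"))
  regions <- check_intervals(regions, "regions")
  if (length(regions) == 0) {
    return(matrix)
  }
  tol <- 1e-9
  keep <- rep(TRUE, nrow(matrix$bins))
  for (r in regions) {
    keep <- keep & !(matrix$bins$lo < r[2] - tol & matrix$bins$hi > r[1] + tol)
  }
  n_removed <- sum(!keep)
  if (all(!keep)) abort("`regions` would remove every bin.")
  inform(sprintf("removed %d bin(s) in %d region(s).", n_removed, length(regions)))
  matrix$x <- matrix$x[, keep, drop = FALSE]
  matrix$bins <- matrix$bins[keep, , drop = FALSE]
  matrix$removed_regions <- c(matrix$removed_regions, regions)
  matrix
}

#' Normalise each spectrum to a constant sum
#'
#' Scales every row so its bin intensities sum to `target` (conventionally
#' 100), minimising the effect of variable overall concentration between
#' samples. Idempotent; rows with non-positive sums are an error.
#'
#' @param matrix A `spectra_matrix`, or a plain numeric matrix.
#' @param target Positive row-sum target (default 100).
#' @return Same class as the input, normalised.
#' @export
normalize_constant_sum <- function(matrix, target = 100) {
  stopifnot_scalar_number(target, "target", positive = TRUE)
  is_sm <- inherits(matrix, "spectra_matrix")
  x <- if (is_sm) matrix$x else as_x_matrix(matrix)
  rs <- rowSums(x)
  bad <- which(rs <= 0)
  if (length(bad) > 0) {
    ids <- rownames(x)[bad] %||% as.character(bad)
    abort(sprintf(
      "non-positive row sum for sample(s): %s",
      paste(ids, collapse = ", ")
    ))
  }
  xn <- x * (target / rs)
  if (!is_sm) {
    return(xn)
  }
  matrix$x <- xn
  matrix$normalization <- "constant_sum"
  matrix$normalization_target <- target
  matrix
}
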