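# Internal helpers shared across modules.

# Coerce the X block of any supported container to a plain numeric matrix.
# Accepts a matrix, a data frame (numeric columns only; a `sample_id` column
# becomes rownames), or a `spectra_matrix`.
as_x_matrix <- function(x) {
  if (inherits(x, "spectra_matrix")) {
    return(x$x)
  }
  if (is.data.frame(x)) {
    ids <- NULL
    if ("sample_id" %in% names(x)) {
      ids <- as.character(x$sample_id)
      x <- x[setdiff(names(x), "sample_id")]
    }
    keep <- vapply(x, is.numeric, logical(1))
    m <- as.matrix(x[keep])
    if (!is.null(ids)) rownames(m) <- ids
    return(m)
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

# Coerce a response to a numeric matrix (vector -> one column).
as_y_matrix <- function(y) {
  if (is.data.frame(y)) y <- as.matrix(y[vapply(y, is.numeric, logical(1))])
  if (is.null(dim(y))) y <- matrix(as.numeric(y), ncol = 1)
  storage.mode(y) <- "double"
  y
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# Intervals are length-2 numeric vectors (lo, hi); a list of them is the
# standard representation for ppm exclusion regions.
check_intervals <- function(regions, name = "regions") {
  if (is.null(regions) || length(regions) == 0) {
    return(list())
  }
  if (is.numeric(regions) && length(regions) == 2) regions <- list(regions)
  ok <- vapply(
    regions,
    function(r) is.numeric(r) && length(r) == 2 && all(is.finite(r)) && r[1] < r[2],
    logical(1)
  )
  if (!all(ok)) {
    abort(sprintf("`%s` must be a list of (lo, hi) pairs with lo < hi.", name))
  }
  lapply(regions, as.numeric)
}

# sample() from a value set without the scalar-expansion surprise
# (sample(6) means sample from 1:6).
sample_from <- function(values, n) {
  values[sample.int(length(values), n, replace = TRUE)]
}

# Longest run of TRUE values in a logical vector (NA treated as FALSE).
max_true_run <- function(flag) {
  flag[is.na(flag)] <- FALSE
  if (!any(flag)) {
    return(0L)
  }
  r <- rle(flag)
  max(r$lengths[r$values])
}
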