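# ggplot2 views of the fitted objects.

#' @import ggplot2
NULL

#' Plot raw spectra
#'
#' Overlay intensity-versus-ppm traces for a handful of samples, with the
#' ppm axis reversed as is conventional for NMR.
#'
#' @param raw A [raw_spectra()] object.
#' @param samples Indices or sample ids to draw (default first 3).
#' @return A ggplot object.
#' @export
plot_spectra <- function(raw, samples = 1:3) {
  stopifnot(inherits(raw, "raw_spectra"))
  if (is.numeric(samples)) samples <- raw$sample_ids[samples]
  df <- purrr::map(samples, function(id) {
    tibble(sample_id = id, ppm = raw$ppm, intensity = raw$intensities[id, ])
  }) |> bind_rows()
  ggplot(df, aes(.data$ppm, .data$intensity, colour = .data$sample_id)) +
    geom_line(linewidth = 0.3) +
    scale_x_reverse() +
    labs(x = "chemical shift (ppm)", y = "intensity", colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.pca_model <- function(object, components = c(1, 2), metadata = NULL,
                               colour = NULL, ...) {
  scores <- tidy(object, "scores")
  if (!is.null(metadata)) scores <- left_join(scores, metadata, by = "sample_id")
  xvar <- paste0("PC", components[1])
  yvar <- paste0("PC", components[2])
  p <- ggplot(scores, aes(.data[[xvar]], .data[[yvar]]))
  p <- if (!is.null(colour)) p + geom_point(aes(colour = .data[[colour]])) else p + geom_point()
  p + labs(
    x = sprintf("%s (%.0f%%)", xvar, 100 * object$explained_variance[components[1]]),
    y = sprintf("%s (%.0f%%)", yvar, 100 * object$explained_variance[components[2]])
  ) + theme_minimal()
}

#' @export
autoplot.ptpls2_model <- function(object, metadata = NULL, colour = NULL, ...) {
  scores <- tidy(object)
  if (!is.null(metadata)) scores <- left_join(scores, metadata, by = "sample_id")
  yvar <- if (object$n_orthogonal > 0) "to1" else "tp1"
  p <- ggplot(scores, aes(.data$tp1, .data[[yvar]]))
  p <- if (!is.null(colour)) p + geom_point(aes(colour = .data[[colour]])) else p + geom_point()
  p + labs(x = "predictive score (tp1)", y = if (yvar == "to1") "orthogonal score (to1)" else "tp1") +
    theme_minimal()
}

#' @export
autoplot.bspc_chart <- function(object, ...) {
  limits <- object$points |>
    distinct(.data$time, .data$lower, .data$upper)
  ggplot(object$points, aes(.data$time, .data$predicted, group = .data$animal_id)) +
    geom_ribbon(
      data = limits,
      aes(.data$time, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.15
    ) +
    geom_line(aes(colour = .data$reference)) +
    geom_point(data = filter(object$points, .data$flag), colour = "red", size = 0.8) +
    labs(
      x = "expanded time (min)", y = "predicted time (min)",
      colour = "reference"
    ) +
    theme_minimal()
}

#' @export
autoplot.permutation_test <- function(object, statistic = c("R2", "Q2"), ...) {
  statistic <- match.arg(statistic)
  vals <- if (statistic == "R2") object$null_r2 else object$null_q2
  obs <- if (statistic == "R2") object$observed_r2 else object$observed_q2
  ggplot(tibble(value = vals), aes(.data$value)) +
    geom_histogram(bins = 30, fill = "grey70") +
    geom_vline(xintercept = obs, colour = "red") +
    labs(x = sprintf("permuted %s", statistic), y = "count") +
    theme_minimal()
}

#' @export
autoplot.stability_selection <- function(object, top = 20, ...) {
  df <- object$frequencies |>
    arrange(desc(.data$frequency)) |>
    head(top)
  ggplot(df, aes(
    x = stats::reorder(.data$variable, .data$frequency),
    y = .data$frequency, fill = .data$stable
  )) +
    geom_col() +
    coord_flip() +
    geom_hline(yintercept = object$stability_threshold, linetype = 2) +
    labs(x = NULL, y = "selection frequency", fill = "stable") +
    theme_minimal()
}
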