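# Batch statistical process control of per-animal metabolic trajectories.

#' Linearly expand per-animal timescales to a common duration
#'
#' Phases whose duration differs between animals (the asphyxial period
#' ranges over 4-10 minutes) are mapped onto a common clock by the linear
#' map `minute * target_duration / duration`, so the endpoint of every
#' animal lands on `target_duration` and an animal already lasting the
#' target duration is mapped identically.
#'
#' @param data Data frame with one row per sample, containing the
#'   within-phase minute and the animal identifier.
#' @param target_duration Common duration in minutes (default 10).
#' @param time,animal Column names (strings) of the minute and animal id.
#' @param durations Optional named vector of per-animal phase durations;
#'   defaults to each animal's largest observed minute.
#' @return The input tibble with an `expanded_time` column appended.
#' @export
expand_timescale <- function(data, target_duration = 10,
                             time = "minute_in_phase", animal = "animal_id",
                             durations = NULL) {
  stopifnot(is.data.frame(data))
  stopifnot_scalar_number(target_duration, "target_duration", positive = TRUE)
  tm <- as.numeric(data[[time]])
  an <- as.character(data[[animal]])
  if (is.null(durations)) {
    durations <- tapply(tm, an, max)
  }
  counts <- table(an)
  if (any(counts < 2)) {
    abort(sprintf(
      "animal(s) with fewer than 2 timepoints: %s",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  d <- durations[an]
  if (any(is.na(d)) || any(d <= 0)) {
    abort("every animal needs a positive phase duration.")
  }
  out <- as_tibble(data)
  out$expanded_time <- tm * target_duration / as.numeric(d)
  attr(out, "target_duration") <- target_duration
  out
}

#' Fit a BSPC reference model
#'
#' Fits a PLS model predicting the expanded time ("process maturity") from
#' the feature block, using the reference animals only, then interpolates
#' each reference animal's predicted-time trajectory onto a common grid and
#' computes the pointwise across-animal mean and sample standard deviation.
#' Control limits are later drawn at `mean(t) +/- k sd(t)`. Test animals
#' (for example damaged ones) are never part of the fit or the limits.
#'
#' @param x Unscaled feature matrix, rows aligned with `time`/`animal`.
#' @param time Expanded time per sample (minutes on the common scale).
#' @param animal Animal identifier per sample.
#' @param reference Identifiers of the reference animals (>= 2).
#' @param n_comp Number of PLS components (default 3).
#' @param grid_step Grid step on the common timescale (default 0.5 min).
#' @param x_scale Column scaling, estimated on reference samples only.
#' @param n_folds Folds for the Q2 estimate of the time model.
#' @return An object of class `bspc_model` with the fitted `pls`, its
#'   scaling, the `grid`, `reference_mean`/`reference_sd` per grid point,
#'   `r2` and `q2`.
#' @export
fit_bspc <- function(x, time, animal, reference, n_comp = 3, grid_step = 0.5,
                     x_scale = "pareto", n_folds = 7) {
  x <- as_x_matrix(x)
  time <- as.numeric(time)
  animal <- as.character(animal)
  if (length(time) != nrow(x) || length(animal) != nrow(x)) {
    abort("`time` and `animal` must align with the rows of `x`.")
  }
  reference <- as.character(reference)
  if (length(unique(reference)) < 2) abort("at least 2 reference animals are required.")
  if (!all(reference %in% animal)) {
    abort(sprintf(
      "reference animal(s) absent from the data: %s",
      paste(setdiff(reference, animal), collapse = ", ")
    ))
  }
  ref_rows <- animal %in% reference
  fs <- fit_scaled_pls(x[ref_rows, , drop = FALSE], time[ref_rows], n_comp,
    x_scale = x_scale
  )
  pred_ref <- as.numeric(predict(fs$fit, apply_scaling(
    x[ref_rows, , drop = FALSE], fs$scaling
  ))) + fs$y_center
  t_ref <- time[ref_rows]
  a_ref <- animal[ref_rows]
  grid <- seq(min(t_ref), max(t_ref), by = grid_step)
  traj <- vapply(unique(a_ref), function(id) {
    sel <- a_ref == id
    approx(t_ref[sel], pred_ref[sel], xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  n_at <- rowSums(!is.na(traj))
  keep <- n_at >= 2
  if (!all(keep)) {
    warn(sprintf("%d grid point(s) dropped (fewer than 2 reference animals).", sum(!keep)))
  }
  if (!any(keep)) abort("no grid point is covered by 2 or more reference animals.")
  grid <- grid[keep]
  traj <- traj[keep, , drop = FALSE]
  ref_mean <- rowMeans(traj, na.rm = TRUE)
  ref_sd <- apply(traj, 1, sd, na.rm = TRUE)
  q2 <- tryCatch(
    tail(cross_validate_q2(x[ref_rows, , drop = FALSE], t_ref, n_comp,
      n_folds = min(n_folds, floor(sum(ref_rows) / 2)), x_scale = x_scale
    )$q2, 1),
    error = function(e) NA_real_
  )
  structure(
    list(
      pls = fs$fit, scaling = fs$scaling, y_center = fs$y_center,
      reference_animal_ids = unique(a_ref), grid = grid,
      reference_mean = ref_mean, reference_sd = ref_sd,
      reference_trajectories = traj,
      r2 = cor(pred_ref, t_ref)^2, q2 = q2, n_comp = fs$fit$n_comp
    ),
    class = "bspc_model"
  )
}

#' @export
print.bspc_model <- function(x, ...) {
  cat(sprintf(
    "<bspc_model> A = %d, %d reference animals, grid %.1f-%.1f min, R2 = %.2f, Q2 = %.2f\n",
    x$n_comp, length(x$reference_animal_ids), min(x$grid), max(x$grid), x$r2, x$q2
  ))
  invisible(x)
}

#' @export
glance.bspc_model <- function(x, ...) {
  tibble(
    n_comp = x$n_comp, r2 = x$r2, q2 = x$q2,
    n_reference = length(x$reference_animal_ids),
    grid_min = min(x$grid), grid_max = max(x$grid)
  )
}

#' Control chart of trajectories against a BSPC reference
#'
#' Projects every animal (reference and test) through the fitted maturity
#' model, interpolates the predicted-time trajectory onto the reference
#' grid, and flags points outside `mean(t) +/- k sd(t)`. An animal is
#' declared out of control when it has at least `run_length` consecutive
#' flagged points (a run rule; isolated 2-SD excursions are expected about
#' 4.6% of the time even in control).
#'
#' @param model A [fit_bspc()] model.
#' @param x Feature matrix of all animals to chart.
#' @param time Expanded time per row of `x`.
#' @param animal Animal identifier per row of `x`.
#' @param k Control-limit width in standard deviations (default 2).
#' @param run_length Consecutive flagged points declaring an animal out of
#'   control (default 3).
#' @return An object of class `bspc_chart`: a `points` tibble (`animal_id`,
#'   `time`, `predicted`, `lower`, `upper`, `flag`, `reference`) and an
#'   `animals` summary (fraction of points flagged, longest run, first
#'   excursion time, `out_of_control`).
#' @export
bspc_chart <- function(model, x, time, animal, k = 2, run_length = 3) {
  stopifnot(inherits(model, "bspc_model"))
  if (k <= 0) abort("`k` must be positive.")
  x <- as_x_matrix(x)
  time <- as.numeric(time)
  animal <- as.character(animal)
  pred <- as.numeric(predict(model$pls, apply_scaling(x, model$scaling))) + model$y_center
  lower <- model$reference_mean - k * model$reference_sd
  upper <- model$reference_mean + k * model$reference_sd
  pts <- list()
  for (id in unique(animal)) {
    sel <- animal == id
    if (sum(sel) < 2) {
      warn(sprintf("animal %s has fewer than 2 samples and is excluded.", id))
      next
    }
    yi <- approx(time[sel], pred[sel], xout = model$grid, rule = 1)$y
    ok <- !is.na(yi)
    if (!any(ok)) {
      warn(sprintf("animal %s has no samples in the grid range and is excluded.", id))
      next
    }
    lo_i <- lower[ok]
    up_i <- upper[ok]
    pts[[id]] <- tibble(
      animal_id = id, time = model$grid[ok], predicted = yi[ok],
      lower = lo_i, upper = up_i,
      flag = yi[ok] < lo_i | yi[ok] > up_i,
      reference = id %in% model$reference_animal_ids
    )
  }
  points <- bind_rows(pts)
  animals <- points |>
    group_by(.data$animal_id, .data$reference) |>
    summarise(
      n_points = n(),
      n_out = sum(.data$flag),
      fraction_out = mean(.data$flag),
      max_run = max_true_run(.data$flag),
      first_out_time = if (any(.data$flag)) min(.data$time[.data$flag]) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(out_of_control = .data$max_run >= run_length)
  structure(
    list(points = points, animals = animals, k = k, run_length = as.integer(run_length)),
    class = "bspc_chart"
  )
}

#' @export
print.bspc_chart <- function(x, ...) {
  cat(sprintf(
    "<bspc_chart> k = %g, %d animal(s), %d out of control\n",
    x$k, nrow(x$animals), sum(x$animals$out_of_control)
  ))
  invisible(x)
}

#' @export
tidy.bspc_chart <- function(x, ...) {
  x$points
}

#' @export
glance.bspc_chart <- function(x, ...) {
  tibble(
    k = x$k, run_length = x$run_length,
    n_animals = nrow(x$animals),
    n_out_of_control = sum(x$animals$out_of_control),
    point_fraction_out = mean(x$points$flag)
  )
}
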