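# One-command pipeline presets chaining the stages into the three headline
# analyses: arrest-cause contrast, asphyxia trajectory monitoring, and the
# within-group CPR contrast.

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null", na = "null"
  )
  invisible(path)
}

# Feature block for multivariate presets: binned/normalised spectra when
# available, otherwise log concentrations.
pipeline_x_block <- function(cohort, config) {
  if (!is.null(cohort$spectra)) {
    pp <- config$preprocessing
    sm <- bin_spectra(cohort$spectra,
      ppm_min = pp$ppm_min, ppm_max = pp$ppm_max,
      width = pp$width, exclusions = pp$exclusions
    )
    if (length(pp$drug_regions) > 0) {
      sm <- suppressMessages(remove_bins(sm, pp$drug_regions))
    }
    sm <- normalize_constant_sum(sm, pp$normalization_target)
    list(x = sm$x, source = "spectra")
  } else {
    x <- log(as_x_matrix(cohort$quant))
    list(x = x, source = "log_quant")
  }
}

check_phase <- function(metadata, phase, preset) {
  if (!any(metadata$phase == phase)) {
    abort(sprintf(
      "preset `%s` needs samples in phase `%s`; phases present: %s",
      preset, phase, paste(unique(metadata$phase), collapse = ", ")
    ))
  }
}

#' Run a preset analysis pipeline
#'
#' Chains preprocessing, latent modelling, validation and reporting into
#' one reproducible invocation. Three presets are available:
#'
#' * `"ca-contrast"`: ptPLS2 discriminant analysis of the two arrest
#'   causes over the untreated-arrest minutes (design matrix of class and
#'   time), with cross-validation, permutation testing and Monte-Carlo
#'   stability selection.
#' * `"asphyxia-bspc"`: linear timescale expansion of the asphyxial phase,
#'   BSPC reference model on no-damaged animals, 2-SD control chart of all
#'   animals, and an endpoint PCA of baseline versus last asphyxial
#'   minute.
#' * `"cpr-contrast"`: within-group ptPLS2 of first versus last CPR
#'   minute plus a paired Wilcoxon / fold-change / q-value effect table.
#'
#' Every artefact is written to `out_dir` along with a JSON snapshot of
#' the configuration and seed, so a re-run with the same inputs and seed
#' reproduces the outputs exactly.
#'
#' @param cohort A [generate_cohort()] result, or a list with `quant`,
#'   `metadata` and optionally `spectra` (a [raw_spectra()]).
#' @param preset One of `"ca-contrast"`, `"asphyxia-bspc"`,
#'   `"cpr-contrast"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed used for every stochastic stage.
#' @param config A [pipeline_config()].
#' @param group Group analysed by `"cpr-contrast"` (default the second
#'   group label present, conventionally VFCA).
#' @return A list of class `pipeline_run` with the fitted objects, result
#'   tibbles and file paths.
#' @export
run_pipeline <- function(cohort, preset = c("ca-contrast", "asphyxia-bspc", "cpr-contrast"),
                         out_dir, seed = 1L, config = pipeline_config(),
                         group = NULL) {
  preset <- match.arg(preset)
  stopifnot(inherits(config, "pipeline_config"))
  md <- as_tibble(cohort$metadata)
  check_required_columns(
    md, c("sample_id", "animal_id", "group", "phase", "minute_in_phase"),
    "metadata"
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  xb <- pipeline_x_block(cohort, config)
  if (!identical(rownames(xb$x), md$sample_id)) {
    xb$x <- xb$x[match(md$sample_id, rownames(xb$x)), , drop = FALSE]
  }
  results <- switch(preset,
    "ca-contrast" = run_ca_contrast(xb, md, config, seed, out_dir),
    "asphyxia-bspc" = run_asphyxia_bspc(xb, cohort, md, config, seed, out_dir),
    "cpr-contrast" = run_cpr_contrast(xb, cohort, md, config, seed, out_dir, group)
  )
  snapshot <- list(
    preset = preset, seed = seed, x_source = xb$source,
    config = unclass(config), n_samples = nrow(md),
    package_version = as.character(utils::packageVersion("arrestomix"))
  )
  write_json_out(snapshot, file.path(out_dir, "run_config.json"))
  structure(
    c(list(preset = preset, out_dir = out_dir, seed = seed), results),
    class = "pipeline_run"
  )
}

choose_components <- function(x, y, config, ...) {
  if (identical(config$model$components, "auto")) {
    max_a <- min(config$model$max_components, nrow(x) - 1, ncol(x))
    as.integer(select_components(x, y, max_a,
      n_folds = min(config$validation$n_folds, floor(nrow(x) / 2)),
      x_scale = config$preprocessing$scaling, ...
    ))
  } else {
    as.integer(config$model$components)
  }
}

run_ca_contrast <- function(xb, md, config, seed, out_dir) {
  check_phase(md, "CA", "ca-contrast")
  rows <- md$phase == "CA"
  md_ca <- md[rows, , drop = FALSE]
  if (length(unique(md_ca$group)) < 2) {
    abort("ca-contrast needs CA samples from both groups.")
  }
  x <- xb$x[rows, , drop = FALSE]
  y <- design_matrix(md_ca, "group", "minute_in_phase")
  scaling <- config$preprocessing$scaling
  a <- choose_components(x, y, config)
  fs <- fit_scaled_pls(x, y, a, scaling)
  pt <- post_transform(fs$fit)
  val <- validate_pls(x, y, a,
    n_folds = min(config$validation$n_folds, floor(nrow(x) / 2)),
    n_perm = config$validation$n_permutations, seed = seed,
    scheme = config$validation$scheme, x_scale = scaling
  )
  vip_tab <- vip(fs$fit)
  stab <- stability_selection(x, y, a,
    n_subsets = 50, inclusion_probability = 0.7,
    seed = seed + 1L, x_scale = scaling
  )
  scores <- tidy(pt) |> left_join(md_ca, by = "sample_id")
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(vip_tab, file.path(out_dir, "vip.csv"))
  readr::write_csv(stab$frequencies, file.path(out_dir, "stability.csv"))
  write_json_out(as.list(glance(val)), file.path(out_dir, "validation.json"))
  list(model = pt, validation = val, vip = vip_tab, stability = stab, scores = scores)
}

run_asphyxia_bspc <- function(xb, cohort, md, config, seed, out_dir) {
  check_phase(md, config$bspc$phase, "asphyxia-bspc")
  aca <- md$group == md$group[md$phase == config$bspc$phase][1]
  rows <- md$phase == config$bspc$phase & aca
  md_a <- md[rows, , drop = FALSE]
  if (!"damage_class" %in% names(md_a)) abort("metadata needs `damage_class` for BSPC.")
  expanded <- expand_timescale(md_a, target_duration = config$bspc$target_duration)
  reference <- unique(md_a$animal_id[md_a$damage_class == config$bspc$reference_class])
  if (length(reference) < 2) {
    abort(sprintf(
      "asphyxia-bspc needs >= 2 reference animals of class `%s`.",
      config$bspc$reference_class
    ))
  }
  x <- xb$x[rows, , drop = FALSE]
  model <- fit_bspc(x, expanded$expanded_time, expanded$animal_id, reference,
    n_comp = config$bspc$n_components, grid_step = config$bspc$grid_step,
    x_scale = config$preprocessing$scaling
  )
  chart <- bspc_chart(model, x, expanded$expanded_time, expanded$animal_id,
    k = config$bspc$k
  )
  # Endpoint PCA: baseline vs last minute of the expanded phase.
  last_md <- md_a |>
    group_by(.data$animal_id) |>
    slice_max(.data$minute_in_phase, n = 1, with_ties = FALSE) |>
    ungroup()
  base_md <- md |> filter(.data$phase == "baseline", .data$animal_id %in% md_a$animal_id)
  pca_md <- bind_rows(
    base_md |> mutate(point = "baseline"),
    last_md |> mutate(point = "end_of_phase")
  )
  xp <- xb$x[match(pca_md$sample_id, md$sample_id), , drop = FALSE]
  sp <- suppressWarnings(scale_features(xp, config$preprocessing$scaling))
  pca <- fit_pca(sp$x, 2)
  pca_scores <- tidy(pca, "scores") |> left_join(pca_md, by = "sample_id")
  readr::write_csv(chart$points, file.path(out_dir, "bspc_chart.csv"))
  readr::write_csv(chart$animals, file.path(out_dir, "bspc_animals.csv"))
  readr::write_csv(pca_scores, file.path(out_dir, "endpoint_pca_scores.csv"))
  write_json_out(as.list(glance(model)), file.path(out_dir, "bspc_model.json"))
  list(model = model, chart = chart, endpoint_pca = pca, pca_scores = pca_scores)
}

run_cpr_contrast <- function(xb, cohort, md, config, seed, out_dir, group) {
  check_phase(md, "CPR", "cpr-contrast")
  if (is.null(group)) {
    grps <- unique(md$group)
    group <- if (length(grps) > 1) grps[length(grps)] else grps[1]
  }
  md_cpr <- md |> filter(.data$phase == "CPR", .data$group == !!group)
  if (nrow(md_cpr) == 0) {
    abort(sprintf("cpr-contrast: no CPR samples for group `%s`.", group))
  }
  ends <- md_cpr |>
    group_by(.data$animal_id) |>
    filter(n() >= 2) |>
    summarise(
      first_id = .data$sample_id[which.min(.data$minute_in_phase)],
      last_id = .data$sample_id[which.max(.data$minute_in_phase)],
      .groups = "drop"
    )
  sel_md <- bind_rows(
    md_cpr |> filter(.data$sample_id %in% ends$first_id) |> mutate(point = "begin"),
    md_cpr |> filter(.data$sample_id %in% ends$last_id) |> mutate(point = "end")
  )
  x <- xb$x[match(sel_md$sample_id, md$sample_id), , drop = FALSE]
  y <- design_matrix(sel_md, "point")
  scaling <- config$preprocessing$scaling
  a <- choose_components(x, y, config)
  fs <- fit_scaled_pls(x, y, a, scaling)
  pt <- post_transform(fs$fit)
  val <- validate_pls(x, y, a,
    n_folds = min(config$validation$n_folds, floor(nrow(x) / 2)),
    n_perm = config$validation$n_permutations, seed = seed,
    scheme = config$validation$scheme, x_scale = scaling
  )
  effects <- paired_effect_table(cohort$quant, md, "CPR", "CPR",
    from_minute = "first", to_minute = "last", group = group
  )
  scores <- tidy(pt) |> left_join(sel_md, by = "sample_id")
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(effects, file.path(out_dir, "effect_table.csv"))
  write_json_out(as.list(glance(val)), file.path(out_dir, "validation.json"))
  list(model = pt, validation = val, effects = effects, scores = scores, group = group)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> preset `%s`, seed %d, outputs in %s\n", x$preset, x$seed, x$out_dir))
  invisible(x)
}
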