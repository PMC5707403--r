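# Tabular interchange: tidy CSV/TSV with schema checks, dialect chosen by
# file extension.

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

write_delim_auto <- function(x, path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(x, path)
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}

check_required_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s lacks required column(s): %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read and write sample tables
#'
#' CSV/TSV readers and writers for the package's tabular containers
#' (dialect auto-detected by extension, unknown columns preserved). Every
#' reader validates its schema: a quantification table needs a unique
#' `sample_id` plus numeric metabolite columns; metadata needs the sample,
#' animal, group, damage-class, phase and minute columns; a wide spectra
#' table has `sample_id` plus one numeric column per ppm grid point.
#'
#' @param path File path ending in `.csv` or `.tsv`.
#' @param quant,metadata A tibble to write.
#' @param raw A [raw_spectra()] object to write.
#' @return Readers return a tibble (or `raw_spectra`); writers return the
#'   path invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_quant_table <- function(path) {
  df <- read_delim_auto(path)
  check_required_columns(df, "sample_id", "quantification table")
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf(
      "duplicated sample_id(s): %s",
      paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")
    ))
  }
  df
}

#' @rdname table_io
#' @export
write_quant_table <- function(quant, path) {
  check_required_columns(quant, "sample_id", "quantification table")
  write_delim_auto(quant, path)
}

#' @rdname table_io
#' @export
read_metadata_table <- function(path) {
  df <- read_delim_auto(path)
  check_required_columns(
    df,
    c("sample_id", "animal_id", "group", "damage_class", "phase", "minute_in_phase"),
    "metadata table"
  )
  if (anyDuplicated(df$sample_id)) abort("duplicated sample_id in metadata.")
  df
}

#' @rdname table_io
#' @export
write_metadata_table <- function(metadata, path) {
  check_required_columns(
    metadata,
    c("sample_id", "animal_id", "group", "damage_class", "phase", "minute_in_phase"),
    "metadata table"
  )
  write_delim_auto(metadata, path)
}

#' @rdname table_io
#' @export
read_spectra_table <- function(path) {
  df <- read_delim_auto(path)
  check_required_columns(df, "sample_id", "spectra table")
  ppm <- suppressWarnings(as.numeric(setdiff(names(df), "sample_id")))
  if (any(is.na(ppm))) abort("spectra table columns after sample_id must be numeric ppm values.")
  raw_spectra(ppm, as.matrix(df[setdiff(names(df), "sample_id")]),
    sample_ids = df$sample_id
  )
}

#' @rdname table_io
#' @export
write_spectra_table <- function(raw, path) {
  stopifnot(inherits(raw, "raw_spectra"))
  df <- bind_cols(
    tibble(sample_id = raw$sample_ids),
    as_tibble(raw$intensities, .name_repair = ~ format(raw$ppm, trim = TRUE, digits = 10))
  )
  write_delim_auto(df, path)
}

#' Read a pipeline configuration
#'
#' Loads a YAML (or JSON) pipeline configuration and merges it over the
#' package defaults: a `preprocessing` block (ppm range, bin width,
#' exclusions, drug regions, normalisation target, scaling), a `model`
#' block (components, post-transformation), a `validation` block (folds,
#' scheme, permutations), a `bspc` block (phase, target duration, k,
#' reference class) and a `stats` block (fdr method).
#'
#' @param path Path to a YAML/JSON file, or `NULL` for pure defaults.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL) {
  defaults <- list(
    preprocessing = list(
      ppm_min = 0.80, ppm_max = 9.00, width = 0.01,
      exclusions = list(c(4.66, 5.18)), drug_regions = list(),
      normalization_target = 100, scaling = "pareto"
    ),
    model = list(components = "auto", max_components = 5, post_transform = TRUE),
    validation = list(n_folds = 7, scheme = "interleaved", n_permutations = 199),
    bspc = list(
      phase = "asphyxia", target_duration = 10, k = 2,
      reference_class = "no-damaged", n_components = 3, grid_step = 0.5
    ),
    stats = list(fdr = "BH")
  )
  if (is.null(path)) {
    cfg <- defaults
  } else {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg <- modifyList(defaults, user)
  }
  structure(cfg, class = "pipeline_config")
}
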