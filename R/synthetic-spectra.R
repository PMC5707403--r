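#' Render NMR-like spectra from a concentration table
#'
#' Builds one synthetic 1H spectrum per sample as a superposition of
#' Lorentzian resonances, one set per metabolite, with intensity
#' proportional to the sample's concentration, plus an optional smooth
#' baseline and additive Gaussian noise. Intensities are clipped at zero.
#' With zero noise and baseline the integrated area of each metabolite's
#' peaks is exactly linear in its concentration, which is the property the
#' binning and normalisation stages are tested against.
#'
#' @param quant Tibble with `sample_id` plus one concentration column per
#'   metabolite (as produced by [generate_cohort()]).
#' @param specs Named list of [metabolite_spec()] objects; only entries with
#'   `ppm_peaks` contribute resonances. Every peak centre must lie inside
#'   `ppm_range`.
#' @param ppm_range Chemical-shift range of the grid (default 0.80-9.00).
#' @param ppm_step Grid step in ppm (default 0.002, i.e. 5 points per
#'   0.01-ppm bin).
#' @param baseline_amp Amplitude of the smooth baseline (0 disables it).
#' @param noise_sd SD of the additive Gaussian noise (0 disables it).
#' @param seed Integer seed for the noise draws.
#' @return A [raw_spectra()] object with one row per `quant` row.
#' @export
generate_spectra <- function(quant, specs, ppm_range = c(0.80, 9.00),
                             ppm_step = 0.002, baseline_amp = 0,
                             noise_sd = 0, seed = 1L) {
  stopifnot_scalar_number(ppm_step, "ppm_step", positive = TRUE)
  if (length(ppm_range) != 2 || ppm_range[1] >= ppm_range[2]) {
    abort("`ppm_range` must be an increasing pair.")
  }
  if (!"sample_id" %in% names(quant)) abort("`quant` needs a `sample_id` column.")
  ppm <- seq(ppm_range[1], ppm_range[2], by = ppm_step)

  with_peaks <- Filter(function(sp) !is.null(sp$ppm_peaks) && nrow(sp$ppm_peaks) > 0, specs)
  for (sp in with_peaks) {
    out <- sp$ppm_peaks$center < ppm_range[1] | sp$ppm_peaks$center > ppm_range[2]
    if (any(out)) {
      abort(sprintf(
        "`%s` has peak centre(s) outside the ppm grid: %s",
        sp$name, paste(format(sp$ppm_peaks$center[out]), collapse = ", ")
      ))
    }
  }

  met_names <- vapply(with_peaks, `[[`, character(1), "name")
  missing <- setdiff(met_names, names(quant))
  if (length(missing) > 0) {
    abort(sprintf("`quant` lacks column(s): %s", paste(missing, collapse = ", ")))
  }

  # One Lorentzian template per metabolite (peaks x grid summed).
  shapes <- vapply(with_peaks, function(sp) {
    pk <- sp$ppm_peaks
    rowSums(vapply(seq_len(nrow(pk)), function(j) {
      pk$amplitude[j] * pk$hwhm[j]^2 / ((ppm - pk$center[j])^2 + pk$hwhm[j]^2)
    }, numeric(length(ppm))))
  }, numeric(length(ppm)))

  conc <- as.matrix(quant[met_names])
  intensities <- if (length(met_names) > 0) conc %*% t(shapes) else {
    matrix(0, nrow(quant), length(ppm))
  }
  if (baseline_amp != 0) {
    bl <- baseline_amp * (1 + 0.5 * cos(pi * (ppm - ppm_range[1]) / diff(ppm_range)))
    intensities <- sweep(intensities, 2, bl, "+")
  }
  if (noise_sd > 0) {
    set.seed(seed)
    intensities <- intensities + matrix(
      rnorm(length(intensities), 0, noise_sd),
      nrow = nrow(intensities)
    )
  }
  intensities[intensities < 0] <- 0
  raw_spectra(ppm, intensities, sample_ids = quant$sample_id)
}
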