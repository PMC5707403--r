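# Cohort generator: determinism, closed-form trajectories, fold-change
# caps, and spectra rendering.

test_that("identical seeds reproduce the cohort bit-identically", {
  cfg <- cohort_config(n_animals_per_group = 3, seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$quant, c2$quant)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$truth$animals, c2$truth$animals)
  s1 <- generate_spectra(c1$quant, cfg$metabolite_specs,
    ppm_step = 0.02, noise_sd = 0.1, seed = 7
  )
  s2 <- generate_spectra(c2$quant, cfg$metabolite_specs,
    ppm_step = 0.02, noise_sd = 0.1, seed = 7
  )
  expect_identical(s1$intensities, s2$intensities)
})

test_that("noiseless trajectories follow the closed form exactly", {
  # Rate log(2)/min doubles the concentration each asphyxial minute.
  spec <- metabolite_spec("m", 10,
    baseline_cv = 0.3,
    rates = data.frame(group = "ACA", phase = "asphyxia", class = "*", rate = log(2))
  )
  cfg <- cohort_config(
    n_animals_per_group = 3, groups = "ACA", damaged_fraction_aca = 0,
    asphyxia_duration_range = c(2, 2), metabolite_specs = list(m = spec),
    noise_sd_frac = 0, seed = 11
  )
  co <- generate_cohort(cfg)
  wide <- dplyr::inner_join(co$quant, co$metadata, by = "sample_id")
  for (id in unique(wide$animal_id)) {
    base <- wide$m[wide$animal_id == id & wide$phase == "baseline"]
    end <- wide$m[wide$animal_id == id & wide$phase == "asphyxia" &
      wide$minute_in_phase == 2]
    expect_equal(end / base, 4, tolerance = 1e-12)
  }
  # And the recorded ground truth matches the emitted concentrations.
  expect_equal(co$quant$m, co$truth$trajectories$noiseless_m, tolerance = 1e-12)
})

test_that("drawn fold changes never exceed the class caps", {
  co <- generate_cohort(cohort_config(n_animals_per_group = 5, seed = 3))
  lf <- dplyr::inner_join(co$truth$trajectories, co$metadata, by = "sample_id")
  cls <- co$truth$animals
  for (i in seq_len(nrow(cls))) {
    rows <- lf[lf$animal_id == cls$animal_id[i], ]
    for (spec in co$truth$config$metabolite_specs) {
      cap <- spec$max_fold_change[[cls$damage_class[i]]]
      expect_true(all(rows[[paste0("logfold_", spec$name)]] <= log(cap) + 1e-9))
    }
  }
  # The headline contrast: succinate capped at 40-fold (damaged) vs 3-fold.
  succ <- lf[, c("animal_id", "logfold_succinate")] |>
    dplyr::inner_join(cls, by = "animal_id")
  expect_true(all(succ$logfold_succinate[succ$damage_class == "damaged"] <= log(40) + 1e-9))
  expect_true(all(succ$logfold_succinate[succ$damage_class == "no-damaged"] <= log(3) + 1e-9))
})

test_that("metadata satisfies the design invariants", {
  co <- generate_cohort(cohort_config(n_animals_per_group = 4, seed = 5))
  md <- co$metadata
  expect_false(any(duplicated(md[c("animal_id", "phase", "minute_in_phase")])))
  expect_true(all(md$damage_class[md$group != "ACA"] == "n/a"))
  expect_true(all(md$damage_class[md$group == "ACA"] %in% c("damaged", "no-damaged")))
  # Deterministic damaged count: round(fraction * n).
  expect_equal(sum(co$truth$animals$damage_class == "damaged"), round(0.4 * 4))
  # VFCA animals skip the asphyxial phase.
  expect_false(any(md$phase == "asphyxia" & md$group == "VFCA"))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(metabolite_specs = list()), "empty")
  expect_error(cohort_config(asphyxia_duration_range = c(0, 5)), "positive")
  expect_error(cohort_config(damaged_fraction_aca = 1.4), "0, 1")
  expect_error(cohort_config(ca_duration = -1), "positive")
  expect_error(metabolite_spec("x", -2), "positive")
  expect_error(metabolite_spec("x", 1, max_fold_change = 0.5), ">= 1")
  expect_error(
    metabolite_spec("x", 1, ppm_peaks = data.frame(center = 12, amplitude = 1, hwhm = 0.01)),
    "0.80-9.00"
  )
})

test_that("spectrum area is linear in concentration with zero noise", {
  spec <- metabolite_spec("m", 1,
    ppm_peaks = data.frame(center = 3.0, amplitude = 1, hwhm = 0.01)
  )
  quant <- tibble::tibble(sample_id = c("a", "b"), m = c(2, 5))
  rs <- generate_spectra(quant, list(m = spec), ppm_step = 0.005)
  area <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(rs$ppm))
  ratio <- area(rs$intensities["b", ]) / area(rs$intensities["a", ])
  expect_equal(ratio, 5 / 2, tolerance = 1e-6)
})

test_that("disjoint peaks recover per-metabolite concentration ratios", {
  specs <- list(
    m1 = metabolite_spec("m1", 1, ppm_peaks = data.frame(center = 2.0, amplitude = 1, hwhm = 0.005)),
    m2 = metabolite_spec("m2", 1, ppm_peaks = data.frame(center = 7.0, amplitude = 0.5, hwhm = 0.005))
  )
  quant <- tibble::tibble(sample_id = "s", m1 = 3, m2 = 12)
  rs <- generate_spectra(quant, specs, ppm_step = 0.002)
  # Numeric-integration oracle: per-region integral of a unit-concentration
  # spectrum of each metabolite alone.
  unit1 <- generate_spectra(tibble::tibble(sample_id = "u", m1 = 1, m2 = 0), specs, ppm_step = 0.002)
  unit2 <- generate_spectra(tibble::tibble(sample_id = "u", m1 = 0, m2 = 1), specs, ppm_step = 0.002)
  region <- function(raw, lo, hi) {
    sel <- raw$ppm >= lo & raw$ppm <= hi
    y <- raw$intensities[1, sel]
    sum((y[-1] + y[-length(y)]) / 2 * diff(raw$ppm[sel]))
  }
  est1 <- region(rs, 1.5, 2.5) / region(unit1, 1.5, 2.5)
  est2 <- region(rs, 6.5, 7.5) / region(unit2, 6.5, 7.5)
  # Lorentzian tails leak a little across regions; recovery is to ~0.1%.
  expect_equal(est1 / est2, 3 / 12, tolerance = 1e-3)
})

test_that("zero concentrations and zero noise give the bare baseline", {
  spec <- metabolite_spec("m", 1,
    ppm_peaks = data.frame(center = 3.0, amplitude = 1, hwhm = 0.01)
  )
  quant <- tibble::tibble(sample_id = "s", m = 0)
  flat <- generate_spectra(quant, list(m = spec), ppm_step = 0.01)
  expect_true(all(flat$intensities == 0))
  with_bl <- generate_spectra(quant, list(m = spec), ppm_step = 0.01, baseline_amp = 2)
  expect_true(all(with_bl$intensities >= 0))
  expect_gt(min(with_bl$intensities), 0)
})

test_that("peaks outside the grid are a configuration error", {
  spec <- metabolite_spec("m", 1,
    ppm_peaks = data.frame(center = 8.5, amplitude = 1, hwhm = 0.01)
  )
  quant <- tibble::tibble(sample_id = "s", m = 1)
  expect_error(
    generate_spectra(quant, list(m = spec), ppm_range = c(0.8, 5)),
    "outside the ppm grid"
  )
})
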