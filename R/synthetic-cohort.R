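#' Describe one simulated metabolite
#'
#' A `metabolite_spec` defines the concentration model of one analyte in the
#' synthetic cohort: a lognormal animal baseline, class-specific kinetic
#' rates per experimental phase, a hard cap on the achievable fold change,
#' and the NMR resonances used when rendering spectra.
#'
#' The trajectory is piecewise linear in log concentration: flat at
#' baseline, rising (or falling) at `rate` log-units per minute through the
#' asphyxia, cardiac-arrest and CPR phases, and decaying exponentially back
#' towards baseline after return of spontaneous circulation. The log fold
#' change is capped at `log(max_fold_change)` for the animal's damage class.
#'
#' @param name Metabolite name.
#' @param baseline_mean Baseline concentration in umol/L (positive).
#' @param baseline_cv Between-animal coefficient of variation of the
#'   baseline (lognormal; 0 gives every animal exactly `baseline_mean`).
#' @param animal_intercept_sd Additive animal random-intercept SD in umol/L.
#' @param rates Data frame with columns `group`, `phase`, `class`, `rate`
#'   (log-fold per minute). `"*"` is a wildcard for `group` and `class`;
#'   unmatched combinations default to rate 0. Asphyxial rates are per
#'   minute of the nominal (maximal) episode: animals that arrest earlier
#'   progress proportionally faster, so the end-of-asphyxia fold change is
#'   set by the damage class rather than by the episode duration. CA and
#'   CPR rates apply per real minute.
#' @param max_fold_change Named numeric of caps per damage class
#'   (`damaged`, `no-damaged`, `n/a`), or a single value for all classes.
#'   Caps must be >= 1.
#' @param ppm_peaks Data frame with columns `center` (ppm, within
#'   0.80-9.00), `amplitude` (relative), `hwhm` (half width at half maximum,
#'   ppm), or `NULL` for analytes quantified but not rendered in spectra.
#' @return An object of class `metabolite_spec`.
#' @seealso [swine_ca_metabolites()] for the shipped preset.
#' @export
metabolite_spec <- function(name, baseline_mean, baseline_cv = 0,
                            animal_intercept_sd = 0, rates = NULL,
                            max_fold_change = Inf, ppm_peaks = NULL) {
  stopifnot_scalar_number(baseline_mean, "baseline_mean", positive = TRUE)
  stopifnot_scalar_number(baseline_cv, "baseline_cv")
  if (baseline_cv < 0) abort("`baseline_cv` must be non-negative.")
  stopifnot_scalar_number(animal_intercept_sd, "animal_intercept_sd")
  if (is.null(rates)) {
    rates <- tibble(group = character(), phase = character(), class = character(), rate = numeric())
  }
  rates <- as_tibble(rates)
  need <- c("group", "phase", "class", "rate")
  if (!all(need %in% names(rates))) {
    abort("`rates` needs columns group, phase, class, rate.")
  }
  if (any(!is.finite(rates$rate))) abort("rates must be finite.")
  if (length(max_fold_change) == 1 && is.null(names(max_fold_change))) {
    max_fold_change <- c(
      damaged = unname(max_fold_change),
      `no-damaged` = unname(max_fold_change),
      `n/a` = unname(max_fold_change)
    )
  }
  if (any(max_fold_change < 1)) abort("`max_fold_change` caps must be >= 1.")
  if (!is.null(ppm_peaks)) {
    ppm_peaks <- as_tibble(ppm_peaks)
    if (!all(c("center", "amplitude", "hwhm") %in% names(ppm_peaks))) {
      abort("`ppm_peaks` needs columns center, amplitude, hwhm.")
    }
    if (any(ppm_peaks$center < 0.80 | ppm_peaks$center > 9.00)) {
      abort(sprintf("`%s`: ppm peak centres must lie within 0.80-9.00 ppm.", name))
    }
    if (any(ppm_peaks$hwhm <= 0) || any(ppm_peaks$amplitude < 0)) {
      abort("`ppm_peaks` amplitudes must be >= 0 and hwhm > 0.")
    }
  }
  structure(
    list(
      name = as.character(name), baseline_mean = baseline_mean,
      baseline_cv = baseline_cv, animal_intercept_sd = animal_intercept_sd,
      rates = rates, max_fold_change = max_fold_change, ppm_peaks = ppm_peaks
    ),
    class = "metabolite_spec"
  )
}

# Most-specific matching rate for (group, phase, class); 0 when unmatched.
lookup_rate <- function(spec, group, phase, class) {
  r <- spec$rates
  hit <- (r$phase == phase) &
    (r$group == group | r$group == "*") &
    (r$class == class | r$class == "*")
  if (!any(hit)) {
    return(0)
  }
  r <- r[hit, , drop = FALSE]
  specificity <- (r$group == group) + (r$class == class)
  r$rate[which.max(specificity)]
}

lookup_cap <- function(spec, class) {
  caps <- spec$max_fold_change
  if (class %in% names(caps)) {
    return(unname(caps[[class]]))
  }
  if (length(caps) >= 1) {
    return(unname(caps[[1]]))
  }
  Inf
}

#' Shipped metabolite preset for the swine cardiac-arrest cohort
#'
#' Six analytes with kinetics chosen to reproduce the qualitative behaviour
#' of experimental asphyxial (ACA) versus ventricular-fibrillation (VFCA)
#' cardiac arrest: succinate rises steeply during asphyxia only in damaged
#' ACA animals (capped at 40-fold over baseline, versus 3-fold in
#' no-damaged animals), stays flat during no-flow arrest in VFCA and
#' accumulates there only once CPR restores flow; lactate, malate,
#' hypoxanthine and glutamate follow related hypoxia kinetics; alanine is a
#' weakly responsive control. Baseline concentrations are order-of-magnitude
#' literature values and the resonance positions (for example the lactate
#' doublet near 1.33 ppm and the succinate singlet at 2.41 ppm) are common
#' literature chemical shifts — both are conventions of this generator, not
#' measurements.
#'
#' @return A named list of [metabolite_spec()] objects.
#' @export
swine_ca_metabolites <- function() {
  rt <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    tibble(group = m[, 1], phase = m[, 2], class = m[, 3], rate = as.numeric(m[, 4]))
  }
  peaks <- function(...) {
    m <- matrix(as.numeric(c(...)), ncol = 3, byrow = TRUE)
    tibble(center = m[, 1], amplitude = m[, 2], hwhm = m[, 3])
  }
  specs <- list(
    metabolite_spec(
      "succinate", 20, baseline_cv = 0.15,
      rates = rt(
        "ACA", "asphyxia", "damaged", 0.45,
        "ACA", "asphyxia", "no-damaged", 0.13,
        "ACA", "CPR", "damaged", 0.05,
        "ACA", "CPR", "no-damaged", 0.03,
        "VFCA", "CPR", "*", 0.28
      ),
      max_fold_change = c(damaged = 40, `no-damaged` = 3, `n/a` = 12),
      ppm_peaks = peaks(2.41, 1.0, 0.004)
    ),
    metabolite_spec(
      "lactate", 1500, baseline_cv = 0.10,
      rates = rt(
        "ACA", "asphyxia", "damaged", 0.25,
        "ACA", "asphyxia", "no-damaged", 0.16,
        "*", "CA", "*", 0.02,
        "ACA", "CPR", "*", 0.04,
        "VFCA", "CPR", "*", 0.08
      ),
      max_fold_change = c(damaged = 12, `no-damaged` = 8, `n/a` = 5),
      ppm_peaks = peaks(
        1.32, 0.55, 0.004,
        1.34, 0.55, 0.004,
        4.11, 0.20, 0.005
      )
    ),
    metabolite_spec(
      "malate", 8, baseline_cv = 0.15,
      rates = rt(
        "ACA", "asphyxia", "damaged", 0.30,
        "ACA", "asphyxia", "no-damaged", 0.10,
        "VFCA", "CPR", "*", 0.19
      ),
      max_fold_change = c(damaged = 15, `no-damaged` = 4, `n/a` = 4),
      ppm_peaks = peaks(
        2.37, 0.5, 0.005,
        2.68, 0.5, 0.005,
        4.30, 0.4, 0.005
      )
    ),
    metabolite_spec(
      "hypoxanthine", 4, baseline_cv = 0.20,
      rates = rt(
        "ACA", "asphyxia", "damaged", 0.35,
        "ACA", "asphyxia", "no-damaged", 0.15,
        "ACA", "CA", "*", 0.08,
        "VFCA", "CPR", "*", 0.18
      ),
      max_fold_change = c(damaged = 25, `no-damaged` = 6, `n/a` = 7),
      ppm_peaks = peaks(
        8.19, 0.6, 0.004,
        8.21, 0.6, 0.004
      )
    ),
    metabolite_spec(
      "glutamate", 150, baseline_cv = 0.10,
      rates = rt(
        "ACA", "asphyxia", "damaged", 0.12,
        "ACA", "asphyxia", "no-damaged", -0.02,
        "VFCA", "CPR", "*", 0.07
      ),
      max_fold_change = c(damaged = 6, `no-damaged` = 2, `n/a` = 2),
      ppm_peaks = peaks(
        2.08, 0.4, 0.006,
        2.35, 0.4, 0.006,
        3.75, 0.3, 0.005
      )
    ),
    metabolite_spec(
      "alanine", 300, baseline_cv = 0.10,
      rates = rt(
        "*", "asphyxia", "*", 0.05,
        "VFCA", "CPR", "*", 0.05
      ),
      max_fold_change = c(damaged = 4, `no-damaged` = 3, `n/a` = 2),
      ppm_peaks = peaks(
        1.47, 0.6, 0.004,
        1.49, 0.6, 0.004
      )
    )
  )
  setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Configure a synthetic cardiac-arrest cohort
#'
#' Defines the study design the generator emulates: two groups of animals
#' (asphyxial, `ACA`, and ventricular-fibrillation, `VFCA`, cardiac arrest),
#' per-minute plasma sampling through baseline, a variable asphyxial
#' pre-arrest period (ACA only), five minutes of untreated arrest, a
#' variable CPR phase, and post-resuscitation draws at fixed hours.
#' A fixed fraction of ACA animals is assigned the `damaged` class
#' (deterministic count after a seeded shuffle).
#'
#' @param n_animals_per_group Animals per group (default 10).
#' @param groups Group labels; the first is the asphyxial group carrying
#'   damage classes.
#' @param damaged_fraction_aca Fraction of ACA animals classed `damaged`
#'   (default 0.4, i.e. 4 of 10).
#' @param asphyxia_duration_range Integer minutes `c(min, max)` for the
#'   asphyxial period (default 4-10). Damaged animals draw from the upper
#'   part of the range (at least 7 minutes where the range allows),
#'   mirroring the association between long asphyxia and poor outcome.
#' @param ca_duration Untreated-arrest duration in minutes (default 5).
#' @param cpr_duration_range Integer minutes `c(min, max)` for CPR
#'   (default 2-10).
#' @param post_rosc_hours Hours after ROSC at which samples are drawn;
#'   24 is reported as the terminal `24h` phase.
#' @param metabolite_specs Named list of [metabolite_spec()] objects.
#' @param noise_sd_frac SD of the multiplicative lognormal measurement
#'   noise on the log scale (default 0.05).
#' @param recovery_tau Time constant (minutes) of the post-ROSC exponential
#'   decay of log fold changes back to baseline (default 25, so most
#'   disturbances normalise within the first hour).
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_animals_per_group = 10,
                          groups = c("ACA", "VFCA"),
                          damaged_fraction_aca = 0.4,
                          asphyxia_duration_range = c(4L, 10L),
                          ca_duration = 5L,
                          cpr_duration_range = c(2L, 10L),
                          post_rosc_hours = c(1, 2, 3, 4, 24),
                          metabolite_specs = swine_ca_metabolites(),
                          noise_sd_frac = 0.05,
                          recovery_tau = 25,
                          seed = 1L) {
  if (n_animals_per_group < 1) abort("`n_animals_per_group` must be positive.")
  if (length(groups) < 1) abort("at least one group label is required.")
  if (damaged_fraction_aca < 0 || damaged_fraction_aca > 1) {
    abort("`damaged_fraction_aca` must lie in [0, 1].")
  }
  if (length(asphyxia_duration_range) != 2 || any(asphyxia_duration_range < 1) ||
    asphyxia_duration_range[1] > asphyxia_duration_range[2]) {
    abort("`asphyxia_duration_range` must be an increasing pair of positive minutes.")
  }
  stopifnot_scalar_number(ca_duration, "ca_duration", positive = TRUE)
  if (length(cpr_duration_range) != 2 || any(cpr_duration_range < 1) ||
    cpr_duration_range[1] > cpr_duration_range[2]) {
    abort("`cpr_duration_range` must be an increasing pair of positive minutes.")
  }
  if (length(metabolite_specs) == 0) abort("`metabolite_specs` must not be empty.")
  if (!all(vapply(metabolite_specs, inherits, logical(1), "metabolite_spec"))) {
    abort("`metabolite_specs` must be a list of metabolite_spec objects.")
  }
  if (noise_sd_frac < 0) abort("`noise_sd_frac` must be non-negative.")
  stopifnot_scalar_number(recovery_tau, "recovery_tau", positive = TRUE)
  structure(
    list(
      n_animals_per_group = as.integer(n_animals_per_group),
      groups = as.character(groups),
      damaged_fraction_aca = damaged_fraction_aca,
      asphyxia_duration_range = as.integer(asphyxia_duration_range),
      ca_duration = as.integer(ca_duration),
      cpr_duration_range = as.integer(cpr_duration_range),
      post_rosc_hours = as.numeric(post_rosc_hours),
      metabolite_specs = metabolite_specs,
      noise_sd_frac = noise_sd_frac,
      recovery_tau = recovery_tau,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Per-animal sample timeline; minute_in_phase is within-phase, and
# `decay_time` carries minutes since ROSC for the recovery phases.
animal_timeline <- function(config, has_asphyxia, asphyxia_duration, cpr_duration) {
  rows <- list(tibble(phase = "baseline", minute_in_phase = 0L, decay_time = NA_real_))
  if (has_asphyxia) {
    rows <- c(rows, list(tibble(
      phase = "asphyxia", minute_in_phase = seq_len(asphyxia_duration),
      decay_time = NA_real_
    )))
  }
  rows <- c(rows, list(
    tibble(phase = "CA", minute_in_phase = seq_len(config$ca_duration), decay_time = NA_real_),
    tibble(phase = "CPR", minute_in_phase = seq_len(cpr_duration), decay_time = NA_real_)
  ))
  hrs <- config$post_rosc_hours
  if (length(hrs) > 0) {
    rows <- c(rows, list(tibble(
      phase = ifelse(hrs >= 24, "24h", "post-ROSC"),
      minute_in_phase = as.integer(ifelse(hrs >= 24, 0, hrs * 60)),
      decay_time = hrs * 60
    )))
  }
  bind_rows(rows)
}

# Log fold-change trajectory for one animal x metabolite over its timeline.
# Asphyxial rates are per minute of the nominal (maximal) asphyxial episode:
# an animal arresting earlier progresses proportionally faster, so its
# end-of-asphyxia profile depends on its damage class, not on how long the
# episode happened to last. CA and CPR rates are per real minute.
logfold_trajectory <- function(tl, spec, group, class, asphyxia_duration, config) {
  cap <- log(lookup_cap(spec, class))
  nominal <- config$asphyxia_duration_range[2]
  r_asph <- lookup_rate(spec, group, "asphyxia", class)
  if (asphyxia_duration > 0) r_asph <- r_asph * nominal / asphyxia_duration
  r_ca <- lookup_rate(spec, group, "CA", class)
  r_cpr <- lookup_rate(spec, group, "CPR", class)
  l_asph_end <- if (asphyxia_duration > 0) min(r_asph * asphyxia_duration, cap) else 0
  l_ca_end <- min(l_asph_end + r_ca * config$ca_duration, cap)
  cpr_minutes <- tl$minute_in_phase[tl$phase == "CPR"]
  l_cpr_end <- if (length(cpr_minutes) > 0) {
    min(l_ca_end + r_cpr * max(cpr_minutes), cap)
  } else {
    l_ca_end
  }
  vapply(seq_len(nrow(tl)), function(i) {
    ph <- tl$phase[i]
    m <- tl$minute_in_phase[i]
    switch(ph,
      baseline = 0,
      asphyxia = min(r_asph * m, cap),
      CA = min(l_asph_end + r_ca * m, cap),
      CPR = min(l_ca_end + r_cpr * m, cap),
      l_cpr_end * exp(-tl$decay_time[i] / config$recovery_tau)
    )
  }, numeric(1))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a full longitudinal cohort under the concentration model
#' `y = baseline_animal * g(phase, t; class) * exp(e)`, where `g` is
#' piecewise linear in log concentration (see [metabolite_spec()]),
#' `e ~ Normal(0, noise_sd_frac^2)`, and animal baselines are lognormal
#' around the metabolite mean with an optional additive random intercept.
#' Every drawn parameter is recorded in the returned ground truth so that
#' downstream estimators can be tested for recovery.
#'
#' @param config A [cohort_config()].
#' @return A list of class `ca_cohort` with
#'   * `quant`: tibble, one row per sample, `sample_id` plus one
#'     concentration column (umol/L) per metabolite;
#'   * `metadata`: tibble with `sample_id`, `animal_id`, `group`,
#'     `damage_class`, `phase`, `minute_in_phase`;
#'   * `truth`: list recording the config, per-animal damage classes and
#'     phase durations, drawn baselines, and the noiseless trajectory of
#'     every sample x metabolite.
#' @examples
#' cfg <- cohort_config(n_animals_per_group = 2, seed = 7)
#' cohort <- generate_cohort(cfg)
#' head(cohort$metadata)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  specs <- config$metabolite_specs
  met_names <- vapply(specs, `[[`, character(1), "name")

  aca_group <- config$groups[1]
  animals <- list()
  for (g in config$groups) {
    ids <- sprintf("%s%02d", g, seq_len(config$n_animals_per_group))
    cls <- rep("n/a", length(ids))
    if (g == aca_group) {
      n_dam <- round(config$damaged_fraction_aca * length(ids))
      shuffled <- sample(length(ids))
      cls <- rep("no-damaged", length(ids))
      if (n_dam > 0) cls[shuffled[seq_len(n_dam)]] <- "damaged"
    }
    d_asph <- if (g == aca_group) {
      # Damaged animals draw from the upper part (>= 7 min) of the range,
      # reflecting the association between long asphyxia and poor outcome.
      lo <- config$asphyxia_duration_range[1]
      hi <- config$asphyxia_duration_range[2]
      lo_dam <- max(lo, min(7L, hi))
      ifelse(cls == "damaged",
        sample_from(seq(lo_dam, hi), length(ids)),
        sample_from(seq(lo, hi), length(ids))
      )
    } else {
      rep(0L, length(ids))
    }
    d_cpr <- sample_from(
      seq(config$cpr_duration_range[1], config$cpr_duration_range[2]),
      length(ids)
    )
    animals[[g]] <- tibble(
      animal_id = ids, group = g, damage_class = cls,
      asphyxia_duration = as.integer(d_asph), cpr_duration = as.integer(d_cpr)
    )
  }
  animals <- bind_rows(animals)

  # Animal baselines: lognormal around the mean (median-preserving on the
  # log scale when cv > 0) plus an optional additive intercept.
  baselines <- lapply(seq_len(nrow(animals)), function(i) {
    vapply(specs, function(sp) {
      sdlog <- sqrt(log(1 + sp$baseline_cv^2))
      b <- if (sdlog > 0) {
        rlnorm(1, meanlog = log(sp$baseline_mean) - sdlog^2 / 2, sdlog = sdlog)
      } else {
        sp$baseline_mean
      }
      if (sp$animal_intercept_sd > 0) b <- b + rnorm(1, 0, sp$animal_intercept_sd)
      max(b, .Machine$double.eps)
    }, numeric(1))
  })
  baselines <- do.call(rbind, baselines)
  dimnames(baselines) <- list(animals$animal_id, met_names)

  meta_rows <- list()
  traj_rows <- list()
  for (i in seq_len(nrow(animals))) {
    a <- animals[i, ]
    tl <- animal_timeline(config, a$asphyxia_duration > 0, a$asphyxia_duration, a$cpr_duration)
    sample_id <- sprintf("%s_%s_%02d", a$animal_id, tl$phase, tl$minute_in_phase)
    meta_rows[[i]] <- tibble(
      sample_id = sample_id, animal_id = a$animal_id, group = a$group,
      damage_class = a$damage_class, phase = tl$phase,
      minute_in_phase = tl$minute_in_phase
    )
    lf <- vapply(specs, function(sp) {
      logfold_trajectory(tl, sp, a$group, a$damage_class, a$asphyxia_duration, config)
    }, numeric(nrow(tl)))
    if (nrow(tl) == 1) lf <- matrix(lf, nrow = 1)
    noiseless <- sweep(exp(lf), 2, baselines[a$animal_id, ], "*")
    traj_rows[[i]] <- list(sample_id = sample_id, logfold = lf, noiseless = noiseless)
  }
  metadata <- bind_rows(meta_rows)
  noiseless <- do.call(rbind, lapply(traj_rows, `[[`, "noiseless"))
  logfold <- do.call(rbind, lapply(traj_rows, `[[`, "logfold"))
  colnames(noiseless) <- colnames(logfold) <- met_names

  eps <- matrix(rnorm(length(noiseless), 0, config$noise_sd_frac),
    nrow = nrow(noiseless)
  )
  conc <- noiseless * exp(eps)
  quant <- bind_cols(tibble(sample_id = metadata$sample_id), as_tibble(conc))

  truth <- list(
    config = config,
    animals = animals,
    baselines = as_tibble(baselines, rownames = "animal_id"),
    trajectories = bind_cols(
      tibble(sample_id = metadata$sample_id),
      as_tibble(logfold) |> rename_with(~ paste0("logfold_", .x)),
      as_tibble(noiseless) |> rename_with(~ paste0("noiseless_", .x))
    )
  )
  structure(list(quant = quant, metadata = metadata, truth = truth),
    class = "ca_cohort"
  )
}

#' @export
print.ca_cohort <- function(x, ...) {
  cat(sprintf(
    "<ca_cohort> %d samples, %d animals (%s), %d metabolites\n",
    nrow(x$quant), nrow(x$truth$animals),
    paste(unique(x$metadata$group), collapse = "/"),
    ncol(x$quant) - 1
  ))
  invisible(x)
}
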