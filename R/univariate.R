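# Longitudinal univariate statistics: mixed-effects models, exact rank
# tests, fold changes and FDR q-values.

#' Linear mixed-effects model for one metabolite
#'
#' Fits `value ~ time + group (+ time:group) + (1 | animal)` by restricted
#' maximum likelihood — the model for longitudinal metabolite
#' concentrations where repeated measurements on the same animal are
#' correlated. P-values are Wald tests with Satterthwaite degrees of
#' freedom (via lmerTest). The reported R2 is the squared correlation
#' between fitted and observed values, and the group coding is treatment
#' contrasts with the alphabetically first level as reference (recorded in
#' the output). If the mixed model cannot be estimated (for example
#' noiseless data with no animal effect), the fitter falls back to an
#' ordinary least-squares fit with zero random-intercept variance.
#'
#' @param data Data frame, one row per observation.
#' @param response,time,group,animal Column names (strings).
#' @param include_interaction Include the `time:group` term (default TRUE).
#' @return An object of class `mixed_model_fit`; see [tidy()] / [glance()].
#' @export
fit_mixed_model <- function(data, response = "value", time = "minute",
                            group = "group", animal = "animal_id",
                            include_interaction = TRUE) {
  stopifnot(is.data.frame(data))
  for (col in c(response, time, group, animal)) {
    if (!col %in% names(data)) abort(sprintf("column `%s` not found.", col))
  }
  d <- tibble(
    value = as.numeric(data[[response]]),
    time = as.numeric(data[[time]]),
    group = factor(as.character(data[[group]])),
    animal = factor(as.character(data[[animal]]))
  )
  d <- d[complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$group)) < 1 || var(d$time) == 0 && nlevels(droplevels(d$group)) < 2) {
    abort("singular design: need time variation or at least two groups.")
  }
  per_group <- table(unique(d[c("group", "animal")])$group)
  if (any(per_group < 2)) {
    abort("each group needs at least 2 animals.")
  }
  fixed <- if (include_interaction) "value ~ time * group" else "value ~ time + group"
  form <- as.formula(paste(fixed, "+ (1 | animal)"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = d, REML = TRUE)
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    ols <- lm(as.formula(fixed), data = d)
    cf <- summary(ols)$coefficients
    coefs <- tibble(
      term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
      df = ols$df.residual, p_value = cf[, 4]
    )
    var_b <- 0
    var_e <- summary(ols)$sigma^2
    fitted_vals <- fitted(ols)
    engine <- "ols_fallback"
  } else {
    cf <- coef(summary(fit))
    coefs <- tibble(
      term = rownames(cf), estimate = cf[, "Estimate"],
      std_error = cf[, "Std. Error"], df = cf[, "df"],
      p_value = cf[, "Pr(>|t|)"]
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_b <- vc$vcov[vc$grp == "animal"]
    var_e <- vc$vcov[vc$grp == "Residual"]
    fitted_vals <- fitted(fit)
    engine <- "lmer_reml"
  }
  structure(
    list(
      coefficients = coefs,
      includes_interaction = include_interaction,
      random_intercept_variance = var_b,
      residual_variance = var_e,
      r2 = cor(fitted_vals, d$value)^2,
      r2_definition = "squared correlation of fitted vs observed",
      n_animals = nlevels(droplevels(d$animal)),
      n_obs = nrow(d),
      reference_level = levels(droplevels(d$group))[1],
      engine = engine,
      fit = if (engine == "lmer_reml") fit else NULL
    ),
    class = "mixed_model_fit"
  )
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf(
    "<mixed_model_fit> %s, %d obs / %d animals, R2 = %.3f (reference group: %s)\n",
    if (x$includes_interaction) "time * group" else "time + group",
    x$n_obs, x$n_animals, x$r2, x$reference_level
  ))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.mixed_model_fit <- function(x, ...) {
  x$coefficients
}

#' @export
glance.mixed_model_fit <- function(x, ...) {
  tibble(
    r2 = x$r2,
    random_intercept_variance = x$random_intercept_variance,
    residual_variance = x$residual_variance,
    n_animals = x$n_animals, n_obs = x$n_obs,
    includes_interaction = x$includes_interaction,
    engine = x$engine
  )
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired differences. Zero differences are dropped
#' (Wilcoxon's original policy) and absolute differences are mid-ranked on
#' ties. With `n <= 25` informative pairs the p-value is exact — the null
#' distribution of V over all 2^n sign assignments of the (possibly
#' mid-ranked) ranks, computed by convolution; above that the normal
#' approximation with continuity and tie correction is used.
#'
#' @param before,after Numeric vectors of equal length (>= 2).
#' @return A list with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n` (informative pairs) and `method`.
#' @examples
#' wilcoxon_paired(c(1, 2, 3, 4, 5), c(2, 3, 5, 6, 9))$p_value # 2/32
#' @export
wilcoxon_paired <- function(before, after) {
  if (length(before) != length(after)) abort("`before` and `after` must have equal length.")
  if (length(before) < 2) abort("need at least 2 pairs.")
  d <- as.numeric(after) - as.numeric(before)
  d <- d[d != 0]
  if (length(d) == 0) abort("all differences are zero; no information.")
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 25) {
    # Exact null of V over all 2^n sign assignments (ranks doubled so
    # mid-ranks stay on an integer grid), by polynomial convolution.
    r2 <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(r2)))
    for (rr in r2) {
      shifted <- c(rep(0, rr), counts[seq_len(length(counts) - rr)])
      counts <- counts + shifted
    }
    total <- 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(counts[seq_len(v2 + 1)]) / total
    p_ge <- sum(counts[seq(v2 + 1, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    ties <- any(duplicated(abs(d)))
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    if (v == mu) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Mann-Whitney U test
#'
#' Two-sided unpaired rank test for a between-group comparison. Without
#' ties and with `n_a + n_b <= 20` the p-value is exact; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#' The reported U counts pairs won by `group_a` (ties count one half).
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A list with `statistic` (U), `p_value` and `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value # 2 / choose(6, 3) = 0.1
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty.")
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  mu <- na * nb / 2
  if (!ties && na + nb <= 20) {
    p <- if (u > mu) {
      2 * (1 - pwilcox(u - 1, na, nb))
    } else {
      2 * pwilcox(u, na, nb)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    nn <- na + nb
    tie_tab <- table(pooled)
    sigma2 <- na * nb / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    z <- if (sigma2 > 0) (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2) else 0
    if (u == mu) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Per-animal fold changes between two timepoints
#'
#' Computes, per metabolite and animal, the relative increase
#' `FC = (x_to - x_from) / x_from` between two sampled points, then
#' summarises mean, minimum and maximum across animals. An animal with a
#' non-positive starting value is excluded with a warning. Selector
#' strings `"first"` / `"last"` pick the extreme minute within the phase
#' per animal; a number picks that minute exactly.
#'
#' @param quant Wide concentration tibble (`sample_id` + metabolites).
#' @param metadata Sample metadata with `sample_id`, `animal_id`, `group`,
#'   `phase`, `minute_in_phase`.
#' @param from_phase,to_phase Phase labels of the two points.
#' @param from_minute,to_minute `"first"`, `"last"` or a minute number.
#' @param group Optional group label to restrict to.
#' @param definition `"relative_increase"` (default) or `"ratio"`
#'   (`x_to / x_from`).
#' @return A tibble with `metabolite`, `mean_fc`, `min_fc`, `max_fc`, `n`.
#' @export
fold_changes <- function(quant, metadata, from_phase, to_phase,
                         from_minute = "first", to_minute = "last",
                         group = NULL,
                         definition = c("relative_increase", "ratio")) {
  definition <- match.arg(definition)
  paired <- pair_timepoints(quant, metadata, from_phase, to_phase,
    from_minute, to_minute,
    group = group
  )
  fc_fun <- function(from, to) {
    if (definition == "relative_increase") (to - from) / from else to / from
  }
  bad <- paired |>
    filter(.data$from_value <= 0) |>
    distinct(.data$animal_id)
  if (nrow(bad) > 0) {
    warn(sprintf(
      "animal(s) excluded for non-positive starting value: %s",
      paste(bad$animal_id, collapse = ", ")
    ))
  }
  paired |>
    filter(.data$from_value > 0) |>
    mutate(fc = fc_fun(.data$from_value, .data$to_value)) |>
    group_by(.data$metabolite) |>
    summarise(
      mean_fc = mean(.data$fc), min_fc = min(.data$fc),
      max_fc = max(.data$fc), n = n(), .groups = "drop"
    )
}

# Long table of per-animal (from, to) value pairs for every metabolite.
pair_timepoints <- function(quant, metadata, from_phase, to_phase,
                            from_minute, to_minute, group = NULL) {
  for (col in c("sample_id", "animal_id", "phase", "minute_in_phase")) {
    if (!col %in% names(metadata)) abort(sprintf("metadata lacks column `%s`.", col))
  }
  md <- as_tibble(metadata)
  if (!is.null(group)) md <- filter(md, .data$group == !!group)
  pick <- function(ph, minute) {
    sub <- filter(md, .data$phase == ph)
    if (nrow(sub) == 0) abort(sprintf("no samples in phase `%s`.", ph))
    if (identical(minute, "first")) {
      sub <- sub |>
        group_by(.data$animal_id) |>
        slice_min(.data$minute_in_phase, n = 1, with_ties = FALSE) |>
        ungroup()
    } else if (identical(minute, "last")) {
      sub <- sub |>
        group_by(.data$animal_id) |>
        slice_max(.data$minute_in_phase, n = 1, with_ties = FALSE) |>
        ungroup()
    } else {
      sub <- filter(sub, .data$minute_in_phase == as.numeric(minute))
    }
    sub
  }
  from_md <- pick(from_phase, from_minute)
  to_md <- pick(to_phase, to_minute)
  animals <- intersect(from_md$animal_id, to_md$animal_id)
  if (length(animals) == 0) abort("no animal has both timepoints.")
  mets <- setdiff(names(quant), "sample_id")
  long <- quant |>
    tidyr::pivot_longer(all_of(mets), names_to = "metabolite", values_to = "value")
  from_vals <- from_md |>
    filter(.data$animal_id %in% animals) |>
    select("sample_id", "animal_id") |>
    inner_join(long, by = "sample_id") |>
    select("animal_id", "metabolite", from_value = "value")
  to_vals <- to_md |>
    filter(.data$animal_id %in% animals) |>
    select("sample_id", "animal_id") |>
    inner_join(long, by = "sample_id") |>
    select("animal_id", "metabolite", to_value = "value")
  inner_join(from_vals, to_vals, by = c("animal_id", "metabolite"))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment,
#' `q_(i) = min over j >= i of p_(j) * m / j`, clipped at 1 and mapped back
#' to the input order. Inputs outside (0, 1] are an error.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @examples
#' fdr_qvalues(c(0.01, 0.02, 0.03, 0.5))
#' @export
fdr_qvalues <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Paired effect table between two timepoints
#'
#' For each metabolite: paired Wilcoxon signed-rank p-value between the two
#' timepoints across animals, Benjamini-Hochberg q-value across
#' metabolites, mean/min/max fold change, and the direction of the mean
#' change — the within-group summary of what changed during a phase.
#'
#' @inheritParams fold_changes
#' @return A tibble with `metabolite`, `p_value`, `q_value`, `mean_fc`,
#'   `min_fc`, `max_fc`, `direction`, `n` and `test`.
#' @export
paired_effect_table <- function(quant, metadata, from_phase, to_phase,
                                from_minute = "first", to_minute = "last",
                                group = NULL,
                                definition = c("relative_increase", "ratio")) {
  definition <- match.arg(definition)
  paired <- pair_timepoints(quant, metadata, from_phase, to_phase,
    from_minute, to_minute,
    group = group
  )
  tests <- paired |>
    group_by(.data$metabolite) |>
    summarise(
      p_value = wilcoxon_paired(.data$from_value, .data$to_value)$p_value,
      .groups = "drop"
    )
  fcs <- fold_changes(quant, metadata, from_phase, to_phase,
    from_minute, to_minute,
    group = group, definition = definition
  )
  tests |>
    inner_join(fcs, by = "metabolite") |>
    mutate(
      q_value = fdr_qvalues(.data$p_value),
      direction = ifelse(.data$mean_fc >= ifelse(definition == "ratio", 1, 0), "up", "down"),
      test = "paired_wilcoxon"
    ) |>
    select(
      "metabolite", "p_value", "q_value", "mean_fc", "min_fc", "max_fc",
      "direction", "n", "test"
    ) |>
    arrange(.data$p_value)
}
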