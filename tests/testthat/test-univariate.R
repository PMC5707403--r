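# Mixed-effects fits, exact rank tests, fold changes and q-values.

test_that("all-positive differences at n = 5 force the exact p = 2/32", {
  out <- wilcoxon_paired(c(1, 2, 3, 4, 5), c(2, 3, 5, 6, 9))
  expect_equal(out$p_value, 0.0625)
  expect_equal(out$statistic, 15)
  expect_equal(out$method, "exact")
})

test_that("the signed-rank test equals full enumeration, ties included", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    before <- rnorm(n)
    after <- if (rep %% 3 == 0) {
      before + sample(c(-2, -1, 1, 2), n, replace = TRUE) # forced ties
    } else {
      before + rnorm(n)
    }
    expect_equal(
      wilcoxon_paired(before, after)$p_value,
      enum_signrank_p(before, after),
      tolerance = 1e-12
    )
  }
  expect_error(wilcoxon_paired(c(1, 2), c(1, 2)), "zero")
})

test_that("extreme arrangements give the closed-form Mann-Whitney p", {
  out <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 2 / choose(6, 3))
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("the Mann-Whitney test equals full enumeration on random data", {
  set.seed(2)
  for (rep in 1:10) {
    a <- rnorm(8)
    b <- rnorm(7, mean = rep %% 3)
    expect_equal(
      mann_whitney(a, b)$p_value,
      enum_mannwhitney_p(a, b),
      tolerance = 1e-12
    )
  }
})

test_that("symmetric null keeps the signed-rank size near its level", {
  set.seed(3)
  rejections <- 0
  n_runs <- 400
  for (i in seq_len(n_runs)) {
    d <- rnorm(12)
    if (wilcoxon_paired(rep(0, 12), d)$p_value <= 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_runs
  # Exact test is conservative-discrete; binomial band around 0.05.
  expect_gte(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / n_runs) - 0.01)
  expect_lte(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / n_runs))
})

test_that("BH q-values match the hand-applied step-up formula", {
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_qvalues(0.2), 0.2)
  expect_equal(fdr_qvalues(rep(0.3, 5)), rep(0.3, 5))
  set.seed(4)
  p <- runif(20)
  q <- fdr_qvalues(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(fdr_qvalues(c(0.1, 0)), "0, 1")
  expect_error(fdr_qvalues(c(0.1, 1.2)), "0, 1")
})

test_that("noiseless data are interpolated exactly by the mixed model", {
  d <- expand.grid(minute = 1:5, animal_id = sprintf("A%d", 1:6))
  d$group <- ifelse(as.integer(factor(d$animal_id)) <= 3, "g1", "g2")
  g <- as.numeric(d$group == "g2")
  d$value <- 1 + 2 * d$minute + 3 * g + 4 * d$minute * g
  fit <- fit_mixed_model(d, response = "value", time = "minute")
  est <- tidy(fit)$estimate
  expect_equal(est, c(1, 2, 3, 4), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("mixed-model estimates are invariant to relabeling and time origin", {
  set.seed(5)
  d <- expand.grid(minute = 1:8, animal_id = sprintf("A%d", 1:8))
  d$group <- ifelse(as.integer(factor(d$animal_id)) <= 4, "g1", "g2")
  g <- as.numeric(d$group == "g2")
  b_i <- rnorm(8, 0, 0.5)[as.integer(factor(d$animal_id))]
  d$value <- 1 + 0.5 * d$minute + 0.8 * g + 0.3 * d$minute * g + b_i + rnorm(nrow(d), 0, 0.2)
  fit1 <- fit_mixed_model(d, time = "minute")
  d2 <- d
  d2$animal_id <- sprintf("Z%s", rev(as.integer(factor(d$animal_id))))
  fit2 <- fit_mixed_model(d2, time = "minute")
  expect_equal(tidy(fit1)$estimate, tidy(fit2)$estimate, tolerance = 1e-6)
  d3 <- d
  d3$minute <- d3$minute + 100
  fit3 <- fit_mixed_model(d3, time = "minute")
  slopes <- function(f) tidy(f)$estimate[c(2, 4)]
  expect_equal(slopes(fit1), slopes(fit3), tolerance = 1e-6)
})

test_that("dropping the interaction changes the terms, not the story", {
  set.seed(6)
  d <- expand.grid(minute = 1:6, animal_id = sprintf("A%d", 1:8))
  d$group <- ifelse(as.integer(factor(d$animal_id)) <= 4, "g1", "g2")
  g <- as.numeric(d$group == "g2")
  d$value <- 1 + 0.5 * d$minute + 0.8 * g +
    rnorm(8, 0, 0.3)[as.integer(factor(d$animal_id))] + rnorm(nrow(d), 0, 0.2)
  with_int <- fit_mixed_model(d, time = "minute", include_interaction = TRUE)
  without <- fit_mixed_model(d, time = "minute", include_interaction = FALSE)
  expect_false(any(grepl(":", tidy(without)$term)))
  expect_true(any(grepl(":", tidy(with_int)$term)))
  expect_equal(
    tidy(without)$estimate[2],
    tidy(with_int)$estimate[2],
    tolerance = 0.2
  )
  expect_false(without$includes_interaction)
})

test_that("fold changes follow the relative-increase definition", {
  quant <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    met = c(2, 6, 5, 5)
  )
  metadata <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    animal_id = c("a1", "a1", "a2", "a2"),
    group = "G", phase = c("CPR", "CPR", "CPR", "CPR"),
    minute_in_phase = c(1, 5, 1, 5)
  )
  fc <- fold_changes(quant, metadata, "CPR", "CPR")
  expect_equal(fc$mean_fc, mean(c(2, 0))) # (6-2)/2 = 2; (5-5)/5 = 0
  expect_equal(fc$min_fc, 0)
  expect_equal(fc$max_fc, 2)
  ratio <- fold_changes(quant, metadata, "CPR", "CPR", definition = "ratio")
  expect_equal(ratio$mean_fc, mean(c(3, 1)))
})

test_that("a programmed noiseless increase yields the exact mean fold change", {
  spec <- metabolite_spec("m", 10,
    rates = data.frame(group = "ACA", phase = "asphyxia", class = "*", rate = log(5) / 6)
  )
  cfg <- cohort_config(
    n_animals_per_group = 4, groups = "ACA", damaged_fraction_aca = 0,
    asphyxia_duration_range = c(6, 6), metabolite_specs = list(m = spec),
    noise_sd_frac = 0, seed = 8
  )
  co <- generate_cohort(cfg)
  fc <- fold_changes(co$quant, co$metadata, "baseline", "asphyxia")
  expect_equal(fc$mean_fc, 4, tolerance = 1e-9) # (5x - x) / x
})

test_that("non-positive starting values exclude the animal with a warning", {
  quant <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"), met = c(0, 6, 2, 4))
  metadata <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    animal_id = c("a1", "a1", "a2", "a2"),
    group = "G", phase = "CPR", minute_in_phase = c(1, 5, 1, 5)
  )
  expect_warning(fc <- fold_changes(quant, metadata, "CPR", "CPR"), "a1")
  expect_equal(fc$n, 1)
  expect_equal(fc$mean_fc, 1)
})

test_that("the paired effect table mirrors its inputs coherently", {
  co <- tiny_cohort(seed = 10, n = 4)
  tab <- paired_effect_table(co$quant, co$metadata, "CPR", "CPR", group = "VFCA")
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))
  expect_true(all(tab$min_fc <= tab$mean_fc & tab$mean_fc <= tab$max_fc))
  expect_setequal(tab$metabolite, setdiff(names(co$quant), "sample_id"))
  # Succinate accumulates during CPR in the dysrhythmic group.
  expect_equal(tab$direction[tab$metabolite == "succinate"], "up")
})
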