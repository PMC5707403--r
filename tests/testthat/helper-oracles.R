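# Independent oracles and small data generators used across the suite.

# Seeded random matrix, column-scaled.
rand_scaled <- function(n, p, seed, method = "mean_center") {
  set.seed(seed)
  suppressWarnings(scale_features(matrix(rnorm(n * p), n, p), method))$x
}

# Two-class data with a handful of informative variables.
two_class_data <- function(n_per = 10, p = 8, shift = 2, n_inform = 3,
                           noise = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p, 0, noise), 2 * n_per, p)
  cls <- rep(c(1, -1), each = n_per)
  x[, seq_len(n_inform)] <- x[, seq_len(n_inform)] +
    outer(cls, rep(shift / 2, n_inform))
  list(x = x, y = cls)
}

# Brute-force two-sided signed-rank p over all 2^n sign assignments
# (mid-ranks on tied absolute differences, zeros dropped).
enum_signrank_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force two-sided Mann-Whitney p over all choose(n, n_a) group
# assignments (assumes no ties).
enum_mannwhitney_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(i) sum(r[i])) - na * (na + 1) / 2
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Align the sign of each column of `a` to the matching column of `b`
# (latent-variable solutions are sign-indeterminate).
sign_align <- function(a, b) {
  for (j in seq_len(ncol(a))) {
    if (sum(a[, j] * b[, j]) < 0) a[, j] <- -a[, j]
  }
  a
}

# Tiny cohort for pipeline-level tests.
tiny_cohort <- function(seed = 1, n = 3, noise = 0.05) {
  generate_cohort(cohort_config(
    n_animals_per_group = n, damaged_fraction_aca = 0.5,
    noise_sd_frac = noise, seed = seed
  ))
}

# Reference/test trajectory simulator for BSPC tests: p feature columns,
# each linear in time plus iid Gaussian noise. Shifted animals behave as
# if they were `shift` minutes ahead from `shift_from` onwards.
bspc_sim <- function(n_ref, n_test = 0, shift = 0, shift_from = 6,
                     noise_sd = 0.5, seed = 1, p = 5, times = 1:10) {
  set.seed(seed)
  slope <- runif(p, 0.5, 1.5)
  icpt <- runif(p, -1, 1)
  gen <- function(t_eff) {
    vapply(seq_len(p), function(j) {
      slope[j] * t_eff + icpt[j] + rnorm(length(t_eff), 0, noise_sd)
    }, numeric(length(t_eff)))
  }
  ids <- c(
    sprintf("REF%03d", seq_len(n_ref)),
    if (n_test > 0) sprintf("TST%03d", seq_len(n_test))
  )
  rows <- lapply(ids, function(id) {
    t_eff <- times
    if (grepl("^TST", id)) {
      t_eff <- ifelse(times >= shift_from, times + shift, times)
    }
    list(
      md = tibble::tibble(animal_id = id, time = times),
      x = gen(t_eff)
    )
  })
  list(
    md = dplyr::bind_rows(lapply(rows, `[[`, "md")),
    x = do.call(rbind, lapply(rows, `[[`, "x")),
    reference = ids[grepl("^REF", ids)],
    test = ids[grepl("^TST", ids)]
  )
}
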