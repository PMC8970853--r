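test_that("same config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_patients = 6, t_range = c(10L, 30L), seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$profiles, b$cohort$profiles)
  expect_identical(a$cohort$series, b$cohort$series)
  expect_identical(a$truth, b$truth)
})

test_that("patient i's data is invariant to n_patients", {
  small <- generate_cohort(cohort_config(n_patients = 3, seed = 9,
                                         t_range = c(5L, 15L)))
  large <- generate_cohort(cohort_config(n_patients = 10, seed = 9,
                                         t_range = c(5L, 15L)))
  sel <- function(df) df[df$patient_id %in% sprintf("P%05d", 1:3), ]
  expect_equal(small$cohort$series, sel(large$cohort$series),
               ignore_attr = "row.names")
  expect_equal(small$truth$params, sel(large$truth$params),
               ignore_attr = "row.names")
})

test_that("n_patients = 0 yields an empty cohort with a valid schema", {
  g <- generate_cohort(cohort_config(n_patients = 0, seed = 1))
  expect_s3_class(g$cohort, "icu_cohort")
  expect_identical(nrow(g$cohort$profiles), 0L)
  expect_true(all(c("map", "lactate", "drug_present") %in%
                    names(g$cohort$series)))
  expect_identical(nrow(g$truth$params), 0L)
})

test_that("zero effects and zero noise reproduce the baselines exactly", {
  cfg <- cohort_config(n_patients = 4, t_range = c(5L, 9L),
                       mu_noise_sd = 0, sigma_log_noise_sd = 0, seed = 2)
  tp <- generate_cohort(cfg)$truth$params
  for (i in seq_len(nrow(tp))) {
    k <- match(tp$variable[i], cfg$monitored_vars)
    expect_identical(tp$mu_true[i], unname(cfg$state_means[k, tp$state[i]]))
    expect_identical(tp$sigma_true[i], unname(cfg$state_sds[k, tp$state[i]]))
  }
})

test_that("simulated sex frequency matches the Bernoulli oracle", {
  n <- 10000L
  g <- generate_cohort(cohort_config(n_patients = n, t_range = c(2L, 2L),
                                     seed = 5))
  # binomial standard error oracle: |p_hat - 0.5| < 3 * sqrt(0.25 / n)
  expect_lt(abs(mean(g$cohort$profiles$sex) - 0.5), 3 * sqrt(0.25 / n))
  expect_equal(g$cohort$profiles$bmi,
               g$cohort$profiles$weight / g$cohort$profiles$height^2)
})

test_that("series lengths and time indices obey the configured range", {
  g <- generate_cohort(cohort_config(n_patients = 12, t_range = c(4L, 8L),
                                     seed = 3))
  for (d in split(g$cohort$series, g$cohort$series$patient_id)) {
    expect_identical(d$time, seq_len(nrow(d)))
    expect_gte(nrow(d), 4L)
    expect_lte(nrow(d), 8L)
  }
  expect_identical(nrow(g$truth$states), nrow(g$cohort$series))
})

test_that("per-state sample means converge to the true mu", {
  g <- generate_cohort(cohort_config(n_patients = 1, t_range = c(4000L, 4000L),
                                     seed = 8))
  s <- merge(g$cohort$series, g$truth$states)
  tp <- g$truth$params
  for (i in seq_len(nrow(tp))) {
    x <- s[s$state == tp$state[i], tp$variable[i]]
    se <- tp$sigma_true[i] / sqrt(length(x))
    expect_lt(abs(mean(x) - tp$mu_true[i]), 4 * se)
  }
})

test_that("invalid configs raise errors naming the offending field", {
  expect_error(cohort_config(t_range = c(1L, 5L)), "t_range")
  expect_error(cohort_config(initial_probs = c(0.6, 0.6)), "initial_probs")
  expect_error(cohort_config(state_sds = matrix(c(1, -1, 1, 1), 2, 2)),
               "state_sds")
  expect_error(cohort_config(monitored_vars = c("heart_rate")),
               "monitored_vars")
  expect_error(cohort_config(
    covariate_effects = data.frame(variable = "nope", state = 1,
                                   parameter = "mu", covariate = "sex",
                                   effect = 1)), "covariate_effects")
})

test_that("well-separated MAP states make the rule track the hidden state", {
  cfg <- cohort_config(n_patients = 15, t_range = c(30L, 60L), seed = 21)
  g <- generate_cohort(cfg)
  # Gaussian tail oracle: P(MAP<=65 | failure) = pnorm((65-55)/5) ~ 0.977,
  # P(MAP<=65 | safe) = pnorm((65-85)/5) ~ 3e-5, so agreement must be high
  expect_gt(rule_state_agreement(g$cohort, g$truth), 0.9)
})

test_that("identical MAP distributions degrade agreement to the state marginal", {
  cfg <- cohort_config(
    n_patients = 10, t_range = c(50L, 100L), seed = 13,
    state_means = matrix(c(96, 87, 85, 85), 2, 2, byrow = TRUE),
    state_sds = matrix(c(10, 9, 5, 5), 2, 2, byrow = TRUE),
    transition_stay_prob = c(0.8, 0.95),
    lactate_params = list(meanlog = c(log(1), log(1)), sdlog = c(0.1, 0.1)),
    drug_prob_by_state = c(0, 0))
  g <- generate_cohort(cfg)
  # no failure signal at all: every label is safe, so agreement equals
  # the fraction of time spent in the safe state (here the larger one)
  agree <- rule_state_agreement(g$cohort, g$truth)
  expect_identical(agree, mean(g$truth$states$state == 2L))
  expect_gt(agree, 0.5)
})

test_that("near-deterministic separated MAP gives perfect agreement", {
  cfg <- cohort_config(
    n_patients = 5, t_range = c(20L, 40L), seed = 4,
    state_means = matrix(c(96, 87, 60, 80), 2, 2, byrow = TRUE),
    state_sds = matrix(c(10, 9, 1e-9, 1e-9), 2, 2, byrow = TRUE),
    mu_noise_sd = 0, sigma_log_noise_sd = 0,
    lactate_params = list(meanlog = c(log(1), log(1)), sdlog = c(0.1, 0.1)),
    drug_prob_by_state = c(0, 0))
  g <- generate_cohort(cfg)
  expect_identical(rule_state_agreement(g$cohort, g$truth), 1)
})
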