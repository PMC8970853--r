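#' Generate a seeded synthetic ICU cohort
#'
#' Simulates a cohort with the statistical structure the pipeline assumes:
#' covariates drawn per patient (sex Bernoulli; age, weight, height
#' truncated normal; BMI derived as weight/height^2), per-patient true
#' emission parameters linear in the covariates, a first-order Markov
#' hidden-state path, Gaussian observations independent across variables
#' given the state, and state-dependent lactate / drug-indicator channels
#' so the circulatory-failure rule correlates with the hidden state.
#'
#' Each patient i draws from a substream seeded deterministically from
#' `config$seed` and i, so patient i's data does not depend on
#' `n_patients` and the same config + seed reproduces the cohort exactly.
#'
#' @param config a [cohort_config()].
#' @return a list with elements `cohort` (class `icu_cohort`: `profiles`,
#'   `series`, `labels = NULL`) and `truth` (class `icu_truth`: `states`
#'   with the true per-time state path and `params` with the true
#'   `mu_true` / `sigma_true` per patient x variable x state).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  N <- config$n_patients
  vars <- config$monitored_vars
  K <- length(vars)
  S <- config$n_states

  trans <- transition_from_stay(config$transition_stay_prob)

  profiles <- vector("list", N)
  series <- vector("list", N)
  states <- vector("list", N)
  params <- vector("list", N)

  for (i in seq_len(N)) {
    set.seed(patient_seed(config$seed, i))
    pid <- sprintf("P%05d", i)

    cov <- draw_covariates(config$covariate_dists)
    profiles[[i]] <- data.frame(patient_id = pid, sex = cov["sex"],
                                age = cov["age"], weight = cov["weight"],
                                height = cov["height"], bmi = cov["bmi"],
                                row.names = NULL)

    tp <- true_patient_params(config, cov)   # list(mu, sigma): K x S
    params[[i]] <- data.frame(
      patient_id = pid,
      variable = rep(vars, times = S),
      state = rep(seq_len(S), each = K),
      mu_true = as.vector(tp$mu),
      sigma_true = as.vector(tp$sigma),
      row.names = NULL)

    tvals <- seq.int(config$t_range[1], config$t_range[2])
    Tn <- tvals[sample.int(length(tvals), 1L)]
    path <- simulate_markov_path(Tn, config$initial_probs, trans)
    states[[i]] <- data.frame(patient_id = pid, time = seq_len(Tn),
                              state = path, row.names = NULL)

    obs <- matrix(rnorm(Tn * K,
                        mean = t(tp$mu[, path, drop = FALSE]),
                        sd = t(tp$sigma[, path, drop = FALSE])),
                  nrow = Tn, ncol = K, dimnames = list(NULL, vars))
    df <- data.frame(patient_id = pid, time = seq_len(Tn), obs,
                     check.names = FALSE, row.names = NULL)
    if (config$label_channels) {
      df$lactate <- rlnorm(Tn, config$lactate_params$meanlog[path],
                           config$lactate_params$sdlog[path])
      df$drug_present <- rbinom(Tn, 1L, config$drug_prob_by_state[path])
    }
    series[[i]] <- df
  }

  cohort <- new_cohort(
    profiles = bind_or_empty(profiles, empty_profiles()),
    series = bind_or_empty(series, empty_series(vars, config$label_channels)))
  truth <- structure(list(
    states = bind_or_empty(states, data.frame(patient_id = character(),
                                              time = integer(),
                                              state = integer())),
    params = bind_or_empty(params, data.frame(patient_id = character(),
                                              variable = character(),
                                              state = integer(),
                                              mu_true = numeric(),
                                              sigma_true = numeric()))),
    class = "icu_truth")
  list(cohort = cohort, truth = truth)
}

# substream seed for patient i; kept inside 32-bit signed range
patient_seed <- function(seed, i) {
  (abs(seed) + 48271 * i) %% 2147483647L
}

transition_from_stay <- function(stay) {
  S <- length(stay)
  if (S == 1L) return(matrix(1, 1, 1))
  A <- matrix(0, S, S)
  for (s in seq_len(S)) {
    A[s, ] <- (1 - stay[s]) / (S - 1)
    A[s, s] <- stay[s]
  }
  A
}

simulate_markov_path <- function(Tn, init, trans) {
  S <- length(init)
  path <- integer(Tn)
  path[1] <- sample.int(S, 1L, prob = init)
  for (t in seq_len(Tn - 1L)) {
    path[t + 1L] <- sample.int(S, 1L, prob = trans[path[t], ])
  }
  path
}

# inverse-CDF truncated normal draw: exact and loop-free
rtruncnorm1 <- function(mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(1L, plo, phi), mean, sd)
}

draw_covariates <- function(cd) {
  sex <- rbinom(1L, 1L, cd$sex_p)
  age <- rtruncnorm1(cd$age[1], cd$age[2], cd$age[3], cd$age[4])
  weight <- rtruncnorm1(cd$weight[1], cd$weight[2], cd$weight[3], cd$weight[4])
  height <- rtruncnorm1(cd$height[1], cd$height[2], cd$height[3], cd$height[4])
  c(sex = sex, age = age, weight = weight, height = height,
    bmi = weight / height^2)
}

# K x S true parameter matrices for one patient: additive effects on mu,
# additive on log(sigma) so any effect size keeps sigma positive
true_patient_params <- function(config, cov) {
  vars <- config$monitored_vars
  K <- length(vars); S <- config$n_states
  mu <- unname(config$state_means)
  logadj <- matrix(0, K, S)      # additive on log sigma => multiplicative
  ce <- config$covariate_effects
  if (!is.null(ce) && nrow(ce)) {
    for (j in seq_len(nrow(ce))) {
      k <- match(ce$variable[j], vars)
      s <- ce$state[j]
      delta <- ce$effect[j] * cov[[ce$covariate[j]]]
      if (ce$parameter[j] == "mu") mu[k, s] <- mu[k, s] + delta
      else logadj[k, s] <- logadj[k, s] + delta
    }
  }
  if (config$mu_noise_sd > 0)
    mu <- mu + matrix(rnorm(K * S, 0, config$mu_noise_sd), K, S)
  if (config$sigma_log_noise_sd > 0)
    logadj <- logadj + matrix(rnorm(K * S, 0, config$sigma_log_noise_sd), K, S)
  list(mu = mu, sigma = unname(config$state_sds) * exp(logadj))
}

bind_or_empty <- function(lst, empty) {
  if (!length(lst)) return(empty)
  do.call(rbind, lst)
}

empty_profiles <- function() {
  data.frame(patient_id = character(), sex = numeric(), age = numeric(),
             weight = numeric(), height = numeric(), bmi = numeric())
}

empty_series <- function(vars, label_channels) {
  df <- data.frame(patient_id = character(), time = integer())
  for (v in vars) df[[v]] <- numeric()
  if (label_channels) {
    df$lactate <- numeric()
    df$drug_present <- integer()
  }
  df
}

#' Agreement between the rule label and the true hidden state
#'
#' Labels the cohort with the circulatory-failure rule and returns the
#' fraction of time points where the failure/safe label matches the true
#' simulated state (state 1 is the failure-aligned state by the
#' generator's convention). Used to calibrate how informative the
#' labelling channels are about the hidden state.
#'
#' @param cohort an `icu_cohort` with labelling channels.
#' @param truth the matching `icu_truth`.
#' @param ... passed to [label_states()] (threshold overrides).
#' @return fraction in \[0, 1\].
#' @export
rule_state_agreement <- function(cohort, truth, ...) {
  labels <- label_states(cohort$series, ...)
  key_l <- paste(labels$patient_id, labels$time)
  key_t <- paste(truth$states$patient_id, truth$states$time)
  idx <- match(key_l, key_t)
  if (anyNA(idx))
    icp_stop("truth does not cover all labelled time points", "schema_error")
  truth_failure <- truth$states$state[idx] == 1L
  mean((labels$label == "failure") == truth_failure)
}
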