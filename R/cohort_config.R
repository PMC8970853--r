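#' Synthetic cohort configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. The
#' defaults describe a two-state world in which the failure-like state
#' (state 1) has low mean arterial pressure (MAP), elevated heart rate,
#' elevated lactate and a high probability of vasoactive/inotropic drug
#' presence, so that the rule-based circulatory-failure label tracks the
#' hidden state.
#'
#' Per-patient true emission parameters are linear in the covariates:
#' `mu[n,k,s] = state_means[k,s] + sum_c effect * covariate_c + noise`,
#' and `log sigma[n,k,s] = log(state_sds[k,s]) + sum_c effect * covariate_c
#' + noise`, so configured sigma effects are multiplicative and simulated
#' SDs stay positive for any effect size. BMI is always derived as
#' `weight / height^2` (height in metres), never sampled directly.
#'
#' @param n_patients number of patients (may be 0 for an empty cohort).
#' @param t_range integer vector `c(min, max)` of series lengths; min >= 2.
#' @param n_states number of hidden states (default 2).
#' @param monitored_vars character vector of monitored variable names.
#' @param state_means numeric matrix, variables x states: baseline means.
#' @param state_sds numeric matrix, variables x states: baseline SDs (> 0).
#' @param covariate_effects data frame with columns `variable`, `state`,
#'   `parameter` ("mu" or "sigma"), `covariate` (one of sex, age, weight,
#'   height, bmi), `effect`; or `NULL` for no covariate dependence.
#' @param mu_noise_sd SD of patient-level noise added to each true mu.
#' @param sigma_log_noise_sd SD of patient-level noise on log sigma.
#' @param transition_stay_prob per-state self-transition probability in (0,1).
#' @param initial_probs initial state distribution (sums to 1).
#' @param lactate_params list with `meanlog` and `sdlog`, each length
#'   `n_states`: lognormal lactate parameters per state.
#' @param drug_prob_by_state per-state Bernoulli probability of the
#'   vasoactive/inotropic drug indicator at each time point.
#' @param covariate_dists list with `sex_p` and, for each of age / weight /
#'   height, `c(mean, sd, lower, upper)` truncated-normal parameters
#'   (height in metres).
#' @param label_channels logical; generate map/lactate/drug channels.
#' @param seed integer seed; each patient draws from a substream derived
#'   from it, so patient i's data is invariant to `n_patients`.
#'
#' @return an object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 5, seed = 1)
#' cohort <- generate_cohort(cfg)$cohort
#' head(cohort$series)
cohort_config <- function(n_patients = 100L,
                          t_range = c(50L, 200L),
                          n_states = 2L,
                          monitored_vars = c("heart_rate", "map"),
                          state_means = NULL,
                          state_sds = NULL,
                          covariate_effects = NULL,
                          mu_noise_sd = 1,
                          sigma_log_noise_sd = 0.05,
                          transition_stay_prob = c(0.95, 0.95),
                          initial_probs = NULL,
                          lactate_params = list(meanlog = c(log(3), log(1.2)),
                                                sdlog = c(0.35, 0.35)),
                          drug_prob_by_state = c(0.6, 0.05),
                          covariate_dists = list(
                            sex_p = 0.5,
                            age = c(62, 15, 18, 95),
                            weight = c(78, 15, 40, 160),
                            height = c(1.70, 0.10, 1.40, 2.10)),
                          label_channels = TRUE,
                          seed = 1L) {
  K <- length(monitored_vars)
  S <- as.integer(n_states)
  if (is.null(state_means)) {
    state_means <- default_state_means(monitored_vars, S)
  }
  if (is.null(state_sds)) {
    state_sds <- default_state_sds(monitored_vars, S)
  }
  state_means <- as.matrix(state_means)
  state_sds <- as.matrix(state_sds)
  rownames(state_means) <- rownames(state_sds) <- monitored_vars
  if (is.null(initial_probs)) initial_probs <- rep(1 / S, S)

  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    t_range = as.integer(t_range),
    n_states = S,
    monitored_vars = monitored_vars,
    state_means = state_means,
    state_sds = state_sds,
    covariate_effects = covariate_effects,
    mu_noise_sd = mu_noise_sd,
    sigma_log_noise_sd = sigma_log_noise_sd,
    transition_stay_prob = transition_stay_prob,
    initial_probs = initial_probs,
    lactate_params = lactate_params,
    drug_prob_by_state = drug_prob_by_state,
    covariate_dists = covariate_dists,
    label_channels = isTRUE(label_channels),
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

# defaults: state 1 is the failure-like state (low MAP, high heart rate)
default_state_means <- function(vars, S) {
  known <- list(heart_rate = c(96, 87), map = c(55, 85),
                systolic_bp = c(90, 120), diastolic_bp = c(50, 70))
  m <- matrix(NA_real_, length(vars), S)
  for (i in seq_along(vars)) {
    base <- known[[vars[i]]]
    if (is.null(base)) base <- c(0, 5)
    m[i, ] <- rep_len(base, S)
  }
  m
}

default_state_sds <- function(vars, S) {
  known <- list(heart_rate = c(10, 9), map = c(5, 5),
                systolic_bp = c(8, 8), diastolic_bp = c(6, 6))
  m <- matrix(NA_real_, length(vars), S)
  for (i in seq_along(vars)) {
    base <- known[[vars[i]]]
    if (is.null(base)) base <- c(1, 1)
    m[i, ] <- rep_len(base, S)
  }
  m
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    icp_stop(sprintf("invalid cohort_config: field '%s' %s", field, why),
             "config_error")
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 0L)
    fail("n_patients", "must be a non-negative integer")
  if (length(cfg$t_range) != 2L || any(is.na(cfg$t_range)) ||
      cfg$t_range[1] > cfg$t_range[2])
    fail("t_range", "must be c(min, max) with min <= max")
  if (cfg$t_range[1] < 2L)
    fail("t_range", "must have min >= 2 (an HMM needs two observations)")
  if (cfg$n_states < 1L) fail("n_states", "must be >= 1")
  S <- cfg$n_states; K <- length(cfg$monitored_vars)
  if (K < 1L) fail("monitored_vars", "must name at least one variable")
  if (anyDuplicated(cfg$monitored_vars))
    fail("monitored_vars", "must not contain duplicates")
  if (cfg$label_channels && !("map" %in% cfg$monitored_vars))
    fail("monitored_vars", "must include 'map' when label channels are on")
  if (!all(dim(cfg$state_means) == c(K, S)))
    fail("state_means", sprintf("must be a %d x %d matrix", K, S))
  if (!all(dim(cfg$state_sds) == c(K, S)))
    fail("state_sds", sprintf("must be a %d x %d matrix", K, S))
  if (any(!is.finite(cfg$state_sds)) || any(cfg$state_sds <= 0))
    fail("state_sds", "must be strictly positive")
  if (length(cfg$transition_stay_prob) != S ||
      any(cfg$transition_stay_prob <= 0) || any(cfg$transition_stay_prob >= 1))
    fail("transition_stay_prob", "must be length n_states, each in (0,1)")
  if (length(cfg$initial_probs) != S || any(cfg$initial_probs < 0) ||
      abs(sum(cfg$initial_probs) - 1) > 1e-12)
    fail("initial_probs", "must be length n_states and sum to 1 (1e-12)")
  if (cfg$mu_noise_sd < 0) fail("mu_noise_sd", "must be >= 0")
  if (cfg$sigma_log_noise_sd < 0) fail("sigma_log_noise_sd", "must be >= 0")
  if (length(cfg$drug_prob_by_state) != S ||
      any(cfg$drug_prob_by_state < 0) || any(cfg$drug_prob_by_state > 1))
    fail("drug_prob_by_state", "must be length n_states, each in [0,1]")
  lp <- cfg$lactate_params
  if (!is.list(lp) || length(lp$meanlog) != S || length(lp$sdlog) != S ||
      any(lp$sdlog <= 0))
    fail("lactate_params", "needs meanlog/sdlog of length n_states, sdlog > 0")
  cd <- cfg$covariate_dists
  if (is.null(cd$sex_p) || cd$sex_p < 0 || cd$sex_p > 1)
    fail("covariate_dists", "sex_p must be in [0,1]")
  for (v in c("age", "weight", "height")) {
    p <- cd[[v]]
    if (is.null(p) || length(p) != 4L || p[2] <= 0 || p[3] >= p[4])
      fail("covariate_dists",
           sprintf("%s must be c(mean, sd > 0, lower < upper)", v))
  }
  ce <- cfg$covariate_effects
  if (!is.null(ce)) {
    need <- c("variable", "state", "parameter", "covariate", "effect")
    if (!is.data.frame(ce) || !all(need %in% names(ce)))
      fail("covariate_effects",
           paste("must be a data frame with columns",
                 paste(need, collapse = ", ")))
    if (!all(ce$variable %in% cfg$monitored_vars))
      fail("covariate_effects", "references unknown monitored variables")
    if (!all(ce$parameter %in% c("mu", "sigma")))
      fail("covariate_effects", "parameter must be 'mu' or 'sigma'")
    if (!all(ce$covariate %in% c("sex", "age", "weight", "height", "bmi")))
      fail("covariate_effects", "covariate must be a basic variable")
    if (!all(ce$state %in% seq_len(S)))
      fail("covariate_effects", "state out of range")
  }
  invisible(cfg)
}
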