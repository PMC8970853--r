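#' @title Hidden Markov model parameters
#' @description Constructs and validates the parameter set of a Gaussian
#'   hidden Markov model: initial state distribution `initial_probs`,
#'   row-stochastic `transition` matrix, and per-state Gaussian emissions.
#'   Emissions are either `diagonal` (per-variable means `mu[k,s]` and
#'   SDs `sigma[k,s]`, variables conditionally independent given the
#'   state) or `full` (per-state mean vector and covariance matrix).
#' @param initial_probs length-S probability vector (sums to 1).
#' @param transition S x S row-stochastic matrix.
#' @param mu K x S matrix of emission means (rownames = variable names).
#' @param sigma K x S matrix of emission SDs (diagonal emissions).
#' @param Sigma optional list of S covariance matrices (full emissions).
#' @param emission "diagonal" or "full".
#' @return an object of class `hmm_parameters`.
#' @export
hmm_parameters <- function(initial_probs, transition, mu, sigma = NULL,
                           Sigma = NULL, emission = c("diagonal", "full")) {
  emission <- match.arg(emission)
  mu <- as.matrix(mu)
  S <- length(initial_probs)
  if (abs(sum(initial_probs) - 1) > 1e-10 || any(initial_probs < 0))
    icp_stop("initial_probs must be a probability vector (sum 1)",
             "hmm_error")
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(S, S)) ||
      any(abs(rowSums(transition) - 1) > 1e-10) || any(transition < 0))
    icp_stop("transition must be S x S row-stochastic", "hmm_error")
  if (ncol(mu) != S) icp_stop("mu must be K x S", "hmm_error")
  if (emission == "diagonal") {
    sigma <- as.matrix(sigma)
    if (!all(dim(sigma) == dim(mu)) || any(sigma <= 0))
      icp_stop("sigma must be K x S with positive entries", "hmm_error")
  } else {
    if (!is.list(Sigma) || length(Sigma) != S)
      icp_stop("Sigma must be a list of S covariance matrices", "hmm_error")
    for (s in seq_len(S)) {
      Sg <- Sigma[[s]]
      if (!isSymmetric(unname(Sg), tol = 1e-8) ||
          inherits(try(chol(Sg), silent = TRUE), "try-error"))
        icp_stop(sprintf("Sigma[[%d]] not symmetric positive-definite", s),
                 "hmm_error")
    }
  }
  structure(list(n_states = S, emission = emission,
                 initial_probs = as.numeric(initial_probs),
                 transition = transition, mu = mu, sigma = sigma,
                 Sigma = Sigma),
            class = "hmm_parameters")
}

# T x S matrix of log emission densities for an observation matrix (T x K)
hmm_log_emissions <- function(params, obs) {
  obs <- as.matrix(obs)
  Tn <- nrow(obs); K <- ncol(obs); S <- params$n_states
  if (nrow(params$mu) != K)
    icp_stop(sprintf("emission dimension mismatch: params have %d variables, series has %d",
                     nrow(params$mu), K), "hmm_error")
  if (any(!is.finite(obs)))
    icp_stop("series contains non-finite observations", "hmm_error")
  logB <- matrix(0, Tn, S)
  for (s in seq_len(S)) {
    if (params$emission == "diagonal") {
      ld <- dnorm(obs, mean = matrix(params$mu[, s], Tn, K, byrow = TRUE),
                  sd = matrix(params$sigma[, s], Tn, K, byrow = TRUE),
                  log = TRUE)
      logB[, s] <- if (K == 1L) ld else rowSums(ld)
    } else {
      logB[, s] <- dmvnorm_log(obs, params$mu[, s], params$Sigma[[s]])
    }
  }
  logB
}

# multivariate normal log-density via Cholesky
dmvnorm_log <- function(x, mean, Sigma) {
  R <- chol(Sigma)
  d <- length(mean)
  centered <- sweep(as.matrix(x), 2L, mean)
  z <- backsolve(R, t(centered), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}

#' Forward-backward smoothing
#'
#' Computes the exact smoothed posterior state probabilities
#' p(state_t = s | all observations) and the total log-likelihood of an
#' observation sequence under fixed HMM parameters, using per-step
#' scaling so no underflow occurs even for very long series.
#'
#' @param params an [hmm_parameters()] object.
#' @param obs numeric matrix (T x K) or vector (T, for K = 1) of
#'   observations.
#' @return list with `posteriors` (T x S, rows sum to 1), `loglik`, and
#'   `xi_sum` (S x S expected transition counts, used by the M-step).
#' @export
forward_backward <- function(params, obs) {
  if (is.vector(obs)) obs <- matrix(obs, ncol = 1)
  logB <- hmm_log_emissions(params, obs)
  fb_core(params$initial_probs, params$transition, logB)
}

# scaled forward-backward given log emission densities
fb_core <- function(init, trans, logB) {
  Tn <- nrow(logB); S <- ncol(logB)
  m <- apply(logB, 1L, max)              # per-step shift against underflow
  B <- exp(logB - m)
  alpha <- matrix(0, Tn, S)
  cvec <- numeric(Tn)
  a <- init * B[1L, ]
  cvec[1L] <- sum(a)
  alpha[1L, ] <- a / cvec[1L]
  if (Tn > 1L) for (t in 2:Tn) {
    a <- (alpha[t - 1L, ] %*% trans) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, Tn, S)
  beta[Tn, ] <- 1
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    beta[t, ] <- as.numeric(trans %*% (B[t + 1L, ] * beta[t + 1L, ])) /
      cvec[t + 1L]
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  xi_sum <- matrix(0, S, S)
  if (Tn > 1L) for (t in seq_len(Tn - 1L)) {
    xi <- (alpha[t, ] %o% (B[t + 1L, ] * beta[t + 1L, ])) * trans /
      cvec[t + 1L]
    xi_sum <- xi_sum + xi
  }
  list(posteriors = post, loglik = sum(log(cvec)) + sum(m), xi_sum = xi_sum)
}

#' Fit a Gaussian HMM by Baum-Welch expectation maximisation
#'
#' Iterates the E-step (forward-backward responsibilities) and M-step
#' (responsibility-weighted means and variances, expected transition
#' counts) until the relative log-likelihood change falls below `tol` or
#' `max_iter` is reached. The initial state distribution starts uniform;
#' emission means start from a per-variable quantile split with small
#' seeded jitter across restarts, and the restart with the highest
#' log-likelihood is returned. States are decoded by per-time posterior
#' argmax (ties broken toward the lower state index).
#'
#' A variance floor of `var_floor_scale * (sample variance + eps)` per
#' variable prevents likelihood blow-up on near-constant segments;
#' all-constant series return a degenerate fit flagged `degenerate`.
#'
#' @param obs numeric matrix (T x K, columns named by variable) or vector.
#' @param n_states number of hidden states S (default 2).
#' @param emission "diagonal" (variables independent given the state) or
#'   "full" (full covariance per state).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param n_restarts number of jittered initialisations.
#' @param seed integer seed for the restart jitter.
#' @param var_floor_scale scale of the per-variable variance floor.
#' @return an object of class `hmm_fit`: `params`, `posteriors` (T x S),
#'   `decoded`, `loglik_trace`, `loglik`, `converged`, `n_iter`,
#'   `degenerate`, `aligned` (FALSE until [align_states()]).
#' @export
fit_baum_welch <- function(obs, n_states = 2L, emission = c("diagonal", "full"),
                           tol = 1e-6, max_iter = 200L, n_restarts = 3L,
                           seed = 1L, var_floor_scale = 1e-6) {
  emission <- match.arg(emission)
  if (is.vector(obs)) obs <- matrix(obs, ncol = 1,
                                    dimnames = list(NULL, "V1"))
  obs <- as.matrix(obs)
  if (is.null(colnames(obs))) colnames(obs) <- paste0("V", seq_len(ncol(obs)))
  Tn <- nrow(obs); K <- ncol(obs); S <- as.integer(n_states)
  if (S < 1L) icp_stop("n_states must be >= 1", "hmm_error")
  if (Tn < S + 1L)
    icp_stop(sprintf("series too short: T = %d but need T >= S + 1 = %d",
                     Tn, S + 1L), "hmm_error")
  if (any(!is.finite(obs)))
    icp_stop("series contains non-finite observations", "hmm_error")

  sample_var <- apply(obs, 2L, var) * (Tn - 1) / Tn    # MLE variance
  degenerate <- all(sample_var == 0)
  var_floor <- var_floor_scale * (sample_var + 1e-12) + 1e-300
  # floor must be usable even for constant columns
  var_floor <- pmax(var_floor, 1e-12)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- init_emissions(obs, S, var_floor,
                           jitter_seed = if (r == 1L) NULL
                                         else c(seed, r))
    fit <- run_em(obs, S, emission, init, tol, max_iter, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  decoded <- max.col(best$posteriors, ties.method = "first")
  structure(list(params = best$params, posteriors = best$posteriors,
                 decoded = decoded, loglik_trace = best$loglik_trace,
                 loglik = best$loglik, converged = best$converged,
                 n_iter = best$n_iter, degenerate = degenerate,
                 aligned = FALSE, variables = colnames(obs),
                 var_floor = var_floor),
            class = "hmm_fit")
}

# per-variable quantile-band initialisation, optional seeded jitter
init_emissions <- function(obs, S, var_floor, jitter_seed = NULL) {
  Tn <- nrow(obs); K <- ncol(obs)
  mu <- matrix(0, K, S, dimnames = list(colnames(obs), NULL))
  sg <- matrix(0, K, S, dimnames = list(colnames(obs), NULL))
  for (k in seq_len(K)) {
    x <- sort(obs[, k])
    band <- if (S == 1L) rep(1L, Tn)
            else cut(seq_len(Tn), breaks = S, labels = FALSE)
    mu[k, ] <- vapply(split(x, band), mean, numeric(1))
    sg[k, ] <- vapply(split(x, band), function(b) {
      v <- if (length(b) < 2L) 0 else var(b) * (length(b) - 1) / length(b)
      sqrt(max(v, var_floor[k]))
    }, numeric(1))
  }
  if (!is.null(jitter_seed)) {
    set.seed((abs(jitter_seed[1]) %% 1000003) * 1009 + jitter_seed[2])
    spread <- apply(obs, 2L, sd)
    mu <- mu + matrix(rnorm(K * S, 0, 0.1 * (spread + 1e-12)), K, S)
  }
  list(mu = mu, sigma = sg)
}

run_em <- function(obs, S, emission, init, tol, max_iter, var_floor) {
  Tn <- nrow(obs); K <- ncol(obs)
  pi0 <- rep(1 / S, S)
  trans <- matrix(0.2 / max(S - 1, 1), S, S); diag(trans) <- if (S > 1) 0.8 else 1
  mu <- init$mu; sigma <- init$sigma
  Sigma <- NULL
  if (emission == "full") {
    Sigma <- lapply(seq_len(S), function(s) {
      D <- diag(sigma[, s]^2, nrow = K); dimnames(D) <- NULL; D
    })
  }
  loglik_trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  iter <- 0L
  repeat {
    params <- hmm_parameters(pi0, trans, mu,
                             sigma = if (emission == "diagonal") sigma,
                             Sigma = Sigma, emission = emission)
    fb <- fb_core(pi0, trans, hmm_log_emissions(params, obs))
    ll <- fb$loglik
    loglik_trace <- c(loglik_trace, ll)
    iter <- iter + 1L
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    # M-step
    g <- fb$posteriors
    pi0 <- g[1L, ]
    if (Tn > 1L && S > 1L) {
      xs <- fb$xi_sum
      rs <- rowSums(xs)
      trans <- xs / ifelse(rs > 0, rs, 1)
      trans[rs == 0, ] <- 1 / S
    }
    wsum <- colSums(g)
    wsum <- pmax(wsum, 1e-10)
    mu <- t(crossprod(g, obs) / wsum)            # K x S
    if (emission == "diagonal") {
      for (s in seq_len(S)) {
        dev2 <- sweep(obs, 2L, mu[, s])^2
        v <- colSums(g[, s] * dev2) / wsum[s]
        sigma[, s] <- sqrt(pmax(v, var_floor))
      }
    } else {
      for (s in seq_len(S)) {
        centered <- sweep(obs, 2L, mu[, s])
        Sg <- crossprod(centered * g[, s], centered) / wsum[s]
        diag(Sg) <- pmax(diag(Sg), var_floor)
        Sigma[[s]] <- (Sg + t(Sg)) / 2 + diag(1e-10, K)
      }
    }
  }
  params <- hmm_parameters(pi0, trans, mu,
                           sigma = if (emission == "diagonal") sigma,
                           Sigma = Sigma, emission = emission)
  fb <- fb_core(pi0, trans, hmm_log_emissions(params, obs))
  list(params = params, posteriors = fb$posteriors, loglik = fb$loglik,
       loglik_trace = loglik_trace, converged = converged, n_iter = iter)
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> S = %d, T = %d, loglik = %.3f, %s after %d iter%s%s\n",
              x$params$n_states, nrow(x$posteriors), x$loglik,
              if (x$converged) "converged" else "max_iter reached", x$n_iter,
              if (x$aligned) ", aligned" else "",
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Align HMM states to the failure/safe convention
#'
#' Permutes the state indices of a fit so that the state with the lower
#' fitted mean on the reference variable comes first (state 1 =
#' failure-aligned): circulatory failure presents with relatively low
#' mean arterial pressure. Posteriors, decoded states, transition matrix
#' and emission parameters are permuted consistently. Equal means keep
#' the original order (tie reported via a message).
#'
#' @param fit an `hmm_fit`.
#' @param reference_variable variable whose fitted means define the
#'   order; defaults to `"map"` when present, else the first variable.
#' @param convention only `"lower_mean_is_failure"` is defined.
#' @return the aligned `hmm_fit` (`aligned = TRUE`).
#' @export
align_states <- function(fit, reference_variable = NULL,
                         convention = "lower_mean_is_failure") {
  convention <- match.arg(convention)
  vars <- fit$variables
  if (is.null(reference_variable)) {
    reference_variable <- if ("map" %in% vars) "map" else vars[1]
  }
  k <- match(reference_variable, vars)
  if (is.na(k))
    icp_stop(paste("unknown reference variable:", reference_variable),
             "hmm_error")
  means <- fit$params$mu[k, ]
  if (anyDuplicated(means)) {
    message("align_states: tied reference means; keeping original order")
    perm <- seq_along(means)
  } else {
    perm <- order(means)
  }
  fit$params$initial_probs <- fit$params$initial_probs[perm]
  fit$params$transition <- fit$params$transition[perm, perm, drop = FALSE]
  fit$params$mu <- fit$params$mu[, perm, drop = FALSE]
  if (!is.null(fit$params$sigma))
    fit$params$sigma <- fit$params$sigma[, perm, drop = FALSE]
  if (!is.null(fit$params$Sigma))
    fit$params$Sigma <- fit$params$Sigma[perm]
  fit$posteriors <- fit$posteriors[, perm, drop = FALSE]
  fit$decoded <- match(fit$decoded, perm)
  fit$aligned <- TRUE
  fit
}

#' Extract per-state emission parameter records
#'
#' Flattens a fit into one record per variable x state: the estimated
#' `mu_hat` and `sigma_hat` (for full-covariance fits, `sigma_hat` is the
#' square root of the corresponding diagonal covariance entry). These
#' records are the pipeline's central response data.
#'
#' @param fit an `hmm_fit`.
#' @param patient_id identifier attached to each record.
#' @return data frame patient_id, variable, state, mu_hat, sigma_hat,
#'   converged, degenerate.
#' @export
extract_parameters <- function(fit, patient_id) {
  S <- fit$params$n_states
  K <- length(fit$variables)
  sigma_hat <- if (fit$params$emission == "diagonal") {
    as.vector(fit$params$sigma)
  } else {
    as.vector(vapply(fit$params$Sigma, function(Sg) sqrt(diag(Sg)),
                     numeric(K)))
  }
  data.frame(patient_id = patient_id,
             variable = rep(fit$variables, times = S),
             state = rep(seq_len(S), each = K),
             mu_hat = as.vector(fit$params$mu),
             sigma_hat = sigma_hat,
             converged = fit$converged,
             degenerate = fit$degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit, align and extract for every patient in a cohort
#'
#' Convenience wrapper: fits one HMM per patient on the monitored
#' variables, aligns states to the failure convention on the reference
#' variable, and returns the fits plus the stacked parameter records.
#'
#' @param cohort an `icu_cohort`.
#' @param variables monitored variables to model; default all.
#' @param reference_variable passed to [align_states()].
#' @param seed base seed; patient i uses a substream derived from it.
#' @param ... passed to [fit_baum_welch()].
#' @return list with `fits` (named by patient_id) and `records`.
#' @export
fit_cohort <- function(cohort, variables = NULL, reference_variable = NULL,
                       seed = 1L, ...) {
  if (is.null(variables)) variables <- monitored_var_names(cohort$series)
  ids <- unique(cohort$series$patient_id)
  fits <- vector("list", length(ids))
  names(fits) <- ids
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- cohort$series$patient_id == ids[i]
    obs <- as.matrix(cohort$series[rows, variables, drop = FALSE])
    fit <- fit_baum_welch(obs, seed = patient_seed(seed, i), ...)
    fit <- align_states(fit, reference_variable)
    fits[[i]] <- fit
    recs[[i]] <- extract_parameters(fit, ids[i])
  }
  list(fits = fits, records = do.call(rbind, recs))
}
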