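random_params <- function(S, K) {
  init <- runif(S); init <- init / sum(init)
  trans <- matrix(runif(S * S), S, S); trans <- trans / rowSums(trans)
  mu <- matrix(rnorm(K * S, 0, 3), K, S)
  sigma <- matrix(runif(K * S, 0.5, 2), K, S)
  hmm_parameters(init, trans, mu, sigma)
}

test_that("forward-backward equals the exhaustive-path oracle", {
  set.seed(100)
  for (rep in 1:100) {
    S <- sample(1:3, 1); K <- sample(1:2, 1); Tn <- sample(2:8, 1)
    params <- random_params(S, K)
    obs <- matrix(rnorm(Tn * K, 0, 3), Tn, K)
    got <- forward_backward(params, obs)
    want <- brute_force_fb(params$initial_probs, params$transition,
                           params$mu, params$sigma, obs)
    expect_lt(max(abs(got$posteriors - want$posteriors)), 1e-10)
    expect_lt(abs(got$loglik - want$loglik), 1e-10)
  }
})

test_that("single-state posteriors are 1 and the loglik is the Gaussian sum", {
  params <- hmm_parameters(1, matrix(1, 1, 1), matrix(2, 1, 1),
                           matrix(1.5, 1, 1))
  obs <- c(1.2, 2.8, 2.0, 0.4)
  got <- forward_backward(params, obs)
  expect_equal(as.vector(got$posteriors), rep(1, 4))
  expect_equal(got$loglik, sum(dnorm(obs, 2, 1.5, log = TRUE)))
})

test_that("identical emissions with uniform dynamics give posterior 0.5", {
  params <- hmm_parameters(c(0.5, 0.5), matrix(0.5, 2, 2),
                           matrix(c(1, 1), 1, 2), matrix(c(2, 2), 1, 2))
  got <- forward_backward(params, rnorm(10))
  expect_equal(as.vector(got$posteriors), rep(0.5, 20))
})

test_that("relabelling states leaves the likelihood unchanged", {
  set.seed(7)
  params <- random_params(3, 2)
  obs <- matrix(rnorm(12), 6, 2)
  perm <- c(3, 1, 2)
  permuted <- hmm_parameters(params$initial_probs[perm],
                             params$transition[perm, perm],
                             params$mu[, perm], params$sigma[, perm])
  expect_equal(forward_backward(params, obs)$loglik,
               forward_backward(permuted, obs)$loglik)
})

test_that("very long series do not underflow", {
  params <- hmm_parameters(c(0.5, 0.5),
                           matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2),
                           matrix(c(0, 5), 1, 2), matrix(c(1, 1), 1, 2))
  set.seed(3)
  got <- forward_backward(params, rnorm(1e5, 2, 3))
  expect_true(is.finite(got$loglik))
  expect_true(all(abs(rowSums(got$posteriors) - 1) < 1e-8))
})

test_that("S = 1 Baum-Welch recovers the closed-form MLE exactly", {
  set.seed(5)
  x <- rnorm(40, 10, 2)
  fit <- fit_baum_welch(x, n_states = 1, n_restarts = 1)
  expect_equal(unname(fit$params$mu[1, 1]), mean(x))
  expect_equal(unname(fit$params$sigma[1, 1]),
               sqrt(mean((x - mean(x))^2)))     # MLE (divide by T)
  recs <- extract_parameters(fit, "p1")
  expect_equal(recs$mu_hat, mean(x))
})

test_that("Baum-Welch recovers well-separated state means", {
  sim <- sim_hmm_series(5000, mu = c(0, 5), sigma = c(1, 1), stay = 0.95,
                        seed = 11)
  fit <- fit_baum_welch(sim$obs, n_states = 2, seed = 17)
  fit <- align_states(fit, "V1")
  # simulation-truth oracle; 0.15 ~ 4 SE of a state-conditional mean
  expect_lt(abs(fit$params$mu[1, 1] - 0), 0.15)
  expect_lt(abs(fit$params$mu[1, 2] - 5), 0.15)
  expect_true(fit$converged)
})

test_that("the EM log-likelihood trace is non-decreasing on every fit", {
  set.seed(23)
  for (rep in 1:8) {
    Tn <- sample(30:80, 1)
    obs <- cbind(a = rnorm(Tn, sample(0:5, 1)), b = rnorm(Tn, 0, 2))
    fit <- fit_baum_welch(obs, n_states = 2, n_restarts = 2, seed = rep)
    expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  }
})

test_that("posterior rows sum to 1 and decoding is the posterior argmax", {
  sim <- sim_hmm_series(300, c(0, 3), c(1, 1), 0.9, seed = 2)
  fit <- fit_baum_welch(sim$obs, n_states = 2, seed = 1)
  expect_true(all(abs(rowSums(fit$posteriors) - 1) < 1e-8))
  expect_identical(fit$decoded,
                   max.col(fit$posteriors, ties.method = "first"))
})

test_that("an all-constant series yields a flagged degenerate fit", {
  fit <- fit_baum_welch(rep(3.2, 25), n_states = 2, n_restarts = 1)
  expect_true(fit$degenerate)
  expect_true(all(fit$params$sigma > 0))
})

test_that("fitting errors are raised for bad inputs", {
  expect_error(fit_baum_welch(c(1, 2), n_states = 2), "too short",
               class = "hmm_error")
  expect_error(fit_baum_welch(c(1, NA, 3, 4)), "non-finite",
               class = "hmm_error")
  params <- hmm_parameters(c(0.5, 0.5), matrix(0.5, 2, 2),
                           matrix(0, 2, 2), matrix(1, 2, 2))
  expect_error(forward_backward(params, matrix(0, 4, 3)),
               "dimension mismatch", class = "hmm_error")
})

test_that("align_states puts the lower reference mean first", {
  sim <- sim_hmm_series(400, c(70, 90), c(5, 5), 0.9, seed = 9)
  obs <- cbind(heart_rate = rnorm(400, 90, 10), map = sim$obs)
  fit <- fit_baum_welch(obs, n_states = 2, seed = 2)
  aligned <- align_states(fit)          # defaults to "map"
  expect_lt(aligned$params$mu["map", 1], aligned$params$mu["map", 2])
  # idempotent once aligned
  again <- align_states(aligned)
  expect_equal(again$params, aligned$params)
  expect_equal(again$posteriors, aligned$posteriors)
  # permutation consistency: posterior columns follow the state order
  expect_equal(sort(colnames(fit$params$mu)), sort(colnames(aligned$params$mu)))
  expect_equal(forward_backward(aligned$params, obs)$loglik, fit$loglik,
               tolerance = 1e-8)
  expect_error(align_states(fit, "nope"), class = "hmm_error")
})

test_that("tied reference means keep the original order with a message", {
  fit <- fit_baum_welch(rnorm(30), n_states = 2, n_restarts = 1, seed = 1)
  fit$params$mu[1, ] <- c(2, 2)
  expect_message(out <- align_states(fit, "V1"), "tied")
  expect_equal(out$posteriors, fit$posteriors)
})

test_that("extract_parameters has S x K cardinality and full-cov diagonals", {
  set.seed(31)
  obs <- matrix(rnorm(200), 50, 4,
                dimnames = list(NULL, c("a", "b", "c", "map")))
  fit <- fit_baum_welch(obs, n_states = 2, n_restarts = 1, seed = 1)
  recs <- extract_parameters(align_states(fit), "p7")
  expect_identical(nrow(recs), 8L)
  expect_setequal(recs$variable, c("a", "b", "c", "map"))

  full <- fit_baum_welch(obs, n_states = 2, emission = "full",
                         n_restarts = 1, seed = 1)
  frecs <- extract_parameters(full, "p7")
  expect_equal(frecs$sigma_hat[frecs$state == 1],
               unname(sqrt(diag(full$params$Sigma[[1]]))))
})
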