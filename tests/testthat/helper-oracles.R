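# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the forward-backward oracle enumerates every
# state path, the AUC oracle counts pairs.

# exhaustive-path smoothed posteriors and log-likelihood for a diagonal
# Gaussian HMM; obs is T x K
brute_force_fb <- function(init, trans, mu, sigma, obs) {
  obs <- as.matrix(obs)
  Tn <- nrow(obs); K <- ncol(obs); S <- length(init)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  logp <- apply(paths, 1L, function(path) {
    lp <- log(init[path[1]])
    if (Tn > 1L) for (t in 2:Tn) lp <- lp + log(trans[path[t - 1], path[t]])
    for (t in seq_len(Tn)) {
      lp <- lp + sum(dnorm(obs[t, ], mu[, path[t]], sigma[, path[t]],
                           log = TRUE))
    }
    lp
  })
  m <- max(logp)
  w <- exp(logp - m)
  loglik <- m + log(sum(w))
  post <- matrix(0, Tn, S)
  for (t in seq_len(Tn)) for (s in seq_len(S)) {
    post[t, s] <- sum(w[paths[, t] == s]) / sum(w)
  }
  list(posteriors = post, loglik = loglik)
}

# pair-counting AUC: concordant + half ties over all pos x neg pairs
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# tiny labelled cohort built by hand: `pattern` gives each patient's
# label sequence as a string of f/s characters
manual_labelled_cohort <- function(patterns) {
  ids <- sprintf("M%02d", seq_along(patterns))
  profiles <- data.frame(patient_id = ids, sex = 0, age = 50, weight = 70,
                         height = 1.7, bmi = 70 / 1.7^2)
  series <- do.call(rbind, lapply(seq_along(patterns), function(i) {
    tt <- nchar(patterns[i])
    data.frame(patient_id = ids[i], time = seq_len(tt),
               map = 80, lactate = 1, drug_present = 0L)
  }))
  labels <- do.call(rbind, lapply(seq_along(patterns), function(i) {
    ch <- strsplit(patterns[i], "")[[1]]
    data.frame(patient_id = ids[i], time = seq_along(ch),
               label = ifelse(ch == "f", "failure", "safe"))
  }))
  new_cohort(profiles, series, labels)
}

# simulate a two-state Markov-Gaussian series (independent of the
# package's generator) for recovery checks
sim_hmm_series <- function(Tn, mu, sigma, stay, seed) {
  set.seed(seed)
  S <- length(mu)
  path <- integer(Tn)
  path[1] <- sample.int(S, 1L)
  for (t in 2:Tn) {
    path[t] <- if (runif(1) < stay) path[t - 1L]
               else sample(setdiff(seq_len(S), path[t - 1L]), 1L)
  }
  list(obs = rnorm(Tn, mu[path], sigma[path]), path = path)
}
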