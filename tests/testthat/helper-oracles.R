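# Independent brute-force oracles, written with plain loops so they share
# no code path with the vectorized engine they check.

# enumerate all binary latent configurations for K signals
naive_states <- function(K) {
  out <- matrix(0, 2^K, K)
  for (s in seq_len(2^K)) {
    v <- s - 1
    for (k in seq_len(K)) {
      out[s, k] <- v %% 2
      v <- v %/% 2
    }
  }
  out
}

naive_log_potential <- function(z, g, beta, theta) {
  beta <- unname(beta)
  theta <- unname(theta)
  K <- length(z)
  pot <- 0
  for (k in seq_len(K)) {
    if (z[k] == 1) pot <- pot + beta[k, 1] + sum(beta[k, -1] * g)
  }
  for (k in seq_len(K - 1)) for (l in (k + 1):K) {
    pot <- pot + theta[k, l] * z[k] * z[l]
  }
  pot
}

# posterior over states and marginals for one instance
naive_posterior <- function(g, e, params) {
  K <- length(params$signals)
  st <- naive_states(K)
  w <- numeric(nrow(st))
  for (s in seq_len(nrow(st))) {
    pot <- naive_log_potential(st[s, ], g, params$beta, params$theta)
    lik <- 1
    for (k in seq_len(K)) {
      if (!is.na(e[k])) lik <- lik * params$phi[[k]][st[s, k] + 1, e[k]]
    }
    w[s] <- exp(pot) * lik
  }
  prob <- w / sum(w)
  marg <- numeric(K)
  for (k in seq_len(K)) marg[k] <- sum(prob[st[, k] == 1])
  list(states = st, prob = prob, marginals = marg)
}

naive_prior_marginals <- function(g, params) {
  K <- length(params$signals)
  naive_posterior(g, rep(NA_integer_, K), params)$marginals
}

# penalized marginal log-likelihood for an instance set, by enumeration
naive_marginal_ll <- function(G, E, params) {
  K <- length(params$signals)
  st <- naive_states(K)
  total <- 0
  for (i in seq_len(nrow(G))) {
    num <- den <- 0
    for (s in seq_len(nrow(st))) {
      pot <- exp(naive_log_potential(st[s, ], G[i, ], params$beta,
                                     params$theta))
      lik <- 1
      for (k in seq_len(K)) {
        if (!is.na(E[i, k])) lik <- lik * params$phi[[k]][st[s, k] + 1, E[i, k]]
      }
      num <- num + pot * lik
      den <- den + pot
    }
    total <- total + log(num / den)
  }
  pen <- sum(params$beta^2)
  for (k in seq_len(K - 1)) for (l in (k + 1):K) {
    pen <- pen + 2 * params$theta[k, l]^2
  }
  total - params$lambda * pen
}

# random dimensionally consistent parameters for K signals
random_params <- function(K, P, categories = NULL, lambda = 0.5) {
  if (is.null(categories)) categories <- rep(3, K)
  beta <- matrix(rnorm(K * (P + 1), sd = 0.8), K, P + 1)
  theta <- matrix(0, K, K)
  if (K > 1) {
    v <- rnorm(K * (K - 1) / 2, sd = 0.7)
    theta[upper.tri(theta)] <- v
    theta <- theta + t(theta)
  }
  phi <- lapply(categories, function(C) {
    tab <- matrix(rgamma(2 * C, 2), 2, C)
    tab / rowSums(tab)
  })
  watershed_params(beta, theta, phi, lambda = lambda)
}

# random E matrix with given categories and missingness
random_E <- function(n, categories, missing_rate = 0.2) {
  E <- sapply(categories, function(C) sample.int(C, n, replace = TRUE))
  E <- matrix(as.integer(E), n, length(categories))
  E[matrix(runif(n * length(categories)) < missing_rate, n)] <- NA
  E
}

# small fully specified parameter set used across tests (K = 4, P = 3)
fixture_params <- function(lambda = 1) {
  default_sim_params(n_signals = 4, n_annotations = 3,
                     n_informative = 2, lambda = lambda)
}
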