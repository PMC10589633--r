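# Exact-inference engine for the Watershed CRF.
#
# The latent layer Z is a fully connected binary pairwise CRF over the K
# omic signals, conditioned on the annotation vector G:
#   P(z | G) propto exp( sum_k z_k (beta_k0 + beta_k . G)
#                        + sum_{k<l} theta_kl z_k z_l )
# Observed outlier statuses E_k are emitted from categorical tables
# phi_k(e | z_k); missing E_k are marginalized out. K is small (4 in the
# multi-omics model), so all quantities are computed by exact enumeration
# of the 2^K latent configurations.

# All 2^K latent configurations as a (2^K) x K 0/1 matrix.
ws_states <- function(K) {
  s <- as.matrix(expand.grid(rep(list(0:1), K)))
  dimnames(s) <- NULL
  storage.mode(s) <- "double"
  s
}

# Unnormalized log potentials: n x 2^K matrix for G an n x P matrix.
ws_log_potentials <- function(G, params, states = NULL) {
  K <- length(params$signals)
  if (is.null(states)) states <- ws_states(K)
  G <- to_matrix_rows(G, ncol(params$beta) - 1)
  # singleton activations a_nk = beta_k0 + G_n . beta_k
  a <- sweep(G %*% t(params$beta[, -1, drop = FALSE]), 2,
             -params$beta[, 1], "-")
  # pairwise contribution depends on the state only
  pair <- 0.5 * rowSums((states %*% params$theta) * states)
  pot <- a %*% t(states)
  sweep(pot, 2, pair, "+")
}

# Coerce a single annotation vector or matrix to an n x P matrix.
to_matrix_rows <- function(G, P) {
  if (is.null(dim(G))) {
    if (length(G) != P)
      stop("annotation vector has length ", length(G),
           " but parameters expect ", P)
    G <- matrix(G, nrow = 1)
  }
  G <- as.matrix(G)
  if (ncol(G) != P)
    stop("annotation matrix has ", ncol(G),
         " columns but parameters expect ", P)
  G
}

# column-wise pmax: fast row maxima for matrices with few columns
row_max <- function(x) {
  m <- x[, 1]
  for (j in seq_len(ncol(x))[-1]) m <- pmax(m, x[, j])
  m
}

row_softmax <- function(logw) {
  w <- exp(logw - row_max(logw))
  w / rowSums(w)
}

row_logsumexp <- function(logw) {
  m <- row_max(logw)
  m + log(rowSums(exp(logw - m)))
}

#' Exact CRF prior over latent regulatory states
#'
#' Computes the normalized distribution over all \eqn{2^K} configurations of
#' the latent layer given annotation input, by exact enumeration.
#'
#' @param G annotation vector (length P) or matrix (instances x P), on the
#'   standardized scale used in training.
#' @param params a \code{\link{watershed_params}} object.
#' @return list with \code{states} (the \eqn{2^K \times K} configuration
#'   matrix), \code{prob} (instances x \eqn{2^K} state probabilities) and
#'   \code{marginals} (instances x K matrix of \eqn{P(Z_k = 1 \mid G)}).
#' @export
crf_prior <- function(G, params) {
  K <- length(params$signals)
  states <- ws_states(K)
  pot <- ws_log_potentials(G, params, states)
  if (any(!is.finite(pot)))
    stop("non-finite CRF potential; check annotations and parameters")
  prob <- row_softmax(pot)
  marg <- prob %*% states
  colnames(marg) <- params$signals
  list(states = states, prob = prob, marginals = marg)
}

# Per-instance, per-state emission log-likelihood of the observed outlier
# categories. E is an n x K integer matrix of category indices (NA =
# missing). Returns n x 2^K.
ws_emission_loglik <- function(E, params, states = NULL) {
  K <- length(params$signals)
  if (is.null(states)) states <- ws_states(K)
  E <- as.matrix(E)
  if (ncol(E) != K) stop("`E` must have one column per signal")
  n <- nrow(E)
  l0 <- matrix(0, n, K)
  l1 <- matrix(0, n, K)
  for (k in seq_len(K)) {
    tab <- params$phi[[k]]
    obs <- !is.na(E[, k])
    e <- E[obs, k]
    if (any(e < 1 | e > ncol(tab)))
      stop("outlier category out of range for signal ", params$signals[k])
    if (any(tab[, unique(e)] == 0))
      stop("emission table for signal ", params$signals[k],
           " puts zero mass on an observed category")
    l0[obs, k] <- log(tab[1, e])
    l1[obs, k] <- log(tab[2, e])
  }
  l0 %*% (1 - t(states)) + l1 %*% t(states)
}

#' Exact posterior over latent regulatory states given outlier evidence
#'
#' Computes \eqn{P(z \mid G, E) \propto P(z \mid G) \prod_k \phi_k(E_k \mid
#' z_k)} by enumeration of all \eqn{2^K} latent configurations. Missing
#' entries of \code{E} contribute nothing (they are marginalized), so
#' posteriors are defined for all K signals even when only a subset of
#' omics was measured.
#'
#' @param G annotation vector or matrix (instances x P), standardized.
#' @param E integer vector or matrix (instances x K) of observed outlier
#'   categories (index into the signal's category set; see
#'   \code{\link{watershed_params}}), \code{NA} where unmeasured.
#' @param params a \code{\link{watershed_params}} object.
#' @return list with \code{states}, \code{prob} (posterior state
#'   probabilities) and \code{marginals} (instances x K matrix of
#'   \eqn{P(Z_k = 1 \mid G, E)}).
#' @export
joint_posterior <- function(G, E, params) {
  K <- length(params$signals)
  states <- ws_states(K)
  G <- to_matrix_rows(G, ncol(params$beta) - 1)
  if (is.null(dim(E))) E <- matrix(E, nrow = nrow(G))
  pot <- ws_log_potentials(G, params, states)
  emis <- ws_emission_loglik(E, params, states)
  prob <- row_softmax(pot + emis)
  marg <- prob %*% states
  colnames(marg) <- params$signals
  list(states = states, prob = prob, marginals = marg)
}

#' Penalized marginal log-likelihood of observed outlier statuses
#'
#' Evaluates \eqn{\sum_n \log \sum_z P(E^n_{obs} \mid z; \phi) P(z \mid
#' G^n; \beta, \theta) - \lambda(\lVert\beta\rVert^2 +
#' \lVert\theta\rVert^2)} by exact enumeration over the \eqn{2^K} latent
#' configurations.
#'
#' @inheritParams joint_posterior
#' @return a single number.
#' @export
marginal_log_likelihood <- function(G, E, params) {
  K <- length(params$signals)
  states <- ws_states(K)
  G <- to_matrix_rows(G, ncol(params$beta) - 1)
  if (is.null(dim(E))) E <- matrix(E, nrow = nrow(G))
  pot <- ws_log_potentials(G, params, states)
  emis <- ws_emission_loglik(E, params, states)
  ll <- sum(row_logsumexp(pot + emis) - row_logsumexp(pot))
  ll - params$lambda * (sum(params$beta^2) + sum(params$theta[upper.tri(params$theta)]^2) * 2)
}
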