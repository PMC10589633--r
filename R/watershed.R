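#' Fit the multi-omics Watershed model
#'
#' Watershed is a latent-variable model that links the genomic annotations
#' of the rare variants near a gene (G) to latent binary regulatory states
#' (Z, one per omic signal, fully connected by pairwise CRF potentials) and
#' to the observed outlier statuses (E) of those signals. Training maximizes
#' the L2-penalized marginal likelihood of the observed outlier statuses by
#' expectation-maximization with exact inference: with K signals there are
#' only \eqn{2^K} latent configurations, enumerated exactly in both the
#' E-step and the gradient of the M-step.
#'
#' The M-step updates the emission tables \eqn{\phi} in closed form from
#' posterior-weighted category counts with a Dirichlet pseudocount of 1,
#' and maximizes the expected CRF log-likelihood over \eqn{(\beta, \theta)}
#' with a quasi-Newton optimizer using exact analytic gradients. The
#' objective traced (and required to be non-decreasing) is the penalized
#' marginal log-likelihood plus the log-Dirichlet prior implied by the
#' pseudocounts.
#'
#' Initialization is deterministic: per-signal genomic annotation models
#' (\code{\link{fit_gam}}) provide the singleton weights, \eqn{\theta}
#' starts at zero, and the emission tables start from GAM-posterior-weighted
#' category frequencies with pseudocount 1.
#'
#' @param G numeric matrix (instances x annotations), standardized (see
#'   \code{\link{standardize_annotations}}).
#' @param E integer matrix (instances x K signals) of observed outlier
#'   categories (\code{NA} = unmeasured). Directional signals use
#'   categories 1 = under, 2 = none, 3 = over; directionless signals use
#'   1 = none, 2 = outlier (see \code{\link{binarize_outliers}}).
#' @param categories integer vector of emission category counts per signal
#'   (3 for directional, 2 for directionless). Defaults to 3 everywhere
#'   except columns of \code{E} named \code{"splicing"}.
#' @param lambda non-negative L2 penalty on \eqn{\beta} and \eqn{\theta}.
#' @param max_iter,tol EM controls: stop when the relative objective change
#'   drops below \code{tol} or after \code{max_iter} iterations.
#' @param init optional \code{\link{watershed_params}} warm start.
#' @param verbose print the objective each iteration.
#' @return An object of class \code{watershed}: a list with the fitted
#'   \code{params} (\code{\link{watershed_params}}), the per-iteration
#'   objective \code{trace}, the training-data posterior marginals
#'   \code{posterior}, the per-signal initialization GAM fits \code{gam},
#'   and convergence information.
#' @seealso \code{\link{predict.watershed}}, \code{\link{fit_river}},
#'   \code{\link{joint_posterior}}, \code{\link{evaluate_n2}}
#' @export
watershed <- function(G, E, categories = NULL, lambda = 1,
                      max_iter = 300, tol = 1e-6, init = NULL,
                      verbose = FALSE) {
  G <- as.matrix(G)
  E <- as.matrix(E)
  if (nrow(G) != nrow(E)) stop("`G` and `E` must have the same rows")
  K <- ncol(E)
  n <- nrow(G)
  P <- ncol(G)
  signals <- colnames(E)
  if (is.null(signals)) signals <- paste0("signal", seq_len(K))
  if (is.null(categories))
    categories <- ifelse(signals == "splicing", 2L, 3L)
  if (length(categories) != K)
    stop("`categories` must have one entry per signal")
  for (k in seq_len(K)) {
    ok <- is.na(E[, k]) | (E[, k] >= 1 & E[, k] <= categories[k])
    if (!all(ok))
      stop("outlier categories out of range for signal ", signals[k])
  }
  states <- ws_states(K)
  pair_idx <- which(upper.tri(diag(K)), arr.ind = TRUE)

  # --- initialization -------------------------------------------------
  gam_fits <- vector("list", K)
  names(gam_fits) <- signals
  if (is.null(init)) {
    beta <- matrix(0, K, P + 1)
    q1 <- matrix(0.5, n, K) # initial weight on Z_k = 1
    for (k in seq_len(K)) {
      obs <- !is.na(E[, k])
      none_cat <- if (categories[k] == 3) 2L else 1L
      y <- as.numeric(E[obs, k] != none_cat)
      gam_fits[[k]] <- fit_gam(G[obs, , drop = FALSE], y, lambda = lambda)
      beta[k, ] <- gam_fits[[k]]$coef
      q1[obs, k] <- gam_fits[[k]]$fitted
    }
    phi <- ws_update_phi(E, q1, categories)
    theta <- matrix(0, K, K)
    params <- watershed_params(beta, theta, phi, lambda = lambda,
                               signals = signals)
  } else {
    params <- init
    params$lambda <- lambda
    if (ncol(params$beta) != P + 1 || length(params$signals) != K)
      stop("`init` parameters are dimensionally inconsistent with the data")
    for (k in seq_len(K)) {
      obs <- !is.na(E[, k])
      none_cat <- if (categories[k] == 3) 2L else 1L
      y <- as.numeric(E[obs, k] != none_cat)
      gam_fits[[k]] <- fit_gam(G[obs, , drop = FALSE], y, lambda = lambda)
    }
  }

  # --- EM -------------------------------------------------------------
  trace <- numeric(0)
  obj_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step: exact posteriors over the 2^K states
    pot <- ws_log_potentials(G, params, states)
    emis <- ws_emission_loglik(E, params, states)
    q <- row_softmax(pot + emis)
    qmarg <- q %*% states

    # objective: penalized marginal loglik + emission log-prior
    obj <- sum(row_logsumexp(pot + emis) - row_logsumexp(pot)) -
      lambda * ws_penalty(params) + ws_phi_logprior(params$phi)
    trace <- c(trace, obj)
    if (verbose) message(sprintf("iter %3d  objective %.6f", iter, obj))
    if (obj < obj_old - 1e-8 * (1 + abs(obj_old)))
      stop("EM objective decreased (", obj_old, " -> ", obj,
           "); this indicates an inference bug")
    if (is.finite(obj_old) &&
        abs(obj - obj_old) < tol * (1 + abs(obj_old))) {
      converged <- TRUE
      break
    }
    obj_old <- obj

    # M-step: closed-form phi, quasi-Newton (beta, theta)
    phi <- ws_update_phi(E, qmarg, categories)
    bt <- ws_optimize_crf(G, q, qmarg, states, pair_idx, params, lambda)
    params <- watershed_params(bt$beta, bt$theta, phi, lambda = lambda,
                               signals = signals)
  }

  post <- joint_posterior(G, E, params)
  structure(list(params = params, trace = trace, niter = length(trace),
                 converged = converged, posterior = post$marginals,
                 gam = gam_fits, categories = categories,
                 signals = signals, n = n, n_annotations = P,
                 lambda = lambda, call = match.call()),
            class = "watershed")
}

# L2 penalty term: ||beta||^2 + ||theta||^2 (Frobenius, symmetric theta).
ws_penalty <- function(params) {
  sum(params$beta^2) + 2 * sum(params$theta[upper.tri(params$theta)]^2)
}

# log-Dirichlet(2,...,2) prior on the emission tables (pseudocount 1),
# the term that makes the pseudocounted phi update a proper MAP M-step.
ws_phi_logprior <- function(phi) {
  sum(vapply(phi, function(tab) sum(log(tab)), numeric(1)))
}

# Closed-form emission update: posterior-weighted category counts with
# Dirichlet pseudocount 1, per signal and latent state.
ws_update_phi <- function(E, qmarg, categories) {
  K <- ncol(E)
  lapply(seq_len(K), function(k) {
    C <- categories[k]
    obs <- !is.na(E[, k])
    w1 <- qmarg[obs, k]
    w0 <- 1 - w1
    e <- E[obs, k]
    c1 <- c0 <- rep(1, C) # pseudocount
    for (cc in seq_len(C)) {
      sel <- e == cc
      c0[cc] <- c0[cc] + sum(w0[sel])
      c1[cc] <- c1[cc] + sum(w1[sel])
    }
    rbind(c0 / sum(c0), c1 / sum(c1))
  })
}

# M-step over (beta, theta): maximize the expected CRF log-likelihood
#   sum_n sum_s q_ns log P(s | G_n) - lambda * penalty
# with exact analytic gradients; concave, solved by BFGS.
ws_optimize_crf <- function(G, q, qmarg, states, pair_idx, params, lambda) {
  K <- ncol(qmarg)
  P <- ncol(G)
  npair <- nrow(pair_idx)
  # state pair products z_sk * z_sl for each pair (2^K x npair)
  zz <- if (npair > 0)
    states[, pair_idx[, 1], drop = FALSE] * states[, pair_idx[, 2], drop = FALSE]
  else matrix(0, nrow(states), 0)
  # sufficient statistics from the E-step posteriors (fixed during M-step)
  S0 <- colSums(qmarg)                       # K
  SG <- crossprod(G, qmarg)                  # P x K
  Sp <- if (npair > 0) colSums(q %*% zz) else numeric(0)

  unpack <- function(par) {
    beta <- matrix(par[seq_len(K * (P + 1))], K, P + 1)
    theta <- matrix(0, K, K)
    if (npair > 0) {
      tv <- par[K * (P + 1) + seq_len(npair)]
      theta[pair_idx] <- tv
      theta <- theta + t(theta)
    }
    list(beta = beta, theta = theta)
  }
  fn <- function(par) {
    pp <- unpack(par)
    tmp <- params; tmp$beta <- pp$beta; tmp$theta <- pp$theta
    pot <- ws_log_potentials(G, tmp, states)
    lin <- sum(pp$beta[, 1] * S0) + sum(pp$beta[, -1, drop = FALSE] * t(SG)) +
      if (npair > 0) sum(pp$theta[pair_idx] * Sp) else 0
    lin - sum(row_logsumexp(pot)) -
      lambda * (sum(pp$beta^2) + 2 * sum(pp$theta[pair_idx]^2))
  }
  gr <- function(par) {
    pp <- unpack(par)
    tmp <- params; tmp$beta <- pp$beta; tmp$theta <- pp$theta
    pot <- ws_log_potentials(G, tmp, states)
    pr <- row_softmax(pot)
    pmarg <- pr %*% states
    g_b0 <- S0 - colSums(pmarg) - 2 * lambda * pp$beta[, 1]
    g_bs <- SG - crossprod(G, pmarg) - 2 * lambda * t(pp$beta[, -1, drop = FALSE])
    g_t <- if (npair > 0)
      Sp - colSums(pr %*% zz) - 4 * lambda * pp$theta[pair_idx]
    else numeric(0)
    c(as.vector(cbind(g_b0, t(g_bs))), g_t)
  }
  par0 <- c(as.vector(params$beta),
            if (npair > 0) params$theta[pair_idx] else numeric(0))
  # generalized EM: a bounded quasi-Newton improvement of the concave
  # expected CRF log-likelihood keeps the EM objective non-decreasing
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(fnscale = -1, maxit = 40,
                                     reltol = 1e-10))
  unpack(opt$par)
}

#' Fit a single-signal RIVER model
#'
#' RIVER is the single-omic special case of Watershed: the identical
#' latent-variable machinery run with K = 1 signal (no pairwise
#' \eqn{\theta} weights exist).
#'
#' @param G annotation matrix (instances x annotations), standardized.
#' @param e integer vector of observed outlier categories for the one
#'   signal (\code{NA} = unmeasured).
#' @param n_categories 3 for a directional signal, 2 for a directionless
#'   one.
#' @param ... passed to \code{\link{watershed}}.
#' @return a \code{watershed} object with K = 1.
#' @export
fit_river <- function(G, e, n_categories = 3, ...) {
  E <- matrix(as.integer(e), ncol = 1)
  watershed(G, E, categories = n_categories, ...)
}

#' @export
print.watershed <- function(x, ...) {
  cat("Multi-omics Watershed model\n")
  cat("  signals:    ", paste(x$signals, collapse = ", "), "\n")
  cat("  instances:  ", x$n, "  annotations: ", x$n_annotations, "\n")
  cat("  lambda:     ", x$lambda, "\n")
  cat("  EM:         ", x$niter, "iterations,",
      if (x$converged) "converged" else "not converged", "\n")
  cat("  objective:  ", format(utils::tail(x$trace, 1), digits = 8), "\n")
  invisible(x)
}

#' @export
summary.watershed <- function(object, ...) {
  ans <- list(
    signals = object$signals,
    n = object$n,
    n_annotations = object$n_annotations,
    niter = object$niter,
    converged = object$converged,
    objective = utils::tail(object$trace, 1),
    theta = object$params$theta,
    top_annotations = lapply(seq_along(object$signals), function(k) {
      w <- object$params$beta[k, -1]
      names(w) <- colnames(object$params$beta)[-1]
      if (is.null(names(w))) names(w) <- paste0("annot", seq_along(w))
      sort(abs(w), decreasing = TRUE)[seq_len(min(5, length(w)))]
    }),
    phi = object$params$phi
  )
  names(ans$top_annotations) <- object$signals
  class(ans) <- "summary.watershed"
  ans
}

#' @export
print.summary.watershed <- function(x, ...) {
  cat("Multi-omics Watershed model summary\n")
  cat(sprintf("  %d instances, %d annotations, %d signals; EM %s in %d iterations\n",
              x$n, x$n_annotations, length(x$signals),
              if (x$converged) "converged" else "stopped", x$niter))
  cat("  final penalized objective:", format(x$objective, digits = 8), "\n\n")
  cat("Pairwise latent edge weights (theta):\n")
  print(round(x$theta, 3))
  cat("\nTop annotation weights (|beta|) per signal:\n")
  for (s in names(x$top_annotations)) {
    cat("  ", s, ": ",
        paste(names(x$top_annotations[[s]]),
              round(x$top_annotations[[s]], 2),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.watershed <- function(object, ...) {
  list(beta = object$params$beta, theta = object$params$theta,
       phi = object$params$phi)
}

#' @export
logLik.watershed <- function(object, ...) {
  val <- utils::tail(object$trace, 1)
  attr(val, "df") <- length(object$params$beta) +
    sum(upper.tri(object$params$theta)) +
    sum(vapply(object$params$phi, length, numeric(1))) -
    2 * length(object$params$phi)
  class(val) <- "logLik"
  val
}

#' Posterior predictions from a fitted Watershed model
#'
#' @param object a fitted \code{\link{watershed}} model.
#' @param G annotation matrix for the instances to score (standardized on
#'   the training scale).
#' @param E optional outlier-status evidence matrix (instances x K,
#'   \code{NA} = unmeasured). When omitted the CRF prior marginals are
#'   returned (no evidence).
#' @param type \code{"marginal"} for the instances x K matrix of
#'   \eqn{P(Z_k = 1 \mid G, E)}, \code{"state"} for the full posterior
#'   over all \eqn{2^K} latent configurations.
#' @param ... unused.
#' @return a matrix of posterior probabilities.
#' @export
predict.watershed <- function(object, G, E = NULL,
                              type = c("marginal", "state"), ...) {
  type <- match.arg(type)
  params <- object$params
  G <- to_matrix_rows(G, ncol(params$beta) - 1)
  if (is.null(E))
    E <- matrix(NA_integer_, nrow(G), length(params$signals))
  res <- joint_posterior(G, E, params)
  if (type == "marginal") res$marginals else res$prob
}

#' Simulate outlier statuses from a fitted Watershed model
#'
#' Draws latent regulatory states from the fitted CRF prior at the supplied
#' annotation matrix and emits outlier categories from the fitted emission
#' tables — the model's own generative direction.
#'
#' @param object a fitted \code{\link{watershed}} model.
#' @param nsim number of replicate E matrices to draw.
#' @param seed optional integer seed.
#' @param G annotation matrix to condition on (defaults cannot be stored;
#'   supply the matrix the draws should condition on).
#' @param ... unused.
#' @return a list of \code{nsim} lists, each with \code{Z} (latent 0/1
#'   matrix) and \code{E} (emitted category matrix).
#' @export
simulate.watershed <- function(object, nsim = 1, seed = NULL, G, ...) {
  if (!is.null(seed)) set.seed(seed)
  params <- object$params
  pr <- crf_prior(G, params)
  n <- nrow(pr$prob)
  K <- length(params$signals)
  replicate(nsim, simplify = FALSE, {
    sidx <- apply(pr$prob, 1, function(p) sample.int(nrow(pr$states), 1, prob = p))
    Z <- pr$states[sidx, , drop = FALSE]
    E <- matrix(NA_integer_, n, K, dimnames = list(NULL, params$signals))
    for (k in seq_len(K)) {
      tab <- params$phi[[k]]
      E[, k] <- vapply(Z[, k] + 1, function(z)
        sample.int(ncol(tab), 1, prob = tab[z, ]), integer(1))
    }
    list(Z = Z, E = E)
  })
}

#' Plot a fitted Watershed model
#'
#' Displays the pairwise latent edge weights as an image and the largest
#' annotation weights per signal.
#'
#' @param x a fitted \code{\link{watershed}} model.
#' @param which \code{"theta"}, \code{"beta"} or \code{"objective"}.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.watershed <- function(x, which = c("theta", "beta", "objective"), ...) {
  which <- match.arg(which)
  if (which == "theta") {
    K <- length(x$signals)
    graphics::image(seq_len(K), seq_len(K), t(x$params$theta[K:1, ]),
                    axes = FALSE, xlab = "", ylab = "",
                    main = "Latent pairwise edge weights", ...)
    graphics::axis(1, at = seq_len(K), labels = x$signals, las = 2)
    graphics::axis(2, at = seq_len(K), labels = rev(x$signals), las = 2)
  } else if (which == "beta") {
    w <- t(abs(x$params$beta[, -1, drop = FALSE]))
    graphics::matplot(w, type = "h", lty = 1, xlab = "annotation",
                      ylab = "|weight|", main = "Annotation weights", ...)
    graphics::legend("topright", legend = x$signals, col = seq_along(x$signals),
                     lty = 1, bty = "n")
  } else {
    graphics::plot(seq_along(x$trace), x$trace, type = "b",
                   xlab = "EM iteration", ylab = "penalized objective", ...)
  }
  invisible(x)
}
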