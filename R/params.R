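#' Watershed model parameters
#'
#' Container for the parameters of the multi-omics Watershed conditional
#' random field: per-signal singleton weights (intercept plus one weight per
#' genomic annotation), symmetric pairwise weights coupling the latent
#' regulatory states of the signals, and per-signal emission tables giving
#' the probability of each observed outlier category conditional on the
#' latent state.
#'
#' Signals come in two flavours. Directional signals (expression,
#' methylation, protein) emit three categories, \code{under}, \code{none},
#' \code{over}; splicing outliers carry no direction and emit two
#' categories, \code{none} and \code{outlier}.
#'
#' @param beta numeric matrix, K x (P + 1). Row k holds the singleton
#'   potential weights of signal k: first column the intercept, remaining
#'   columns the weights on the P standardized genomic annotations.
#' @param theta numeric K x K symmetric matrix with zero diagonal; pairwise
#'   potential weights between latent signals.
#' @param phi list of K emission tables. Element k is a 2 x C_k matrix whose
#'   rows (latent state 0, latent state 1) sum to one over the C_k observed
#'   categories of signal k.
#' @param lambda non-negative L2 penalty weight applied to \code{beta} and
#'   \code{theta} during training.
#' @param signals character vector of signal names (defaults to the four
#'   omic signals).
#'
#' @return An object of class \code{watershed_params}.
#' @export
watershed_params <- function(beta, theta, phi, lambda = 1,
                             signals = NULL) {
  beta <- as.matrix(beta)
  theta <- as.matrix(theta)
  K <- nrow(beta)
  if (is.null(signals)) {
    signals <- if (!is.null(rownames(beta))) rownames(beta)
               else paste0("signal", seq_len(K))
  }
  if (length(signals) != K)
    stop("`signals` must name one entry per row of `beta`")
  if (!all(dim(theta) == c(K, K)))
    stop("`theta` must be ", K, " x ", K, " to match `beta`")
  if (max(abs(theta - t(theta))) > 1e-12)
    stop("`theta` must be symmetric")
  if (any(diag(theta) != 0))
    stop("`theta` must have a zero diagonal")
  if (!is.list(phi) || length(phi) != K)
    stop("`phi` must be a list with one emission table per signal")
  phi <- lapply(phi, as.matrix)
  for (k in seq_len(K)) {
    if (nrow(phi[[k]]) != 2)
      stop("emission table for signal ", signals[k],
           " must have two rows (latent state 0 and 1)")
    if (any(phi[[k]] < 0))
      stop("emission probabilities must be non-negative")
    if (max(abs(rowSums(phi[[k]]) - 1)) > 1e-8)
      stop("emission table rows for signal ", signals[k], " must sum to 1")
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("`lambda` must be a single non-negative number")
  rownames(beta) <- signals
  dimnames(theta) <- list(signals, signals)
  names(phi) <- signals
  structure(list(beta = beta, theta = theta, phi = phi,
                 lambda = lambda, signals = signals),
            class = "watershed_params")
}

#' @export
print.watershed_params <- function(x, ...) {
  K <- length(x$signals)
  P <- ncol(x$beta) - 1
  cat("Watershed parameters:", K, "signals,", P, "annotations\n")
  cat("  signals:", paste(x$signals, collapse = ", "), "\n")
  cat("  lambda:", x$lambda, "\n")
  cat("  pairwise weights (theta):\n")
  print(round(x$theta, 3))
  invisible(x)
}

# Emission category labels for a signal given its table width.
signal_categories <- function(ncat) {
  if (ncat == 3) c("under", "none", "over")
  else if (ncat == 2) c("none", "outlier")
  else stop("signals must have 2 or 3 emission categories")
}

#' Default generating parameters for simulated cohorts
#'
#' Builds a \code{\link{watershed_params}} object used as the ground truth
#' of the cohort simulator. The defaults encode the qualitative structure
#' the model is designed to detect: a sparse set of informative annotations,
#' stronger coupling between expression and the methylation/splicing
#' signals than between protein and the rest, and emission tables under
#' which a latent regulatory effect raises the outlier probability by an
#' order of magnitude.
#'
#' @param n_signals number of omic signals (4 = expression, methylation,
#'   splicing, protein; the splicing slot, position 3, is directionless).
#' @param n_annotations number of genomic annotations P.
#' @param n_informative how many leading annotations carry true weight.
#' @param effect_size singleton weight placed on each informative
#'   annotation (on the standardized scale).
#' @param lambda L2 penalty stored with the parameters.
#' @return a \code{watershed_params} object.
#' @export
default_sim_params <- function(n_signals = 4, n_annotations = 10,
                               n_informative = 3, effect_size = 1.5,
                               lambda = 1) {
  K <- n_signals
  signals <- if (K == 4) c("expression", "methylation", "splicing", "protein")
             else paste0("signal", seq_len(K))
  beta <- matrix(0, K, n_annotations + 1)
  beta[, 1] <- -2
  ninf <- min(n_informative, n_annotations)
  if (ninf > 0) beta[, 1 + seq_len(ninf)] <- effect_size
  theta <- matrix(0.2, K, K)
  if (K >= 2) theta[1, 2] <- theta[2, 1] <- 1.0
  if (K >= 3) theta[1, 3] <- theta[3, 1] <- 0.9
  if (K >= 4) {
    theta[1, 4] <- theta[4, 1] <- 0.3
    theta[2, 4] <- theta[4, 2] <- 0.2
    theta[3, 4] <- theta[4, 3] <- 0.2
  }
  diag(theta) <- 0
  phi <- lapply(seq_len(K), function(k) {
    if (K == 4 && k == 3) {
      # splicing: directionless two-category emissions
      rbind(c(0.97, 0.03), c(0.35, 0.65))
    } else {
      rbind(c(0.025, 0.95, 0.025), c(0.35, 0.30, 0.35))
    }
  })
  watershed_params(beta, theta, phi, lambda = lambda, signals = signals)
}
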