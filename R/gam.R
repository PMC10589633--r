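#' Genomic annotation model (GAM): L2-penalized logistic regression
#'
#' Predicts binary outlier status of a (gene, individual) instance from its
#' aggregated genomic annotations alone. The slopes carry an L2 (ridge)
#' penalty; the intercept is unpenalized. Fitting is by Newton-Raphson on
#' the penalized log-likelihood
#' \eqn{\ell(\beta) - \lambda \sum_j \beta_j^2}.
#'
#' @param G numeric matrix (instances x annotations), standardized.
#' @param y binary 0/1 outlier labels, one per row of \code{G}.
#' @param lambda non-negative L2 penalty on the slope coefficients.
#' @param max_iter,tol Newton iteration controls; convergence is declared
#'   when the penalized objective changes by less than \code{tol}.
#' @return object of class \code{rc_gam} with elements \code{coef}
#'   (intercept first), \code{fitted}, \code{objective}, \code{lambda},
#'   \code{converged}.
#' @export
fit_gam <- function(G, y, lambda = 1, max_iter = 100, tol = 1e-10) {
  G <- as.matrix(G)
  y <- as.numeric(y)
  if (length(y) != nrow(G)) stop("`y` must have one label per row of `G`")
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1")
  if (all(y == 1) || all(y == 0))
    stop("labels are single-class; the GAM needs both outliers and non-outliers")
  X <- cbind(1, G)
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1))
  beta <- numeric(p)
  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(pen * b^2)
  }
  f_old <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    g <- drop(crossprod(X, y - mu)) - 2 * pen * beta
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(2 * pen, p)
    step <- solve(H, g)
    # damped Newton: halve until the objective does not decrease
    s <- 1
    repeat {
      b_new <- beta + s * step
      f_new <- obj(b_new)
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      s <- s / 2
      if (s < 1e-10) { b_new <- beta; f_new <- f_old; break }
    }
    beta <- b_new
    if (abs(f_new - f_old) < tol) { converged <- TRUE; f_old <- f_new; break }
    f_old <- f_new
  }
  structure(list(coef = beta, fitted = plogis(drop(X %*% beta)),
                 objective = f_old, lambda = lambda, converged = converged),
            class = "rc_gam")
}

#' @export
predict.rc_gam <- function(object, newdata = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- qlogis(object$fitted)
  } else {
    X <- cbind(1, as.matrix(newdata))
    eta <- drop(X %*% object$coef)
  }
  if (type == "response") plogis(eta) else eta
}

#' @export
print.rc_gam <- function(x, ...) {
  cat("Genomic annotation model (L2-penalized logistic regression)\n")
  cat("  annotations:", length(x$coef) - 1,
      " lambda:", x$lambda,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.rc_gam <- function(object, ...) object$coef
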