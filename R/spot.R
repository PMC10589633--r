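# Splicing-outlier detection (SPOT): per-cluster Dirichlet-Multinomial
# fit, Mahalanobis-distance scoring of each individual's junction-usage
# proportions, sampling-based empirical p-values, and aggregation of
# cluster p-values to genes.

#' Filter exon-exon junctions in a cluster
#'
#' Removes junctions with low support while retaining rare junctions:
#' a junction is kept only if some sample has at least
#' \code{min_max_reads} reads on it, and at least
#' \code{support_fraction} of samples have more than
#' \code{min_support_reads} reads. Clusters reduced below two junctions
#' are unusable and returned as \code{NULL}.
#'
#' @param counts integer matrix (individuals x junctions).
#' @param min_max_reads per-junction maximum-read requirement
#'   (default 15).
#' @param min_support_reads,support_fraction read support rule (default:
#'   more than 3 reads in at least 40\% of samples).
#' @return the filtered count matrix, or \code{NULL} when fewer than two
#'   junctions survive; removed junction names in the \code{"removed"}
#'   attribute.
#' @export
filter_junctions <- function(counts, min_max_reads = 15,
                             min_support_reads = 3,
                             support_fraction = 0.4) {
  counts <- as.matrix(counts)
  keep <- apply(counts, 2, max) >= min_max_reads &
    colMeans(counts > min_support_reads) >= support_fraction
  removed <- colnames(counts)[!keep]
  if (sum(keep) < 2) {
    message("cluster dropped: fewer than two junctions pass the filters")
    return(NULL)
  }
  out <- counts[, keep, drop = FALSE]
  attr(out, "removed") <- removed
  out
}

# Dirichlet-Multinomial log-likelihood (multinomial coefficient omitted;
# it is constant in alpha).
dm_loglik <- function(counts, alpha) {
  n <- rowSums(counts)
  a0 <- sum(alpha)
  sum(lgamma(a0) - lgamma(n + a0)) +
    sum(lgamma(sweep(counts, 2, alpha, "+")) ) -
    nrow(counts) * sum(lgamma(alpha))
}

#' Fit a Dirichlet-Multinomial distribution to junction counts
#'
#' Maximum-likelihood estimation of the concentration vector by the
#' digamma fixed-point iteration, initialized by moment matching.
#' Convergence is declared when the relative log-likelihood change falls
#' below \code{tol}.
#'
#' @param counts integer matrix (individuals x junctions, at least 2
#'   junctions); rows with zero depth are ignored, and at least 10
#'   individuals with positive depth are required.
#' @param max_iter,tol iteration controls (defaults 500, 1e-8).
#' @return object of class \code{dm_fit}: \code{alpha} (strictly
#'   positive), \code{loglik}, \code{converged}, \code{n_iter},
#'   \code{mean} (fitted junction-usage proportions).
#' @export
fit_dm <- function(counts, max_iter = 500, tol = 1e-8) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2)
    stop("a Dirichlet-Multinomial fit needs at least two junctions")
  depth <- rowSums(counts)
  counts <- counts[depth > 0, , drop = FALSE]
  if (nrow(counts) < 10)
    stop("fewer than 10 individuals with positive depth")
  if (any(apply(counts, 2, max) == 0))
    stop("all-zero junction; filter junctions before fitting")
  n <- rowSums(counts)
  props <- counts / n
  # moment-matched initializer (Ronning-style precision estimate)
  pbar <- colMeans(props)
  v <- apply(props, 2, stats::var)
  ok <- v > 0 & pbar > 0 & pbar < 1
  prec <- if (any(ok)) max(mean(pbar[ok] * (1 - pbar[ok]) / v[ok]) - 1, 1)
          else ncol(counts)
  alpha <- pmax(pbar * prec, 1e-3)
  ll_old <- dm_loglik(counts, alpha)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    a0 <- sum(alpha)
    num <- colSums(digamma(sweep(counts, 2, alpha, "+"))) -
      nrow(counts) * digamma(alpha)
    den <- sum(digamma(n + a0)) - nrow(counts) * digamma(a0)
    alpha_new <- alpha * num / den
    alpha_new <- pmax(alpha_new, 1e-10)
    ll_new <- dm_loglik(counts, alpha_new)
    if (!is.finite(ll_new)) break
    alpha <- alpha_new
    if (abs(ll_new - ll_old) < tol * (1 + abs(ll_old))) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  structure(list(alpha = alpha, loglik = ll_old, converged = converged,
                 n_iter = it, mean = alpha / sum(alpha)),
            class = "dm_fit")
}

#' @export
print.dm_fit <- function(x, ...) {
  cat("Dirichlet-Multinomial fit:", length(x$alpha), "junctions\n")
  cat("  alpha:", paste(round(x$alpha, 3), collapse = ", "), "\n")
  cat("  loglik:", format(x$loglik, digits = 8),
      " converged:", x$converged, "(", x$n_iter, "iterations )\n")
  invisible(x)
}

# DM covariance of junction proportions at a given depth, reduced to the
# first J-1 coordinates (the full simplex covariance is singular).
dm_prop_cov <- function(alpha, depth) {
  a0 <- sum(alpha)
  mu <- alpha / a0
  J <- length(alpha)
  full <- (diag(mu) - tcrossprod(mu)) / depth * (depth + a0) / (1 + a0)
  full[-J, -J, drop = FALSE]
}

#' Mahalanobis distance of junction usage from the fitted DM mean
#'
#' Distance of each individual's junction-proportion vector from the
#' fitted Dirichlet-Multinomial mean, using the DM covariance of
#' proportions at that individual's sequencing depth, reduced to J - 1
#' coordinates to avoid the simplex singularity.
#'
#' @param fit a \code{\link{fit_dm}} object.
#' @param counts integer matrix (individuals x junctions) on the same
#'   junctions as the fit; every scored row needs depth >= 1.
#' @return non-negative numeric vector of distances (NA for zero-depth
#'   rows).
#' @export
dm_mahalanobis <- function(fit, counts) {
  counts <- as.matrix(counts)
  J <- length(fit$alpha)
  if (ncol(counts) != J)
    stop("count matrix junctions do not match the fitted alpha")
  depth <- rowSums(counts)
  out <- rep(NA_real_, nrow(counts))
  mu <- fit$mean[-J]
  for (d in unique(depth[depth > 0])) {
    sel <- which(depth == d)
    S <- dm_prop_cov(fit$alpha, d)
    Sinv <- tryCatch(solve(S), error = function(e)
      stop("singular proportion covariance for this cluster"))
    dmat <- sweep(counts[sel, -J, drop = FALSE] / d, 2, mu)
    out[sel] <- sqrt(pmax(rowSums((dmat %*% Sinv) * dmat), 0))
  }
  out
}

# Draw `n` DM count vectors at a fixed depth (sequential-binomial
# multinomial on Dirichlet-sampled proportions; vectorized over draws).
dm_sample_counts <- function(n, alpha, depth) {
  J <- length(alpha)
  p <- rdirichlet_mat(n, alpha)
  counts <- matrix(0L, n, J)
  remaining <- rep(depth, n)
  tailp <- t(apply(p[, J:1, drop = FALSE], 1, cumsum))[, J:1, drop = FALSE]
  for (j in seq_len(J - 1)) {
    pj <- ifelse(tailp[, j] > 0, p[, j] / tailp[, j], 0)
    pj <- pmin(pmax(pj, 0), 1)
    counts[, j] <- stats::rbinom(n, remaining, pj)
    remaining <- remaining - counts[, j]
  }
  counts[, J] <- remaining
  counts
}

#' Empirical splicing-outlier p-values for one cluster
#'
#' Compares each individual's observed Mahalanobis distance against
#' random samples from the fitted Dirichlet-Multinomial drawn at that
#' individual's own sequencing depth (the null distance distribution
#' depends on depth). Samples are drawn once per depth class. The
#' add-one correction keeps p-values strictly positive:
#' \eqn{p = (1 + \#\{MD_{samp} \ge MD_{obs}\}) / (n_{samples} + 1)}.
#'
#' @param fit a \code{\link{fit_dm}} object.
#' @param counts integer matrix (individuals x junctions).
#' @param n_samples null draws per depth class (default 10000; fewer
#'   than 100 triggers a warning).
#' @param seed integer seed for the null draws.
#' @return data.frame with \code{md} and \code{p} per individual
#'   (zero-depth individuals are \code{NA}).
#' @export
spot_empirical_pvalues <- function(fit, counts, n_samples = 10000,
                                   seed = 1) {
  if (n_samples < 100)
    warning("fewer than 100 null samples gives coarse empirical p-values")
  counts <- as.matrix(counts)
  set.seed(seed)
  depth <- rowSums(counts)
  md <- dm_mahalanobis(fit, counts)
  p <- rep(NA_real_, nrow(counts))
  for (d in unique(depth[depth > 0])) {
    sel <- which(depth == d)
    samp <- dm_sample_counts(n_samples, fit$alpha, d)
    md_null <- dm_mahalanobis(fit, samp)
    p[sel] <- vapply(md[sel], function(m)
      (1 + sum(md_null >= m)) / (n_samples + 1), numeric(1))
  }
  data.frame(individual = rownames(counts) %||% seq_len(nrow(counts)),
             md = md, p = p, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate cluster p-values to a gene-level p-value
#'
#' With c clusters mapped to a gene, the minimum cluster p-value
#' \eqn{p_m} is corrected for having taken the best of c independent
#' uniforms: \eqn{P_{gene} = 1 - (1 - p_m)^c}.
#'
#' @param cluster_p numeric vector of per-cluster empirical p-values for
#'   one (gene, individual).
#' @return list with \code{p_m}, \code{c}, \code{p_gene} (all \code{NA}
#'   when no cluster p-value is available).
#' @export
gene_level_pvalue <- function(cluster_p) {
  cluster_p <- cluster_p[!is.na(cluster_p)]
  if (length(cluster_p) == 0)
    return(list(p_m = NA_real_, c = 0L, p_gene = NA_real_))
  p_m <- min(cluster_p)
  c <- length(cluster_p)
  list(p_m = p_m, c = c, p_gene = 1 - (1 - p_m)^c)
}

#' Convert a splicing p-value to a non-negative Z-score
#'
#' One-sided upper-tail normal conversion, \eqn{Z = \Phi^{-1}(1 - p)},
#' floored at zero for \eqn{p \ge 0.5}: splicing outliers carry no
#' direction, so the reported Z is non-negative.
#'
#' @param p p-values in (0, 1].
#' @return non-negative Z-scores.
#' @export
pvalue_to_z <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  pmax(stats::qnorm(1 - p), 0)
}
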