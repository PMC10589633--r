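# Synthetic-cohort simulator.
#
# Restricted cohort data cannot be redistributed, so every downstream
# module is exercised on simulated cohorts with the same statistical
# structure: annotation vectors with an informative subset, latent
# regulatory states drawn from a known CRF, categorical outlier statuses
# emitted from known tables, two-exam correlated Z-score matrices with
# injected outliers, Dirichlet-Multinomial junction-cluster counts, and a
# rare-variant table with shared-variant (N2) structure.

#' Configuration for a simulated multi-omics cohort
#'
#' @param n_individuals,n_genes cohort dimensions; instances are the full
#'   (gene, individual) grid.
#' @param n_signals number of omic signals (default 4: expression,
#'   methylation, splicing, protein; splicing is directionless).
#' @param n_annotations number of genomic annotations P.
#' @param true_params generating \code{\link{watershed_params}}; defaults
#'   to \code{\link{default_sim_params}}.
#' @param exam_correlation cross-exam Pearson correlation of the omics
#'   Z-score matrices, in [0, 1]. Default 0.67, the highest per-signal
#'   cross-exam correlation the study design anticipates (plasma
#'   proteome).
#' @param outlier_inject_rate fraction of (feature, individual) cells
#'   receiving an injected outlier effect in the omics matrices.
#' @param outlier_magnitude Z-shift applied to injected outliers (both
#'   exams).
#' @param missing_rate per-signal probability that an instance's outlier
#'   status is unmeasured.
#' @param n2_fraction fraction of instances duplicated into N2 pairs
#'   (shared variant set, shared latent state, independent emissions).
#' @param binary_fraction fraction of annotations that are binary flags
#'   (Bernoulli rate 0.3); the rest are standard normal scores.
#' @param mean_depth mean sequencing depth (Poisson) for junction
#'   clusters.
#' @param seed master integer seed; all sub-streams derive from it, so an
#'   identical configuration reproduces the cohort bit for bit.
#' @return validated object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_individuals, n_genes, n_signals = 4,
                          n_annotations = 10, true_params = NULL,
                          exam_correlation = 0.67,
                          outlier_inject_rate = 0.01,
                          outlier_magnitude = 5,
                          missing_rate = 0.1, n2_fraction = 0.05,
                          binary_fraction = 0.5, mean_depth = 200,
                          seed = 1) {
  counts <- c(n_individuals = n_individuals, n_genes = n_genes,
              n_signals = n_signals, n_annotations = n_annotations)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be positive integers")
  fracs <- c(exam_correlation = exam_correlation,
             outlier_inject_rate = outlier_inject_rate,
             missing_rate = missing_rate, n2_fraction = n2_fraction,
             binary_fraction = binary_fraction)
  bad <- fracs < 0 | fracs > 1
  if (any(bad))
    stop("fraction parameters must lie in [0, 1]: ",
         paste(names(fracs)[bad], collapse = ", "))
  if (is.null(true_params))
    true_params <- default_sim_params(n_signals, n_annotations)
  if (!inherits(true_params, "watershed_params"))
    stop("`true_params` must be a watershed_params object")
  if (ncol(true_params$beta) != n_annotations + 1)
    stop("`true_params` beta has ", ncol(true_params$beta) - 1,
         " annotation weights but n_annotations = ", n_annotations)
  if (length(true_params$signals) != n_signals)
    stop("`true_params` is for ", length(true_params$signals),
         " signals but n_signals = ", n_signals)
  structure(list(n_individuals = n_individuals, n_genes = n_genes,
                 n_signals = n_signals, n_annotations = n_annotations,
                 true_params = true_params,
                 exam_correlation = exam_correlation,
                 outlier_inject_rate = outlier_inject_rate,
                 outlier_magnitude = outlier_magnitude,
                 missing_rate = missing_rate, n2_fraction = n2_fraction,
                 binary_fraction = binary_fraction,
                 mean_depth = mean_depth, seed = seed),
            class = "cohort_config")
}

# Sample one categorical draw per row from a matrix of row-wise
# probabilities (n x C). Vectorized inverse-CDF.
sample_rows <- function(prob) {
  S <- ncol(prob)
  cum <- prob %*% upper.tri(diag(S), diag = TRUE) # row-wise cumulative sums
  u <- stats::runif(nrow(prob))
  as.integer(rowSums(cum < u) + 1L)
}

#' Simulate Watershed (gene, individual) instances from a known CRF
#'
#' Generates the full instance grid in the model's generative direction:
#' annotations G are drawn (binary + continuous mix, then standardized),
#' latent states Z are sampled from the exact CRF prior
#' \eqn{P(z \mid G; \beta, \theta)}, and outlier statuses E are emitted
#' from the true tables \eqn{\phi_k(\cdot \mid Z_k)}. Median Z-scores are
#' drawn consistently with E (tail-uniform construction), a configurable
#' fraction of E entries is set to missing per signal, and a fraction of
#' instances is duplicated into N2 pairs that share the annotation
#' vector, the latent state, and one rare variant, with independent
#' emission draws.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return object of class \code{simulated_cohort}: list with
#'   \code{instances} (gene, individual), standardized annotations
#'   \code{G}, raw annotations \code{G_raw}, emitted statuses \code{E},
#'   \code{median_z}, the rare-variant table \code{variants}, the N2
#'   pairing \code{n2_pairs}, and \code{truth} (latent \code{Z} and the
#'   generating parameters).
#' @export
simulate_watershed_instances <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  params <- config$true_params
  K <- config$n_signals
  P <- config$n_annotations
  inds <- sprintf("I%04d", seq_len(config$n_individuals))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  grid <- expand.grid(individual = inds, gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)

  n_bin <- floor(config$binary_fraction * P)
  G_raw <- cbind(
    matrix(stats::rbinom(n * n_bin, 1, 0.3), n, n_bin),
    matrix(stats::rnorm(n * (P - n_bin)), n, P - n_bin)
  )
  colnames(G_raw) <- paste0("annot", seq_len(P))
  G <- standardize_annotations(G_raw)

  pr <- crf_prior(G, params)
  sidx <- sample_rows(pr$prob)
  Z <- pr$states[sidx, , drop = FALSE]
  colnames(Z) <- params$signals

  categories <- vapply(params$phi, ncol, integer(1))
  E <- matrix(NA_integer_, n, K, dimnames = list(NULL, params$signals))
  medz <- matrix(NA_real_, n, K, dimnames = list(NULL, params$signals))
  for (k in seq_len(K)) {
    tab <- params$phi[[k]]
    E[, k] <- sample_rows(tab[Z[, k] + 1, , drop = FALSE])
    medz[, k] <- draw_z_for_category(E[, k], categories[k])
  }

  # N2 duplication: partner instances share G, the latent state and one
  # rare variant; their emissions and Z-scores are fresh draws.
  n2 <- round(config$n2_fraction * n)
  n2_pairs <- data.frame(gene = character(0), held_in = character(0),
                         held_out = character(0))
  shared_variant <- rep(NA_integer_, n)
  if (n2 > 0 && config$n_individuals >= 2) {
    src <- sample.int(n, n2)
    for (i in src) {
      g <- grid$gene[i]
      partner_id <- sample(setdiff(inds, grid$individual[i]), 1)
      j <- which(grid$gene == g & grid$individual == partner_id)
      G[j, ] <- G[i, ]
      G_raw[j, ] <- G_raw[i, ]
      Z[j, ] <- Z[i, ]
      for (k in seq_len(K)) {
        tab <- params$phi[[k]]
        E[j, k] <- sample_rows(tab[Z[j, k] + 1, , drop = FALSE])
        medz[j, k] <- draw_z_for_category(E[j, k], categories[k])
      }
      shared_variant[j] <- i
      ids <- sort(c(grid$individual[i], partner_id))
      n2_pairs <- rbind(n2_pairs,
                        data.frame(gene = g, held_in = ids[1],
                                   held_out = ids[2]))
    }
  }

  # per-signal missingness, independent across signals
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n * K) < config$missing_rate, n, K)
    E[drop] <- NA
    medz[drop] <- NA
  }

  # rare-variant table: one variant per instance; N2 partners carry the
  # source instance's variant instead of their own
  owner <- ifelse(is.na(shared_variant), seq_len(n), shared_variant)
  variants <- data.frame(
    variant_id = sprintf("v%06d", sort(unique(owner))),
    stringsAsFactors = FALSE
  )
  vmap <- match(owner, sort(unique(owner)))
  carriers <- tapply(grid$individual, vmap,
                     function(x) paste(sort(unique(x)), collapse = ","))
  uo <- sort(unique(owner))
  variants$chrom <- "chr1"
  variants$pos <- 1000L + 20000L * match(grid$gene[uo], genes) +
    seq_along(uo) %% 997L
  variants$ref <- "A"
  variants$alt <- "T"
  variants$gene <- grid$gene[uo]
  variants$carriers <- as.character(carriers)
  variants$af_cohort <- pmin(0.009,
                             lengths(strsplit(variants$carriers, ",")) /
                               (2 * config$n_individuals))
  variants$af_gnomad <- stats::runif(nrow(variants), 0, 0.009)
  variants <- cbind(variants, G_raw[uo, , drop = FALSE])

  structure(list(instances = grid, G = G, G_raw = G_raw, E = E,
                 median_z = medz, variants = variants,
                 n2_pairs = n2_pairs,
                 truth = list(Z = Z, params = params),
                 config = config),
            class = "simulated_cohort")
}

# Z-scores consistent with an emitted category at the two-sided p < 0.05
# threshold: tails drawn uniformly in probability space.
draw_z_for_category <- function(e, ncat) {
  n <- length(e)
  z <- numeric(n)
  if (ncat == 3) {
    z[e == 2] <- stats::qnorm(stats::runif(sum(e == 2), 0.025, 0.975))
    z[e == 1] <- stats::qnorm(stats::runif(sum(e == 1), 0, 0.025))
    z[e == 3] <- stats::qnorm(stats::runif(sum(e == 3), 0.975, 1))
  } else {
    p <- numeric(n)
    p[e == 1] <- stats::runif(sum(e == 1), 0.05, 1)
    p[e == 2] <- stats::runif(sum(e == 2), 0, 0.05)
    z <- pmax(stats::qnorm(1 - p), 0)
  }
  z
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated multi-omics cohort\n")
  cat("  individuals:", x$config$n_individuals,
      " genes:", x$config$n_genes,
      " instances:", nrow(x$instances), "\n")
  cat("  signals:", paste(x$truth$params$signals, collapse = ", "), "\n")
  cat("  N2 pairs:", nrow(x$n2_pairs),
      " variants:", nrow(x$variants), "\n")
  invisible(x)
}

#' Simulate two-exam omics Z-score matrices
#'
#' Emulates residual Z-score matrices for one omic signal measured at two
#' exams roughly a decade apart: each feature's values at the two exams
#' share a latent component so that the per-feature cross-exam Pearson
#' correlation is approximately \code{exam_correlation}, and a configured
#' fraction of (feature, individual) cells receives an injected outlier
#' shift present in both exams.
#'
#' @param config a \code{\link{cohort_config}}; \code{n_genes} sets the
#'   feature count and \code{n_individuals} the columns.
#' @param signal label stored with the matrices.
#' @param seed optional seed override (defaults to the config seed).
#' @return list with matrices \code{exam1} and \code{exam5} (features x
#'   individuals, shared dimnames), the injected outlier index matrix
#'   \code{injected} (feature, individual, sign), and \code{signal}.
#' @export
simulate_omics_matrices <- function(config, signal = "expression",
                                    seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  nf <- config$n_genes
  ni <- config$n_individuals
  rho <- config$exam_correlation
  shared <- matrix(stats::rnorm(nf * ni), nf, ni)
  e1 <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(stats::rnorm(nf * ni), nf, ni)
  e5 <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(stats::rnorm(nf * ni), nf, ni)
  n_out <- round(config$outlier_inject_rate * nf * ni)
  injected <- data.frame(feature = integer(0), individual = integer(0),
                         sign = integer(0))
  if (n_out > 0) {
    cells <- sample.int(nf * ni, n_out)
    sgn <- sample(c(-1, 1), n_out, replace = TRUE)
    e1[cells] <- e1[cells] + sgn * config$outlier_magnitude
    e5[cells] <- e5[cells] + sgn * config$outlier_magnitude
    injected <- data.frame(feature = (cells - 1) %% nf + 1,
                           individual = (cells - 1) %/% nf + 1,
                           sign = sgn)
  }
  dn <- list(sprintf("F%05d", seq_len(nf)), sprintf("I%04d", seq_len(ni)))
  dimnames(e1) <- dimnames(e5) <- dn
  list(exam1 = e1, exam5 = e5, injected = injected, signal = signal)
}

# Dirichlet sampler (rows of a gamma matrix normalized).
rdirichlet_mat <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  x / rowSums(x)
}

#' Simulate junction-cluster counts from a Dirichlet-Multinomial
#'
#' For each cluster, per-individual junction usage proportions are drawn
#' from a Dirichlet with the given concentration vector and read counts
#' from a multinomial at that individual's sequencing depth. Individuals
#' with zero depth produce all-zero rows (flagged unusable downstream).
#'
#' @param config a \code{\link{cohort_config}} (supplies individual count,
#'   mean depth and seed).
#' @param n_clusters number of clusters to simulate.
#' @param alpha Dirichlet concentration vector (shared across clusters) or
#'   a list of per-cluster vectors; entries must be positive. Default
#'   \code{c(10, 5, 5)}.
#' @param depths integer vector of per-individual depths, or \code{NULL}
#'   to draw Poisson(\code{mean_depth}) depths per cluster.
#' @param seed optional seed override.
#' @return list of clusters; each is a list with \code{counts}
#'   (individuals x junctions, rownames individual IDs, colnames
#'   \code{cluster:junction}), \code{cluster_id}, \code{gene} and the
#'   generating \code{alpha}.
#' @export
simulate_junction_clusters <- function(config, n_clusters = 1,
                                       alpha = c(10, 5, 5), depths = NULL,
                                       seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  if (!is.list(alpha)) alpha <- rep(list(alpha), n_clusters)
  if (any(vapply(alpha, function(a) any(a <= 0), logical(1))))
    stop("Dirichlet concentration entries must be strictly positive")
  ni <- config$n_individuals
  inds <- sprintf("I%04d", seq_len(ni))
  lapply(seq_len(n_clusters), function(cl) {
    a <- alpha[[cl]]
    J <- length(a)
    d <- if (is.null(depths)) stats::rpois(ni, config$mean_depth)
         else rep_len(depths, ni)
    p <- rdirichlet_mat(ni, a)
    counts <- matrix(0L, ni, J)
    pos <- d > 0
    if (any(pos)) {
      counts[pos, ] <- t(vapply(which(pos), function(i)
        as.integer(stats::rmultinom(1, d[i], p[i, ])), integer(J)))
    }
    cid <- sprintf("clu_%03d", cl)
    dimnames(counts) <- list(inds, paste(cid, seq_len(J), sep = ":"))
    list(counts = counts, cluster_id = cid,
         gene = sprintf("G%04d", cl), alpha = a)
  })
}
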