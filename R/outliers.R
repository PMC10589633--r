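# Outlier calling for expression, methylation and protein signals:
# expression filters, the m-value transform, hidden-factor estimation,
# covariate residualization to Z-scores, gene-level methylation
# aggregation, joint (two-exam) outlier calls, global-outlier removal,
# and cross-exam / cross-omics replication summaries.

#' Filter an expression matrix by read and TPM support
#'
#' Retains genes with at least \code{min_reads} reads and TPM above
#' \code{min_tpm} (both conditions in the same individual) in at least
#' \code{min_fraction} of individuals. Boundary values are inclusive for
#' reads ("at least") and exclusive for TPM (strictly greater).
#'
#' @param values expression matrix (genes x individuals), e.g.
#'   log2(TPM + 2).
#' @param raw_counts,tpm matrices aligned with \code{values}.
#' @param min_reads,min_tpm,min_fraction filter thresholds (defaults 6,
#'   0.1, 0.2).
#' @return the filtered \code{values} matrix.
#' @export
filter_expression_matrix <- function(values, raw_counts, tpm,
                                     min_reads = 6, min_tpm = 0.1,
                                     min_fraction = 0.2) {
  values <- as.matrix(values)
  raw_counts <- as.matrix(raw_counts)
  tpm <- as.matrix(tpm)
  if (!all(dim(raw_counts) == dim(values)) || !all(dim(tpm) == dim(values)))
    stop("`raw_counts` and `tpm` must be aligned with `values`")
  pass <- raw_counts >= min_reads & tpm > min_tpm
  keep <- rowMeans(pass) >= min_fraction
  if (!any(keep))
    stop("no genes pass the expression filter (>= ", min_reads,
         " reads and TPM > ", min_tpm, " in >= ", min_fraction * 100,
         "% of individuals)")
  values[keep, , drop = FALSE]
}

#' Methylation beta to m-value transform
#'
#' \eqn{m = \log_2(\beta / (1 - \beta))}; strictly increasing on (0, 1),
#' antisymmetric about \eqn{\beta = 0.5}.
#'
#' @param beta methylation beta values strictly inside (0, 1).
#' @return m-values.
#' @export
mvalue_transform <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
    stop("beta values must lie strictly inside (0, 1)")
  log2(beta / (1 - beta))
}

#' Inverse of the m-value transform
#'
#' \eqn{\beta = 2^m / (1 + 2^m)}.
#'
#' @param m m-values.
#' @return methylation beta values in (0, 1).
#' @export
mvalue_inverse <- function(m) {
  x <- 2^m
  x / (1 + x)
}

#' Estimate hidden technical factors by truncated SVD
#'
#' Latent-factor estimation for technical variation: the feature-centered
#' matrix is decomposed by singular value decomposition and the leading
#' \code{k} right singular vectors (one value per individual) are
#' returned, ordered by decreasing explained variance. Columns are
#' mutually orthogonal by construction.
#'
#' @param values matrix (features x individuals).
#' @param k number of factors; must satisfy
#'   \code{k <= min(dim(values)) - 1}.
#' @return individuals x k matrix of factors, with per-factor explained
#'   variance fractions in the \code{"explained_variance"} attribute.
#' @export
estimate_hidden_factors <- function(values, k) {
  values <- as.matrix(values)
  if (k > min(dim(values)) - 1)
    stop("`k` must be at most min(n_features, n_individuals) - 1")
  centered <- values - rowMeans(values)
  sv <- svd(centered, nu = 0, nv = k)
  factors <- sv$v
  rownames(factors) <- colnames(values)
  colnames(factors) <- paste0("factor", seq_len(k))
  attr(factors, "explained_variance") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  factors
}

#' Residualize a molecular matrix on covariates and scale to Z-scores
#'
#' Per feature, ordinary-least-squares residuals of the values on the
#' covariates (shared design, plus an optional per-feature covariate such
#' as the top-QTL genotype), centered and scaled to unit variance within
#' the exam. Missing values are excluded pairwise; features with fewer
#' than \code{min_obs} non-missing individuals, or with zero residual
#' variance, are excluded with a warning.
#'
#' @param values matrix (features x individuals).
#' @param covariates data.frame or matrix (individuals x covariates);
#'   rows must cover every individual (matched by rowname when present,
#'   otherwise by position).
#' @param qtl optional matrix (features x individuals) holding one extra
#'   per-feature covariate (e.g. top-QTL genotype).
#' @param min_obs minimum non-missing individuals to score a feature
#'   (default 30).
#' @return Z-score matrix (features x individuals); excluded features are
#'   rows of \code{NA} and are listed in the \code{"excluded"} attribute.
#' @export
residualize_and_scale <- function(values, covariates, qtl = NULL,
                                  min_obs = 30) {
  values <- as.matrix(values)
  X0 <- as.matrix(covariates)
  if (nrow(X0) != ncol(values))
    stop("covariate rows must cover all individuals")
  X0 <- cbind(`(Intercept)` = 1, X0)
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0)) {
    bad <- colnames(X0)[qrX$pivot[(qrX$rank + 1):ncol(X0)]]
    stop("singular covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  z <- matrix(NA_real_, nrow(values), ncol(values),
              dimnames = dimnames(values))
  excluded <- character(0)
  fnames <- rownames(values)
  if (is.null(fnames)) fnames <- as.character(seq_len(nrow(values)))
  for (i in seq_len(nrow(values))) {
    y <- values[i, ]
    X <- if (is.null(qtl)) X0 else cbind(X0, qtl = qtl[i, ])
    obs <- !is.na(y) & stats::complete.cases(X)
    if (sum(obs) < min_obs) { excluded <- c(excluded, fnames[i]); next }
    fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
    res <- fit$residuals
    s <- stats::sd(res)
    if (!is.finite(s) || s < 1e-12) { excluded <- c(excluded, fnames[i]); next }
    z[i, obs] <- (res - mean(res)) / stats::sd(res - mean(res))
  }
  if (length(excluded) > 0)
    warning("excluded ", length(excluded),
            " feature(s) with too few observations or zero residual variance: ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ..." else "")
  attr(z, "excluded") <- excluded
  z
}

#' Gene-level methylation Z-scores from CpG sites near the TSS
#'
#' Aggregates CpG-level Z-scores to genes as the median Z across all
#' measured CpG sites within \code{window} bp upstream of the gene's
#' transcription start site, strand-aware (upstream of a minus-strand
#' gene lies at larger coordinates). Genes with no qualifying CpG are
#' missing.
#'
#' @param cpg_z CpG-level Z matrix (CpGs x individuals), rownames CpG IDs.
#' @param cpg_coords data.frame with \code{cpg}, \code{chrom}, \code{pos}
#'   covering every row of \code{cpg_z}.
#' @param gene_tss data.frame with \code{gene}, \code{chrom}, \code{tss},
#'   \code{strand} ("+"/"-").
#' @param window upstream window in bp (default 1500); a CpG exactly at
#'   the boundary qualifies, one farther upstream does not.
#' @return gene-level Z matrix (genes x individuals).
#' @export
gene_level_methylation <- function(cpg_z, cpg_coords, gene_tss,
                                   window = 1500) {
  cpg_z <- as.matrix(cpg_z)
  missing_coords <- setdiff(rownames(cpg_z), cpg_coords$cpg)
  if (length(missing_coords) > 0)
    stop("CpG sites with no coordinates: ",
         paste(missing_coords, collapse = ", "))
  m <- match(rownames(cpg_z), cpg_coords$cpg)
  chrom <- cpg_coords$chrom[m]
  pos <- cpg_coords$pos[m]
  out <- matrix(NA_real_, nrow(gene_tss), ncol(cpg_z),
                dimnames = list(gene_tss$gene, colnames(cpg_z)))
  for (i in seq_len(nrow(gene_tss))) {
    g <- gene_tss[i, ]
    upstream <- if (g$strand == "+") pos >= g$tss - window & pos <= g$tss
                else pos >= g$tss & pos <= g$tss + window
    sel <- chrom == g$chrom & upstream
    if (!any(sel)) next
    block <- cpg_z[sel, , drop = FALSE]
    out[i, ] <- apply(block, 2, stats::median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA
  out
}

#' Call joint outliers across two exams
#'
#' A (feature, individual) pair is an over- (under-) outlier when its
#' Z-score exceeds \code{threshold} (falls below \code{-threshold}) in
#' both exams; a control when \eqn{|Z| < 1} in both exams; otherwise
#' neither. Pairs unmeasured in either exam are missing.
#'
#' @param exam1,exam5 aligned Z-score matrices (features x individuals).
#' @param threshold joint-outlier threshold (default 3).
#' @param control_threshold control threshold (default 1).
#' @return object of class \code{outlier_calls}: list with the
#'   \code{status} character matrix (\code{over_outlier},
#'   \code{under_outlier}, \code{control}, \code{neither},
#'   \code{missing}), \code{median_z} (median across the two exams),
#'   both Z matrices and the thresholds.
#' @export
call_joint_outliers <- function(exam1, exam5, threshold = 3,
                                control_threshold = 1) {
  exam1 <- as.matrix(exam1); exam5 <- as.matrix(exam5)
  if (!all(dim(exam1) == dim(exam5)) ||
      !identical(dimnames(exam1), dimnames(exam5)))
    stop("exam matrices must be aligned on features and individuals")
  status <- matrix("neither", nrow(exam1), ncol(exam1),
                   dimnames = dimnames(exam1))
  status[exam1 > threshold & exam5 > threshold] <- "over_outlier"
  status[exam1 < -threshold & exam5 < -threshold] <- "under_outlier"
  status[abs(exam1) < control_threshold &
           abs(exam5) < control_threshold] <- "control"
  status[is.na(exam1) | is.na(exam5)] <- "missing"
  structure(list(status = status, median_z = (exam1 + exam5) / 2,
                 exam1 = exam1, exam5 = exam5, threshold = threshold,
                 control_threshold = control_threshold),
            class = "outlier_calls")
}

#' @export
print.outlier_calls <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("over_outlier", "under_outlier",
                                           "control", "neither", "missing")))
  cat("Joint outlier calls (|Z| >", x$threshold, "in both exams)\n")
  print(tab)
  invisible(x)
}

#' Remove global outlier individuals
#'
#' Individuals with anomalously many outlier calls — more than
#' Q3 + 1.5 IQR of the per-individual outlier-count distribution
#' (linear-interpolation quartiles) — are removed entirely for the
#' signal: all their calls become missing.
#'
#' @param calls an \code{\link{outlier_calls}} object.
#' @return the calls with global outliers removed; removed individual IDs
#'   in \code{$global_outliers}.
#' @export
remove_global_outliers <- function(calls) {
  stopifnot(inherits(calls, "outlier_calls"))
  is_out <- calls$status %in% c("over_outlier", "under_outlier")
  dim(is_out) <- dim(calls$status)
  counts <- colSums(is_out)
  thr <- global_outlier_threshold(counts)
  bad <- which(counts > thr)
  if (length(bad) > 0) {
    calls$status[, bad] <- "missing"
    calls$median_z[, bad] <- NA
  }
  calls$global_outliers <- colnames(calls$status)[bad]
  calls
}

#' Cross-exam replication rate of outlier calls
#'
#' Among exam-1 outliers at \code{call_threshold}, the fraction whose
#' exam-5 Z-score exceeds \code{replicate_threshold} in absolute value
#' with a consistent sign.
#'
#' @param exam1,exam5 aligned Z-score matrices.
#' @param call_threshold exam-1 outlier threshold.
#' @param replicate_threshold exam-5 threshold (default 2).
#' @param direction \code{"both"}, \code{"over"} or \code{"under"}.
#' @return fraction in [0, 1]; the number of exam-1 outliers is attached
#'   as the \code{"n_outliers"} attribute.
#' @export
replication_rate <- function(exam1, exam5, call_threshold,
                             replicate_threshold = 2,
                             direction = c("both", "over", "under")) {
  direction <- match.arg(direction)
  exam1 <- as.matrix(exam1); exam5 <- as.matrix(exam5)
  sel <- switch(direction,
                both = abs(exam1) > call_threshold,
                over = exam1 > call_threshold,
                under = exam1 < -call_threshold)
  sel <- sel & !is.na(exam1) & !is.na(exam5)
  sel[is.na(sel)] <- FALSE
  if (!any(sel))
    stop("no exam-1 outliers at |Z| > ", call_threshold,
         "; replication rate is undefined")
  rep_ok <- abs(exam5[sel]) > replicate_threshold &
    sign(exam5[sel]) == sign(exam1[sel])
  out <- mean(rep_ok)
  attr(out, "n_outliers") <- sum(sel)
  out
}

#' Outlier sharing across omic signals
#'
#' For the outliers called in signal a, the fraction whose mean-across-
#' exam Z-score in signal b exceeds a relaxed threshold in absolute
#' value, plus a one-sided Wilcoxon rank-sum test comparing
#' \eqn{|\bar Z_b|} between signal-a outliers and non-outliers over the
#' shared (feature, individual) universe.
#'
#' @param calls_a an \code{\link{outlier_calls}} object for signal a.
#' @param exam1_b,exam5_b Z-score matrices for signal b (feature and
#'   individual names must overlap those of \code{calls_a}).
#' @param relaxed_threshold sharing threshold on \eqn{|\bar Z_b|}
#'   (default 2).
#' @return list with \code{sharing} (fraction), \code{p_value}
#'   (one-sided rank-sum), \code{n_outliers}, \code{n_background}.
#' @export
cross_omics_sharing <- function(calls_a, exam1_b, exam5_b,
                                relaxed_threshold = 2) {
  stopifnot(inherits(calls_a, "outlier_calls"))
  feats <- intersect(rownames(calls_a$status), rownames(exam1_b))
  inds <- intersect(colnames(calls_a$status), colnames(exam1_b))
  if (length(feats) == 0 || length(inds) == 0)
    stop("signals a and b share no (feature, individual) universe")
  zb <- (as.matrix(exam1_b)[feats, inds, drop = FALSE] +
           as.matrix(exam5_b)[feats, inds, drop = FALSE]) / 2
  st <- calls_a$status[feats, inds, drop = FALSE]
  measured <- !is.na(zb) & st != "missing"
  is_out <- st %in% c("over_outlier", "under_outlier")
  dim(is_out) <- dim(st)
  out_vals <- abs(zb[measured & is_out])
  bg_vals <- abs(zb[measured & !is_out])
  if (length(out_vals) == 0)
    stop("no signal-a outliers are measured in signal b")
  list(
    sharing = mean(out_vals > relaxed_threshold),
    p_value = stats::wilcox.test(out_vals, bg_vals,
                                 alternative = "greater", exact = FALSE)$p.value,
    n_outliers = length(out_vals),
    n_background = length(bg_vals)
  )
}
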