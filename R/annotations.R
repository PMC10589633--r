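# Preparing Watershed inputs: aggregating variant-level genomic
# annotations to (gene, individual) instances, standardizing them, turning
# outlier Z-scores / p-values into categorical statuses, and applying the
# training-instance filters.

# Expand a variant table's comma-separated `carriers` column to long
# (variant_id, individual) format.
expand_carriers <- function(variants) {
  ids <- strsplit(as.character(variants$carriers), ",", fixed = TRUE)
  data.frame(
    variant_id = rep(variants$variant_id, lengths(ids)),
    individual = trimws(unlist(ids)),
    row = rep(seq_len(nrow(variants)), lengths(ids)),
    stringsAsFactors = FALSE
  )
}

#' Aggregate variant annotations to (gene, individual) vectors
#'
#' Assigns each retained rare variant to the genes whose window (gene body
#' plus \code{flank} on either side) contains it, then aggregates every
#' annotation across the variants an individual carries near a gene. The
#' aggregation rule is the maximum per feature, which preserves binary
#' flags and takes the strongest score for continuous features.
#'
#' @param variants variant table: data.frame with \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{carriers} (comma-separated individual
#'   IDs) and the annotation columns.
#' @param windows gene windows: data.frame with \code{gene}, \code{chrom},
#'   \code{start}, \code{end} (gene body, 0-based half-open).
#' @param annotation_cols character vector naming the annotation columns
#'   to aggregate; all must be present in \code{variants}.
#' @param flank window extension in bp on each side of the gene body
#'   (default 10 kb).
#' @return data.frame with \code{gene}, \code{individual} and one
#'   aggregated column per annotation; one row per (gene, individual) with
#'   at least one rare variant in the window.
#' @export
aggregate_annotations <- function(variants, windows, annotation_cols,
                                  flank = 10000) {
  missing_cols <- setdiff(annotation_cols, names(variants))
  if (length(missing_cols) > 0)
    stop("annotations listed but absent from the variant table: ",
         paste(missing_cols, collapse = ", "))
  hits <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sel <- variants$chrom == w$chrom &
      variants$pos >= (w$start - flank) & variants$pos < (w$end + flank)
    if (!any(sel)) return(NULL)
    cbind(gene = w$gene, variants[sel, c("variant_id", "carriers",
                                         annotation_cols)],
          stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(gene = character(0), individual = character(0)))
  long <- expand_carriers(hits)
  long <- cbind(long, gene = hits$gene[long$row],
                hits[long$row, annotation_cols, drop = FALSE])
  agg <- stats::aggregate(long[annotation_cols],
                          by = list(gene = long$gene,
                                    individual = long$individual),
                          FUN = max)
  agg[order(agg$gene, agg$individual), , drop = FALSE]
}

#' Standardize an annotation matrix
#'
#' Mean-centers and scales each annotation column to unit standard
#' deviation (sample sd, denominator n - 1). Constant columns carry no
#' information and are dropped with a warning.
#'
#' @param G numeric matrix or data.frame of annotations (instances x
#'   features), at least two rows.
#' @return the standardized matrix; dropped columns are recorded in the
#'   \code{"dropped"} attribute.
#' @export
standardize_annotations <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) < 2) stop("standardization needs at least two instances")
  sds <- apply(G, 2, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  if (all(constant)) stop("all annotation columns are constant")
  if (any(constant)) {
    warning("dropping constant annotation column(s): ",
            paste(colnames(G)[constant], collapse = ", "))
  }
  out <- scale(G[, !constant, drop = FALSE])
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped") <- colnames(G)[constant]
  out
}

#' Binarize outlier measurements into categorical statuses
#'
#' Maps per-signal outlier evidence to the categorical statuses the
#' Watershed emission layer models: directional signals (expression,
#' methylation, protein) to \{1 = under, 2 = none, 3 = over\} using a
#' two-sided p-value threshold with the direction taken from the sign of
#' Z; directionless signals (splicing) to \{1 = none, 2 = outlier\} using
#' the p-value alone. Missing measurements propagate as \code{NA}.
#'
#' @param z matrix (instances x signals) of median Z-scores (\code{NA} =
#'   unmeasured). Required for directional signals.
#' @param p optional matrix of p-values on the same layout; when omitted
#'   it is derived from \code{z} (two-sided normal for directional
#'   signals, upper-tail for directionless).
#' @param categories integer vector (3 = directional, 2 = directionless)
#'   per signal; defaults to 3 except columns named \code{"splicing"}.
#' @param threshold_p p-value threshold for outlier status (default 0.05).
#' @return integer matrix of outlier categories with the input dimnames.
#' @export
binarize_outliers <- function(z, p = NULL, categories = NULL,
                              threshold_p = 0.05) {
  z <- as.matrix(z)
  K <- ncol(z)
  signals <- colnames(z)
  if (is.null(signals)) signals <- paste0("signal", seq_len(K))
  if (is.null(categories))
    categories <- ifelse(signals == "splicing", 2L, 3L)
  if (is.null(p)) {
    p <- matrix(NA_real_, nrow(z), K)
    for (k in seq_len(K)) {
      p[, k] <- if (categories[k] == 3) 2 * stats::pnorm(-abs(z[, k]))
                else stats::pnorm(z[, k], lower.tail = FALSE)
    }
  } else {
    p <- as.matrix(p)
  }
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  E <- matrix(NA_integer_, nrow(z), K, dimnames = list(rownames(z), signals))
  for (k in seq_len(K)) {
    obs <- !is.na(p[, k])
    if (categories[k] == 3) {
      obs <- obs & !is.na(z[, k])
      E[obs, k] <- ifelse(p[obs, k] < threshold_p,
                          ifelse(z[obs, k] > 0, 3L, 1L), 2L)
    } else {
      E[obs, k] <- ifelse(p[obs, k] < threshold_p, 2L, 1L)
    }
  }
  E
}

#' Filter (gene, individual) instances for Watershed training
#'
#' Applies the training-set filters in order: (1) signals whose two exams
#' disagree (one exam \eqn{|Z| \ge 3}, the other \eqn{|Z| \le 1}) are set
#' to missing; (2) individuals with anomalously many outlier calls in a
#' signal (count above Q3 + 1.5 IQR across individuals, "global
#' outliers") have that signal removed entirely; (3) instances with fewer
#' than two observed signals are dropped; (4) genes with no outlier
#' individual in at least two signals are dropped. Median Z across the
#' two exams (their mean, as the median of two values) is carried forward
#' as the model input.
#'
#' @param gene,individual character vectors, one entry per instance.
#' @param z1,z5 numeric matrices (instances x signals) of exam-1 and
#'   exam-5 Z-scores (\code{NA} = unmeasured). For the directionless
#'   splicing signal use its non-negative Z conversion.
#' @param categories per-signal emission category counts (see
#'   \code{\link{binarize_outliers}}).
#' @param threshold_p p-value threshold for the outlier categories.
#' @return list with \code{kept} (logical index into the input
#'   instances), and for the surviving instances \code{gene},
#'   \code{individual}, \code{median_z}, \code{E}.
#' @export
filter_training_instances <- function(gene, individual, z1, z5,
                                      categories = NULL,
                                      threshold_p = 0.05) {
  z1 <- as.matrix(z1); z5 <- as.matrix(z5)
  stopifnot(all(dim(z1) == dim(z5)),
            length(gene) == nrow(z1), length(individual) == nrow(z1))
  K <- ncol(z1)
  signals <- colnames(z1)
  if (is.null(signals)) signals <- paste0("signal", seq_len(K))
  if (is.null(categories))
    categories <- ifelse(signals == "splicing", 2L, 3L)

  # (1) cross-exam consistency: drop signal values that flip between exams
  inconsistent <- (abs(z1) >= 3 & abs(z5) <= 1) | (abs(z5) >= 3 & abs(z1) <= 1)
  inconsistent[is.na(inconsistent)] <- FALSE
  z1[inconsistent] <- NA
  z5[inconsistent] <- NA

  medz <- (z1 + z5) / 2
  colnames(medz) <- signals
  E <- binarize_outliers(medz, categories = categories,
                         threshold_p = threshold_p)

  # (2) global outliers: per signal, individuals with outlier counts
  # above Q3 + 1.5 IQR lose that signal
  none_cat <- ifelse(categories == 3, 2L, 1L)
  for (k in seq_len(K)) {
    is_out <- !is.na(E[, k]) & E[, k] != none_cat[k]
    counts <- tapply(is_out, individual, sum)
    thr <- global_outlier_threshold(as.numeric(counts))
    bad <- names(counts)[counts > thr]
    if (length(bad) > 0) {
      sel <- individual %in% bad
      E[sel, k] <- NA
      medz[sel, k] <- NA
    }
  }

  # (3) at least two observed signals per instance
  kept <- rowSums(!is.na(E)) >= 2

  # (4) genes with outlier individuals in >= 2 signals
  gene_ok <- vapply(split(seq_len(nrow(E))[kept], gene[kept]), function(idx) {
    out_signals <- vapply(seq_len(K), function(k) {
      any(!is.na(E[idx, k]) & E[idx, k] != none_cat[k])
    }, logical(1))
    sum(out_signals) >= 2
  }, logical(1))
  kept <- kept & gene %in% names(gene_ok)[gene_ok]

  list(kept = kept, gene = gene[kept], individual = individual[kept],
       median_z = medz[kept, , drop = FALSE], E = E[kept, , drop = FALSE])
}

# Tukey fence used for global-outlier removal; linear-interpolation
# (type-7) quartiles.
global_outlier_threshold <- function(counts) {
  q <- stats::quantile(counts, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}
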