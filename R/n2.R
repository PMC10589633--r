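# N2-pair evaluation: held-out individuals sharing an identical rare
# variant set near a gene, precision-recall scoring, and per-variant
# posterior assignment.

#' Build N2 pairs from shared rare-variant sets
#'
#' An N2 pair is two individuals who carry the identical set of rare
#' variants near the same gene. The held-in individual's outlier statuses
#' serve as model evidence; the held-out individual's statuses serve as
#' labels. When more than two individuals share a set, the two
#' lexicographically smallest IDs form the pair (a deterministic rule;
#' the second is held out).
#'
#' @param gene,individual character vectors defining the (gene,
#'   individual) instances under consideration.
#' @param variants variant table with \code{variant_id}, \code{gene} (the
#'   assigned gene) and \code{carriers} (comma-separated individual IDs).
#' @return data.frame with one row per pair: \code{gene}, \code{held_in},
#'   \code{held_out}, \code{variant_set} (comma-joined sorted IDs).
#' @export
build_n2_pairs <- function(gene, individual, variants) {
  long <- expand_carriers(variants)
  long$gene <- variants$gene[long$row]
  inst_key <- paste(gene, individual, sep = "\r")
  long_key <- paste(long$gene, long$individual, sep = "\r")
  long <- long[long_key %in% inst_key, , drop = FALSE]
  if (nrow(long) == 0)
    return(data.frame(gene = character(0), held_in = character(0),
                      held_out = character(0), variant_set = character(0)))
  sets <- tapply(long$variant_id,
                 paste(long$gene, long$individual, sep = "\r"),
                 function(v) paste(sort(unique(v)), collapse = ","))
  parts <- strsplit(names(sets), "\r", fixed = TRUE)
  df <- data.frame(gene = vapply(parts, `[`, "", 1),
                   individual = vapply(parts, `[`, "", 2),
                   variant_set = as.character(sets),
                   stringsAsFactors = FALSE)
  grp <- split(df$individual, paste(df$gene, df$variant_set, sep = "\r"))
  pairs <- lapply(names(grp), function(g) {
    ids <- sort(grp[[g]])
    if (length(ids) < 2) return(NULL)
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    data.frame(gene = parts[1], held_in = ids[1], held_out = ids[2],
               variant_set = parts[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pairs)
  if (is.null(out))
    out <- data.frame(gene = character(0), held_in = character(0),
                      held_out = character(0), variant_set = character(0))
  rownames(out) <- NULL
  out[order(out$gene, out$held_in), , drop = FALSE]
}

#' Area under the precision-recall curve
#'
#' Average-precision estimator: scores are ranked in decreasing order and
#' the precision at each positive is averaged. A perfect ranking gives 1;
#' a random ranking gives approximately the label prevalence.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels of the same length.
#' @return a single number in [0, 1].
#' @export
aucpr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o] == 1
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  sum(precision[lab]) / npos
}

# Precision-recall curve points (decreasing-score sweep).
pr_curve <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o] == 1
  tp <- cumsum(lab)
  data.frame(recall = tp / sum(lab), precision = tp / seq_along(lab))
}

#' Evaluate Watershed and GAM on N2 pairs
#'
#' For each signal, the held-out individual of every N2 pair is scored by
#' the Watershed posterior computed from the shared annotations and the
#' held-in individual's observed outlier statuses, and by the GAM
#' predicted probability (annotations alone). Labels are the held-out
#' individual's binarized outlier statuses. Performance is summarized as
#' the area under the precision-recall curve, with a bootstrap
#' distribution from repeatedly subsampling half of the pairs.
#'
#' @param fit a fitted \code{\link{watershed}} model.
#' @param G annotation matrix, one row per N2 pair (shared by both
#'   individuals), standardized on the training scale.
#' @param E_heldin evidence matrix (pairs x K) of the held-in
#'   individuals' outlier categories.
#' @param labels binary matrix (pairs x K): held-out individuals' outlier
#'   status (1 = outlier), \code{NA} where unmeasured.
#' @param gam_fits optional list of per-signal \code{\link{fit_gam}}
#'   models; defaults to the ones stored in \code{fit}.
#' @param n_boot number of half-subsample bootstrap replicates.
#' @param min_pairs signals with fewer evaluable pairs are skipped.
#' @param seed integer seed for the bootstrap.
#' @return object of class \code{n2_eval}: per-signal list with
#'   \code{aucpr_watershed}, \code{aucpr_gam}, \code{prevalence},
#'   \code{n_pairs}, bootstrap vectors \code{boot_watershed} /
#'   \code{boot_gam}, and PR curve points.
#' @export
evaluate_n2 <- function(fit, G, E_heldin, labels, gam_fits = NULL,
                        n_boot = 100, min_pairs = 10, seed = 1) {
  if (is.null(gam_fits)) gam_fits <- fit$gam
  G <- as.matrix(G); labels <- as.matrix(labels)
  scores_ws <- predict(fit, G, E_heldin)
  K <- length(fit$signals)
  set.seed(seed)
  out <- vector("list", K)
  names(out) <- fit$signals
  for (k in seq_len(K)) {
    ok <- !is.na(labels[, k])
    if (sum(ok) < min_pairs) {
      warning("signal ", fit$signals[k], " has fewer than ", min_pairs,
              " evaluable N2 pairs; skipped")
      next
    }
    lab <- labels[ok, k]
    if (sum(lab == 1) == 0) {
      warning("signal ", fit$signals[k],
              " has no positive labels among N2 pairs; skipped")
      next
    }
    sw <- scores_ws[ok, k]
    sg <- predict(gam_fits[[k]], G[ok, , drop = FALSE])
    m <- length(lab)
    half <- floor(m / 2)
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(m, half)
      c(aucpr(sw[idx], lab[idx]), aucpr(sg[idx], lab[idx]))
    }, numeric(2))
    out[[k]] <- list(
      aucpr_watershed = aucpr(sw, lab),
      aucpr_gam = aucpr(sg, lab),
      prevalence = mean(lab == 1),
      n_pairs = m,
      boot_watershed = boot[1, ],
      boot_gam = boot[2, ],
      pr_watershed = pr_curve(sw, lab),
      pr_gam = pr_curve(sg, lab)
    )
  }
  structure(out, class = "n2_eval")
}

#' @export
print.n2_eval <- function(x, ...) {
  cat("N2-pair evaluation (area under the precision-recall curve)\n")
  for (s in names(x)) {
    if (is.null(x[[s]])) {
      cat(sprintf("  %-12s skipped\n", s)); next
    }
    cat(sprintf(
      "  %-12s n=%4d  prevalence=%.3f  Watershed=%.3f  GAM=%.3f\n",
      s, x[[s]]$n_pairs, x[[s]]$prevalence,
      x[[s]]$aucpr_watershed, x[[s]]$aucpr_gam))
  }
  invisible(x)
}

#' Per-variant posteriors by maximizing over carriers
#'
#' Each rare variant receives, per signal, the maximum posterior across
#' all (gene, individual) instances of individuals carrying it.
#'
#' @param posteriors data.frame with \code{gene}, \code{individual} and
#'   one numeric posterior column per signal.
#' @param variants variant table with \code{variant_id}, \code{gene},
#'   \code{carriers}.
#' @param signal_cols names of the posterior columns (default: all
#'   numeric columns of \code{posteriors}).
#' @return data.frame with \code{variant_id}, \code{gene} and the
#'   max-over-carriers posterior per signal; variants with no scored
#'   carrier are absent.
#' @export
score_all_variants <- function(posteriors, variants, signal_cols = NULL) {
  if (is.null(signal_cols))
    signal_cols <- names(posteriors)[vapply(posteriors, is.numeric, TRUE)]
  long <- expand_carriers(variants)
  long$gene <- variants$gene[long$row]
  m <- match(paste(long$gene, long$individual, sep = "\r"),
             paste(posteriors$gene, posteriors$individual, sep = "\r"))
  scored <- !is.na(m)
  if (!any(scored))
    return(data.frame(variant_id = character(0), gene = character(0)))
  long <- long[scored, , drop = FALSE]
  vals <- posteriors[m[scored], signal_cols, drop = FALSE]
  agg <- stats::aggregate(vals,
                          by = list(variant_id = long$variant_id,
                                    gene = long$gene),
                          FUN = max)
  agg[order(agg$variant_id), , drop = FALSE]
}
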