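# Connecting variant posteriors to traits: percentile normalization of
# GWAS effect sizes, distribution comparison for posterior-thresholded
# variant sets, and the gene-level posterior association test.

#' Percentile-normalize effect sizes
#'
#' Maps each value to rank/n with average ranks for ties; the output is
#' order-preserving and lies in (0, 1], invariant to any strictly
#' monotone transform of the input.
#'
#' @param effects numeric vector (at least one value; typically absolute
#'   GWAS effect sizes).
#' @return fractions in (0, 1].
#' @export
percentile_normalize <- function(effects) {
  if (length(effects) == 0) stop("empty effect-size vector")
  rank(effects, ties.method = "average") / length(effects)
}

#' Compare normalized effect sizes of prioritized variants to background
#'
#' One-sided Wilcoxon rank-sum test that the variants selected by a
#' posterior threshold have larger percentile-normalized effect sizes
#' than the background set.
#'
#' @param background numeric vector of normalized effect sizes for all
#'   rare variants.
#' @param selected normalized effect sizes of the prioritized subset.
#' @return list with \code{median_background}, \code{median_selected},
#'   \code{p_value}, \code{n_selected}, \code{n_background}; an empty
#'   selection returns the explicit empty-set result (\code{NA} medians
#'   and p-value, \code{n_selected = 0}).
#' @export
compare_effect_sets <- function(background, selected) {
  if (length(selected) == 0)
    return(list(median_background = stats::median(background),
                median_selected = NA_real_, p_value = NA_real_,
                n_selected = 0L, n_background = length(background)))
  list(
    median_background = stats::median(background),
    median_selected = stats::median(selected),
    p_value = stats::wilcox.test(selected, background,
                                 alternative = "greater",
                                 exact = FALSE)$p.value,
    n_selected = length(selected),
    n_background = length(background)
  )
}

#' Label trait residuals as outlier / control individuals
#'
#' @param z residual trait Z-scores.
#' @param outlier_threshold individuals with \eqn{|Z|} above this are
#'   trait outliers (default 2).
#' @param control_threshold individuals with \eqn{|Z|} below this are
#'   controls (default 0.2).
#' @return character vector in \{"outlier", "control", "neither"\}.
#' @export
trait_labels <- function(z, outlier_threshold = 2, control_threshold = 0.2) {
  out <- rep("neither", length(z))
  out[abs(z) > outlier_threshold] <- "outlier"
  out[abs(z) < control_threshold] <- "control"
  out[is.na(z)] <- NA
  out
}

#' Gene-level association of variant posteriors with a trait
#'
#' For each gene and each posterior column (plus a combined
#' max-across-signals posterior when several are supplied), compares the
#' posterior distribution of rare variants carried by trait-outlier
#' individuals against those carried by controls with a one-sided
#' Wilcoxon rank-sum test, and adjusts across genes by
#' Benjamini-Hochberg.
#'
#' @param cohort data.frame with one row per (variant, gene, individual)
#'   instance: \code{gene}, \code{label} ("outlier" / "control";
#'   other labels are ignored) and one or more numeric posterior
#'   columns.
#' @param signal_cols names of the posterior columns (default: all
#'   numeric columns).
#' @return data.frame with \code{gene}, \code{signal}, \code{p},
#'   \code{q} (BH within signal), \code{n_outlier}, \code{n_control}.
#'   Genes with an empty label group are skipped with a note.
#' @export
gene_posterior_association <- function(cohort, signal_cols = NULL) {
  if (is.null(signal_cols))
    signal_cols <- names(cohort)[vapply(cohort, is.numeric, TRUE)]
  cohort <- cohort[cohort$label %in% c("outlier", "control"), , drop = FALSE]
  if (length(signal_cols) > 1) {
    cohort$combined <- do.call(pmax,
                               c(cohort[signal_cols], list(na.rm = TRUE)))
    signal_cols <- c(signal_cols, "combined")
  }
  res <- list()
  skipped <- character(0)
  for (g in unique(cohort$gene)) {
    sub <- cohort[cohort$gene == g, , drop = FALSE]
    n_out <- sum(sub$label == "outlier")
    n_ctl <- sum(sub$label == "control")
    if (n_out == 0 || n_ctl == 0) {
      skipped <- c(skipped, g)
      next
    }
    for (s in signal_cols) {
      p <- stats::wilcox.test(sub[[s]][sub$label == "outlier"],
                              sub[[s]][sub$label == "control"],
                              alternative = "greater",
                              exact = FALSE)$p.value
      res[[length(res) + 1]] <- data.frame(
        gene = g, signal = s, p = p,
        n_outlier = n_out, n_control = n_ctl,
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped) > 0)
    message("skipped ", length(skipped),
            " gene(s) with an empty outlier or control group")
  if (length(res) == 0)
    return(data.frame(gene = character(0), signal = character(0),
                      p = numeric(0), q = numeric(0),
                      n_outlier = integer(0), n_control = integer(0)))
  out <- do.call(rbind, res)
  out$q <- NA_real_
  for (s in unique(out$signal)) {
    sel <- out$signal == s
    out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out[order(out$signal, out$p), c("gene", "signal", "p", "q",
                                  "n_outlier", "n_control")]
}
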