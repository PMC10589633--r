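# Rare-variant enrichment near outliers: rarity filters, window
# intersection, relative risk with confidence intervals, comparison of
# two enrichments, and ancestry-matched control selection.

#' Filter a variant table to rare variants
#'
#' Retains variants rare everywhere: cohort allele frequency below the
#' threshold AND every external frequency column (overall and each
#' subpopulation) below the threshold. Missing external frequencies are
#' treated as 0 (the variant is unobserved externally) with a note.
#'
#' @param variants variant table; frequency columns are all columns whose
#'   names start with \code{"af_"} unless \code{af_cols} is given.
#' @param threshold rarity threshold (default 0.01, i.e. 1\%).
#' @param af_cols optional explicit character vector of frequency
#'   columns.
#' @return the subset of rare variants.
#' @export
flag_rare_variants <- function(variants, threshold = 0.01, af_cols = NULL) {
  if (is.null(af_cols))
    af_cols <- grep("^af_", names(variants), value = TRUE)
  if (length(af_cols) == 0)
    stop("no allele-frequency columns found (expected names starting 'af_')")
  af <- as.matrix(variants[af_cols])
  if (!is.numeric(af))
    stop("allele-frequency columns must be numeric")
  bad <- which(rowSums(af < 0 | af > 1, na.rm = TRUE) > 0)
  if (length(bad) > 0)
    stop("malformed allele frequencies in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (anyNA(af)) {
    message("treating ", sum(is.na(af)),
            " missing external allele frequencies as 0")
    af[is.na(af)] <- 0
  }
  variants[rowSums(af < threshold) == length(af_cols), , drop = FALSE]
}

#' Binary rare-variant indicator per (feature, individual)
#'
#' Intersects retained rare variants with feature windows (gene body or
#' CpG site, extended by \code{flank} bp on each side, half-open
#' coordinates) and converts to a binary signal: 1 if the individual
#' carries at least one rare variant inside the window, else 0.
#'
#' @param variants rare-variant table with \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{carriers}.
#' @param windows data.frame with \code{feature}, \code{chrom},
#'   \code{start}, \code{end} (for a CpG site use start = pos, end =
#'   pos + 1).
#' @param flank bp added on each side (default 10 kb).
#' @param individuals individual universe for the columns; defaults to
#'   the union of carriers.
#' @return binary matrix (features x individuals).
#' @export
rare_variant_indicator <- function(variants, windows, flank = 10000,
                                   individuals = NULL) {
  if (any(windows$end < windows$start))
    stop("window with end < start")
  long <- expand_carriers(variants)
  if (is.null(individuals)) individuals <- sort(unique(long$individual))
  out <- matrix(0L, nrow(windows), length(individuals),
                dimnames = list(windows$feature, individuals))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    hit <- variants$chrom == w$chrom &
      variants$pos >= (w$start - flank) & variants$pos < (w$end + flank)
    if (!any(hit)) next
    carriers <- unique(long$individual[long$row %in% which(hit)])
    out[i, individuals %in% carriers] <- 1L
  }
  out
}

#' Relative risk of rare-variant carriage in outliers versus controls
#'
#' From the 2x2 table of (gene, individual) instances — \code{a} outliers
#' with a rare variant, \code{b} outliers without, \code{c} controls
#' with, \code{d} controls without — estimates
#' \eqn{RR = [a/(a+b)] / [c/(c+d)]} with a log-normal (Wald) 95\%
#' confidence interval, \eqn{SE = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}},
#' and a one-sided t-test of \eqn{\log RR / SE} against RR = 1 with
#' \eqn{df = (a+b) + (c+d) - 2}. Zero counts in \code{a} or \code{c}
#' leave the CI and p-value undefined and set an explicit flag (no
#' silent continuity correction).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param conf_level confidence level (default 0.95).
#' @return object of class \code{enrichment_result}.
#' @export
relative_risk <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers")
  if (a + b < 1 || c + d < 1)
    stop("both the outlier and the control margin must be non-empty")
  rr <- (a / (a + b)) / (c / (c + d))
  zero_cell <- a == 0 || c == 0
  if (zero_cell) {
    se <- ci <- p <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(rr) + c(-1, 1) * zq * se)
    df <- (a + b) + (c + d) - 2
    p <- stats::pt(log(rr) / se, df = df, lower.tail = FALSE)
  }
  structure(list(rr = rr, ci_low = ci[1], ci_high = ci[2],
                 se_log = se, p_value = p,
                 n_outlier = a + b, n_control = c + d,
                 table = cells, zero_cell = zero_cell,
                 conf_level = conf_level),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Relative risk: %.4g", x$rr))
  if (!x$zero_cell)
    cat(sprintf("  %g%% CI [%.4g, %.4g]  one-sided p = %.3g",
                100 * x$conf_level, x$ci_low, x$ci_high, x$p_value))
  else
    cat("  (zero cell: CI and p undefined)")
  cat(sprintf("\n  outlier instances: %d (with variant: %d); control instances: %d (with variant: %d)\n",
              x$n_outlier, x$table["a"], x$n_control, x$table["c"]))
  invisible(x)
}

#' Compare two relative-risk estimates
#'
#' Tests whether two enrichments differ:
#' \eqn{t = (\log RR_1 - \log RR_2) / \sqrt{SE_1^2 + SE_2^2}}, two-sided
#' p-value at degrees of freedom equal to the total outlier and control
#' instances in both estimates minus 2.
#'
#' @param r1,r2 \code{\link{relative_risk}} results with defined
#'   standard errors.
#' @return list with \code{t}, \code{df}, \code{p_value}.
#' @export
compare_relative_risks <- function(r1, r2) {
  stopifnot(inherits(r1, "enrichment_result"),
            inherits(r2, "enrichment_result"))
  if (r1$zero_cell || r2$zero_cell || is.na(r1$se_log) || is.na(r2$se_log))
    stop("both enrichment results need a defined standard error")
  t <- (log(r1$rr) - log(r2$rr)) / sqrt(r1$se_log^2 + r2$se_log^2)
  df <- r1$n_outlier + r1$n_control + r2$n_outlier + r2$n_control - 2
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df = df))
}

#' Match outliers to controls by genotype-PC distance
#'
#' Pairs each outlier individual with the control at the smallest
#' Euclidean distance in genotype principal-component space (top 11 PCs
#' in the intended use). Controls may be reused across outliers; exact
#' ties are broken by lexicographic individual-ID order.
#'
#' @param outliers,controls character vectors of individual IDs; the
#'   control pool must be non-empty.
#' @param pcs numeric matrix of PC loadings with individual IDs as
#'   rownames, covering every listed individual.
#' @return data.frame with \code{outlier}, \code{control},
#'   \code{distance}.
#' @export
ancestry_matched_controls <- function(outliers, controls, pcs) {
  if (length(controls) == 0) stop("control pool is empty")
  missing_ids <- setdiff(c(outliers, controls), rownames(pcs))
  if (length(missing_ids) > 0)
    stop("missing PC rows for: ", paste(missing_ids, collapse = ", "))
  controls <- sort(controls)
  cp <- pcs[controls, , drop = FALSE]
  res <- lapply(outliers, function(o) {
    d <- sqrt(colSums((t(cp) - pcs[o, ])^2))
    best <- which(d == min(d))[1] # controls sorted: ties -> smaller ID
    data.frame(outlier = o, control = controls[best],
               distance = d[best], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
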