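# Plain-text interchange: feature x individual matrices and the wide
# per-instance training table as tab-separated files.

#' Write a feature-by-individual matrix as TSV
#'
#' First column \code{feature}, remaining columns one per individual.
#'
#' @param mat numeric matrix with feature rownames and individual
#'   colnames.
#' @param path output file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-individual matrix from TSV
#'
#' @param path TSV written by \code{\link{write_matrix_tsv}} (first
#'   column feature IDs, header row of individual IDs).
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write a Watershed training table as wide TSV
#'
#' One row per (gene, individual) instance: identifiers, annotation
#' columns, per-signal median Z, per-signal outlier category (NA =
#' unmeasured).
#'
#' @param gene,individual identifier vectors.
#' @param G standardized annotation matrix.
#' @param median_z,E per-signal matrices (see \code{\link{watershed}}).
#' @param path output file path.
#' @export
write_watershed_tsv <- function(gene, individual, G, median_z, E, path) {
  zc <- as.data.frame(median_z)
  names(zc) <- paste0("z_", colnames(median_z))
  ec <- as.data.frame(E)
  names(ec) <- paste0("status_", colnames(E))
  df <- cbind(data.frame(gene = gene, individual = individual,
                         stringsAsFactors = FALSE),
              as.data.frame(G), zc, ec)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
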