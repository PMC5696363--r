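# Plain-text matrix I/O: tab-separated values, '#'-prefixed comment header.

#' Write a numeric matrix as TSV
#'
#' Row-major tab-separated values with '#'-prefixed comment lines at the top;
#' readable back with [read_matrix_tsv()].
#'
#' @param x numeric matrix.
#' @param path output file.
#' @param comment optional character vector of header comment lines.
#' @export
write_matrix_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path input file.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", comment.char = "#",
                              header = FALSE))
}

#' Write a sensor montage as TSV (label, x, y, z in mm)
#'
#' @param labels character vector of sensor labels.
#' @param positions N x 3 coordinates (mm).
#' @param path output file.
#' @export
write_montage_tsv <- function(labels, positions, path) {
  df <- data.frame(label = labels, x = positions[, 1], y = positions[, 2],
                   z = positions[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
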