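#' Read and write gene x cell expression matrices
#'
#' CSV/TSV layout: genes in rows, first column gene identifiers, header row
#' of cell identifiers. An MTX triple (`matrix.mtx` plus `genes` and
#' `barcodes` text files alongside) is also accepted; it is read with the
#' Matrix package.
#'
#' @param file Path to a `.csv`, `.tsv`/`.txt` or `.mtx` file.
#' @param matrix Genes x cells numeric matrix with dimnames.
#' @return `read_expression_matrix()` returns a genes x cells numeric
#'   matrix; `write_expression_matrix()` returns `file` invisibly.
#' @export
read_expression_matrix <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "mtx") {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      abort("Reading MTX files requires the Matrix package.")
    }
    m <- as.matrix(Matrix::readMM(file))
    dir <- dirname(file)
    genes_file <- file.path(dir, "genes.tsv")
    cells_file <- file.path(dir, "barcodes.tsv")
    if (!file.exists(genes_file) || !file.exists(cells_file)) {
      abort("MTX input needs `genes.tsv` and `barcodes.tsv` next to it.")
    }
    rownames(m) <- readLines(genes_file)
    colnames(m) <- readLines(cells_file)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(file, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  storage.mode(m) <- "double"
  check_expression_matrix(m)
  m
}

#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(matrix, file) {
  check_expression_matrix(matrix)
  ext <- tolower(tools::file_ext(file))
  sep <- if (ext == "csv") "," else "\t"
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export a trajectory as CSV
#'
#' @param traj A `circuit_trajectory`.
#' @param file Output path.
#' @param format `"long"` (tidy `time, species, value`) or `"wide"` (one
#'   column per species).
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file, format = c("long", "wide")) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  format <- match.arg(format)
  out <- if (format == "long") tidy(traj) else as_tibble(traj)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
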