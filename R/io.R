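#' Validate an expression matrix
#'
#' The package represents expression data as a plain numeric matrix in
#' cells x genes orientation: rows are cells, columns are genes, and the
#' dimnames carry the cell and gene identifiers.  `expression_matrix()`
#' checks the invariants every other function relies on (nonnegative,
#' finite, unique identifiers) and fills in placeholder identifiers when
#' none are present.
#'
#' @param x numeric matrix (or object coercible to one), cells in rows.
#' @param cell_ids,gene_ids optional character vectors overriding the
#'   dimnames of `x`.
#' @return the validated matrix with complete dimnames.
#' @examples
#' m <- expression_matrix(matrix(0:5, nrow = 2))
#' rownames(m)
#' @export
expression_matrix <- function(x, cell_ids = NULL, gene_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x))
    stop("expression values must be numeric")
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("expression matrix must have at least one cell and one gene")
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains NA or non-finite values")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at cell %d, gene %d",
                 bad[1L], bad[2L]))
  }
  if (!is.null(cell_ids)) rownames(x) <- cell_ids
  if (!is.null(gene_ids)) colnames(x) <- gene_ids
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("cell_%d", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("gene_%d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicated cell identifiers")
  if (anyDuplicated(colnames(x)))
    stop("duplicated gene identifiers")
  x
}

#' Read an expression matrix from disk
#'
#' Supported formats: dense delimited text (`dense_csv`, `dense_tsv`) with
#' an optional header row of gene identifiers and an optional first column
#' of cell identifiers, and Matrix Market coordinate triplets
#' (`mtx_triplet`) with 10x-style one-column sidecar files (`barcodes.tsv`
#' for cells, `features.tsv` or `genes.tsv` for genes) next to the `.mtx`
#' file.  The returned matrix is always cells x genes; set
#' `transpose = TRUE` for sources stored genes x cells (the 10x
#' convention).
#'
#' @param path file to read (the `.mtx` file itself for `mtx_triplet`).
#' @param format one of `"dense_csv"`, `"dense_tsv"`, `"mtx_triplet"`.
#' @param transpose if `TRUE` the source is genes x cells and is flipped.
#' @return numeric matrix, cells in rows (see [expression_matrix()]).
#' @export
read_matrix <- function(path, format = c("dense_csv", "dense_tsv", "mtx_triplet"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  m <- switch(format,
              dense_csv = read_dense(path, sep = ","),
              dense_tsv = read_dense(path, sep = "\t"),
              mtx_triplet = read_mtx_triplet(path))
  if (transpose) m <- t(m)
  expression_matrix(m)
}

read_dense <- function(path, sep) {
  first <- readLines(path, n = 1L)
  if (!nzchar(first))
    stop(sprintf("malformed header in %s: empty first line", path))
  cells1 <- strsplit(first, sep, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(cells1[length(cells1)])))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  row_ids <- NULL
  if (ncol(df) > 1L && !is.numeric(df[[1L]])) {
    row_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (!all(vapply(df, is.numeric, logical(1L)))) {
    bad <- which(!vapply(df, is.numeric, logical(1L)))[1L]
    stop(sprintf("non-numeric values in column %d of %s", bad, path))
  }
  m <- as.matrix(df)
  if (!is.null(row_ids)) rownames(m) <- row_ids
  if (!has_header) colnames(m) <- NULL
  if (anyNA(m))
    stop(sprintf("NA value at row %d of %s",
                 which(rowSums(is.na(m)) > 0)[1L], path))
  m
}

read_mtx_triplet <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  dir <- dirname(path)
  sidecar <- function(names) {
    for (nm in names) {
      f <- file.path(dir, nm)
      if (file.exists(f)) return(readLines(f))
    }
    NULL
  }
  barcodes <- sidecar(c("barcodes.tsv", "barcodes.txt"))
  features <- sidecar(c("features.tsv", "genes.tsv", "features.txt"))
  # features label whichever axis matches their length; barcodes the other
  if (!is.null(features) && length(features) == nrow(m) &&
      (is.null(barcodes) || length(barcodes) == ncol(m))) {
    rownames(m) <- features
    if (!is.null(barcodes)) colnames(m) <- barcodes
  } else {
    if (!is.null(barcodes) && length(barcodes) == nrow(m))
      rownames(m) <- barcodes
    if (!is.null(features) && length(features) == ncol(m))
      colnames(m) <- features
  }
  m
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_matrix()]: `read_matrix(path, format)` on the written
#' file reproduces the matrix to float round-trip precision.  For
#' `mtx_triplet` the sidecar identifier files (`barcodes.tsv`,
#' `features.tsv`) are written next to the `.mtx` file.
#'
#' @param x expression matrix, cells in rows.
#' @param path destination file.
#' @param format one of `"dense_csv"`, `"dense_tsv"`, `"mtx_triplet"`.
#' @export
write_matrix <- function(x, path, format = c("dense_csv", "dense_tsv", "mtx_triplet")) {
  format <- match.arg(format)
  x <- expression_matrix(x)
  if (format == "mtx_triplet") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    dir <- dirname(path)
    writeLines(rownames(x), file.path(dir, "barcodes.tsv"))
    writeLines(colnames(x), file.path(dir, "features.tsv"))
  } else {
    sep <- if (format == "dense_csv") "," else "\t"
    df <- data.frame(cell = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  }
  invisible(NULL)
}
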