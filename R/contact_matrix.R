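# ContactMatrix: a symmetric nonnegative matrix over a BinTable, carrying a
# retained-bin mask and a processing-stage tag.

#' Construct a ContactMatrix container
#'
#' @param mat Square symmetric nonnegative matrix.
#' @param bins `BinTable` describing the rows/columns (retained bins only).
#' @param stage One of `"raw"`, `"filtered"`, `"normalized"`.
#' @param mask Logical vector over the *original* bin table marking retained
#'   bins; defaults to all retained.
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(mat, bins, stage = "raw", mask = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("matrix must be square")
  if (!is.null(bins) && nrow(bins) != nrow(mat)) {
    stop("bin table does not match matrix dimension")
  }
  if (any(mat < 0)) stop("contact matrix must be nonnegative")
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat)))) {
    stop("contact matrix must be symmetric")
  }
  if (is.null(mask)) mask <- rep(TRUE, nrow(mat))
  structure(list(mat = mat, bins = bins, stage = stage, mask = mask),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix [%s]: %d x %d bins, total %.4g\n",
              x$stage, nrow(x$mat), ncol(x$mat), sum(x$mat)))
  invisible(x)
}

#' @export
dim.ContactMatrix <- function(x) dim(x$mat)

#' Write / read a contact matrix as dense tab-separated text
#'
#' The header row and first column carry bin ids (`chrom:start-end`).
#'
#' @param M A `ContactMatrix`.
#' @param path File path.
#' @export
write_contact_matrix <- function(M, path) {
  ids <- bin_ids(M$bins)
  m <- M$mat
  rownames(m) <- colnames(m) <- ids
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @param bins Optional `BinTable`; if omitted it is rebuilt from the ids.
#' @param stage Stage tag for the returned object.
#' @export
read_contact_matrix <- function(path, bins = NULL, stage = "raw") {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  if (is.null(bins)) bins <- ids_to_bins(rownames(m))
  contact_matrix(m, bins, stage = stage)
}

#' Write / read a contact matrix in MatrixMarket coordinate format
#'
#' The bin table is written alongside as a BED-like sidecar when `bed_path`
#' is given.
#'
#' @param M A `ContactMatrix`.
#' @param path `.mtx` file path.
#' @param bed_path Optional sidecar path for the bin table.
#' @export
write_contact_mtx <- function(M, path, bed_path = NULL) {
  Matrix::writeMM(Matrix::Matrix(M$mat, sparse = TRUE), path)
  if (!is.null(bed_path)) write_bed_like(M$bins, bed_path)
  invisible(path)
}

#' @rdname write_contact_mtx
#' @param bins `BinTable` for the matrix rows/columns.
#' @param stage Stage tag.
#' @export
read_contact_mtx <- function(path, bins, stage = "raw") {
  m <- as.matrix(Matrix::readMM(path))
  contact_matrix(m, bins, stage = stage)
}

bin_ids <- function(bins) {
  sprintf("%s:%d-%d", bins$chrom, as.integer(bins$start),
          as.integer(bins$end))
}

ids_to_bins <- function(ids) {
  parts <- regmatches(ids, regexec("^(.*):([0-9]+)-([0-9]+)$", ids))
  bins <- data.frame(
    bin = seq_along(ids) - 1L,
    chrom = vapply(parts, `[`, "", 2L),
    start = as.numeric(vapply(parts, `[`, "", 3L)),
    end = as.numeric(vapply(parts, `[`, "", 4L)),
    frag_first = NA_integer_, frag_last = NA_integer_,
    stringsAsFactors = FALSE
  )
  class(bins) <- c("BinTable", "data.frame")
  bins
}
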