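# Matrix readers/writers shared by the command-line interface.  The
# delimited dialect is comma- or tab-separated, no header, '.' decimal,
# rows are observations; the binary container is a serialized R matrix
# (RDS), roundtripping at full precision.

#' Read and write data matrices
#'
#' \code{read_matrix} reads an \eqn{n \times d} numeric matrix from a
#' delimited text file (comma or tab separated, no header) or from a
#' binary RDS container; \code{write_matrix} is its mirror.  Text output
#' uses \code{\%.17g} so a delimited roundtrip reproduces values to full
#' double precision.
#'
#' @param path file path.
#' @param format \code{"delimited"} (default) or \code{"binary"}.
#' @param A numeric matrix to write.
#' @param sep field separator for delimited output; default comma.
#' @return \code{read_matrix}: a numeric matrix. \code{write_matrix}:
#'   \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_matrix(matrix(1:6 / 7, 3, 2), f)
#' read_matrix(f)
#' @export
read_matrix <- function(path, format = c("delimited", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  if (format == "binary") {
    A <- readRDS(path)
    if (!is.matrix(A) || !is.numeric(A)) {
      stop(sprintf("binary container '%s' does not hold a numeric matrix",
                   path), call. = FALSE)
    }
    return(A)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(sprintf("empty file: '%s'", path), call. = FALSE)
  }
  parts <- strsplit(lines, "[,\t]")
  widths <- lengths(parts)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row in '%s': line %d has %d fields, expected %d",
                 path, bad, widths[bad], widths[1L]), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(trimws(unlist(parts))))
  if (anyNA(vals)) {
    bad <- (which(is.na(vals))[1L] - 1L) %/% widths[1L] + 1L
    stop(sprintf("non-numeric cell in '%s' at line %d", path, bad),
         call. = FALSE)
  }
  matrix(vals, nrow = length(lines), byrow = TRUE)
}

#' @rdname read_matrix
#' @export
write_matrix <- function(A, path, format = c("delimited", "binary"),
                         sep = ",") {
  format <- match.arg(format)
  check_matrix(A)
  if (format == "binary") {
    saveRDS(A, path)
  } else {
    txt <- apply(A, 1L, function(row) {
      paste(sprintf("%.17g", row), collapse = sep)
    })
    writeLines(txt, path)
  }
  invisible(path)
}
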