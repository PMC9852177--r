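#' Specify a data-oblivious random sketch
#'
#' A sketch specification fully determines the law of the random \eqn{k
#' \times n} sketching matrix \eqn{S} used to compress an \eqn{n \times d}
#' data matrix \eqn{A} into the \eqn{k \times d} surrogate \eqn{SA}.  Four
#' families are supported:
#' \describe{
#'   \item{\code{gaussian}}{independent \eqn{N(0, 1/k)} entries.}
#'   \item{\code{hadamard}}{the subsampled randomized Hadamard transform
#'     \eqn{S = \Phi H D/\sqrt{k}}: a Rademacher sign flip \eqn{D}, a
#'     Sylvester Hadamard matrix \eqn{H} of order \eqn{n' = 2^{\lceil\log_2
#'     n\rceil}} (the data are zero-padded to \eqn{n'} rows), and a row
#'     sampler \eqn{\Phi} drawing \code{k} rows of \eqn{H}, with
#'     replacement by default.}
#'   \item{\code{clarkson_woodruff}}{the CountSketch: each of the \eqn{n}
#'     input rows is assigned a uniformly chosen output row and a
#'     Rademacher sign, so \eqn{S} has exactly one nonzero per column and
#'     \eqn{SA} costs \eqn{O(nd)}.}
#'   \item{\code{uniform}}{uniform row subsampling with replacement,
#'     rescaled by \eqn{\sqrt{n/k}}.}
#' }
#'
#' The same specification plus the same seed and input always reproduces
#' bit-identical output.  Within one draw the randomness is consumed in a
#' fixed documented order (signs before row choices), so the dense operator
#' returned by [sketch_matrix()] realizes exactly the sketch that
#' [sketch_apply()] applies.
#'
#' @param family sketch family, one of \code{"gaussian"},
#'   \code{"hadamard"}, \code{"clarkson_woodruff"}, \code{"uniform"}.
#'   Unambiguous abbreviations (e.g. \code{"cw"}) are accepted.
#' @param k sketch size (number of rows of \eqn{SA}), a positive integer.
#' @param row_sampling for the Hadamard family only: \code{"with_replacement"}
#'   (default) or \code{"without_replacement"}.
#' @param seed optional integer seed; \code{NULL} uses the current RNG state.
#' @return An object of class \code{"sketch_spec"}.
#' @examples
#' spec <- sketch_spec("clarkson_woodruff", k = 50, seed = 1)
#' A <- matrix(rnorm(400), 100, 4)
#' dim(sketch_apply(A, spec))
#' @seealso [sketch_apply()], [sketch_matrix()]
#' @export
sketch_spec <- function(family = c("gaussian", "hadamard", "clarkson_woodruff",
                                   "uniform"),
                        k,
                        row_sampling = c("with_replacement",
                                         "without_replacement"),
                        seed = NULL) {
  if (length(family) == 1L && family == "cw") family <- "clarkson_woodruff"
  family <- match.arg(family)
  row_sampling <- match.arg(row_sampling)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 1 ||
      k != round(k)) {
    stop("'k' must be a positive integer", call. = FALSE)
  }
  if (row_sampling == "without_replacement" && family != "hadamard") {
    stop("row_sampling = \"without_replacement\" applies to the hadamard family only",
         call. = FALSE)
  }
  structure(
    list(family = family, k = as.integer(k), row_sampling = row_sampling,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sketch_spec"
  )
}

#' @export
print.sketch_spec <- function(x, ...) {
  cat("Sketch specification\n")
  cat("  family      :", x$family, "\n")
  cat("  sketch size :", x$k, "\n")
  if (x$family == "hadamard") cat("  row sampling:", x$row_sampling, "\n")
  cat("  seed        :", if (is.null(x$seed)) "<current RNG>" else x$seed, "\n")
  invisible(x)
}

# shared input validation for data matrices
check_matrix <- function(A, arg = "A") {
  if (!is.matrix(A) || !is.numeric(A)) {
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(A) < 1L || ncol(A) < 1L) {
    stop(sprintf("'%s' must have at least one row and one column", arg),
         call. = FALSE)
  }
  if (!all(is.finite(A))) {
    stop(sprintf("'%s' contains non-finite entries", arg), call. = FALSE)
  }
  invisible(A)
}
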