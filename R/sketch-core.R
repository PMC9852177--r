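#' Fast Walsh-Hadamard transform
#'
#' Computes \eqn{Hx} for the Sylvester-ordered \eqn{\pm 1} Hadamard matrix
#' of order \code{length(x)} by the in-place butterfly recursion in
#' \eqn{O(n \log n)} operations.  Note \eqn{HH = nI}, so
#' \code{fwht(fwht(x))} equals \code{length(x) * x}.
#'
#' @param x numeric vector whose length is a power of two.
#' @return The transformed vector \eqn{Hx}.
#' @examples
#' fwht(c(1, 0))        # c(1, 1)
#' fwht(fwht(c(3, 1, 4, 1))) / 4
#' @export
fwht <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop("'x' must be a non-empty numeric vector", call. = FALSE)
  }
  n <- length(x)
  if (bitwAnd(n, n - 1L) != 0L) {
    stop("length of 'x' must be a power of two", call. = FALSE)
  }
  drop(fwht_mat(matrix(x, ncol = 1L)))
}

# column-wise fast Walsh-Hadamard transform of a matrix whose row count is a
# power of two; each doubling stage is a vectorized butterfly over all columns
fwht_mat <- function(X) {
  n <- nrow(X)
  h <- 1L
  while (h < n) {
    top <- rep(c(TRUE, FALSE), each = h, length.out = n)
    a <- X[top, , drop = FALSE]
    b <- X[!top, , drop = FALSE]
    X[top, ] <- a + b
    X[!top, ] <- a - b
    h <- h * 2L
  }
  X
}

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

# Draw one sketch realization.  Randomness is consumed in a fixed order per
# family (signs, then row choices) so sketch_apply and sketch_matrix realize
# the same operator from the same seed:
#   gaussian          : the k*n entries of S, column-major
#   uniform           : k sampled row indices
#   clarkson_woodruff : n Rademacher signs, then n output-row assignments
#   hadamard          : n' Rademacher signs, then k sampled rows of H
draw_sketch <- function(spec, n) {
  k <- spec$k
  with_seed(spec$seed, switch(
    spec$family,
    gaussian = list(S = matrix(stats::rnorm(k * n, sd = 1 / sqrt(k)), k, n)),
    uniform = list(rows = sample.int(n, k, replace = TRUE)),
    clarkson_woodruff = list(signs = rademacher(n),
                             buckets = sample.int(k, n, replace = TRUE)),
    hadamard = {
      np <- next_pow2(n)
      if (spec$row_sampling == "without_replacement" && k > np) {
        stop(sprintf(paste0("hadamard sketch without replacement needs k <= ",
                            "padded dimension (%d), got k = %d"), np, k),
             call. = FALSE)
      }
      list(np = np,
           signs = rademacher(np),
           rows = sample.int(np, k,
                             replace = spec$row_sampling == "with_replacement"))
    }
  ))
}

#' Apply a random sketch to a data matrix
#'
#' Draws one realization of the sketching matrix \eqn{S} described by
#' \code{spec} and returns the sketched data \eqn{SA} (\eqn{k \times d}).
#' Structured families never materialize \eqn{S}: the Hadamard sketch uses
#' the fast Walsh-Hadamard transform (\eqn{O(n' d \log n')} after zero
#' padding to \eqn{n'} rows), the Clarkson-Woodruff sketch streams each row
#' into its output bucket (\eqn{O(nd)}), and the uniform sketch gathers
#' \eqn{k} rescaled rows.
#'
#' @param A numeric data matrix, rows are observations.
#' @param spec a [sketch_spec()].
#' @return The \eqn{k \times d} sketched matrix.
#' @examples
#' A <- matrix(rnorm(64 * 3), 64, 3)
#' SA <- sketch_apply(A, sketch_spec("hadamard", k = 16, seed = 2))
#' @export
sketch_apply <- function(A, spec) {
  check_matrix(A)
  stopifnot(inherits(spec, "sketch_spec"))
  n <- nrow(A)
  k <- spec$k
  r <- draw_sketch(spec, n)
  switch(
    spec$family,
    gaussian = r$S %*% A,
    uniform = sqrt(n / k) * A[r$rows, , drop = FALSE],
    clarkson_woodruff = {
      S <- Matrix::sparseMatrix(i = r$buckets, j = seq_len(n), x = r$signs,
                                dims = c(k, n))
      as.matrix(S %*% A)
    },
    hadamard = {
      np <- r$np
      X <- r$signs * rbind(A, matrix(0, np - n, ncol(A)))  # D, zero padding
      HX <- fwht_mat(X)                                    # H
      HX[r$rows, , drop = FALSE] / sqrt(k)                 # Phi, 1/sqrt(k)
    }
  )
}

#' Materialize a sketching matrix (dense oracle)
#'
#' Returns the dense \eqn{k \times n} sketching matrix \eqn{S} for the
#' realization that [sketch_apply()] would use with the same specification
#' and seed.  Intended for testing and small problems; the matrix-free
#' [sketch_apply()] is the scalable interface.
#'
#' @param spec a [sketch_spec()].
#' @param n number of input rows.  For the Hadamard family the returned
#'   matrix has \code{next_pow2(n)} columns acting on the zero-padded data;
#'   columns beyond \code{n} multiply padding rows only.
#' @return A dense numeric matrix.
#' @examples
#' spec <- sketch_spec("uniform", k = 2, seed = 1)
#' S <- sketch_matrix(spec, n = 4)
#' A <- diag(4)
#' all.equal(S %*% A, sketch_apply(A, spec))
#' @export
sketch_matrix <- function(spec, n) {
  stopifnot(inherits(spec, "sketch_spec"))
  k <- spec$k
  r <- draw_sketch(spec, n)
  switch(
    spec$family,
    gaussian = r$S,
    uniform = {
      S <- matrix(0, k, n)
      S[cbind(seq_len(k), r$rows)] <- sqrt(n / k)
      S
    },
    clarkson_woodruff = {
      S <- matrix(0, k, n)
      S[cbind(r$buckets, seq_len(n))] <- r$signs
      S
    },
    hadamard = {
      H <- hadamard_matrix(r$np)
      (H[r$rows, , drop = FALSE] %*% diag(r$signs)) / sqrt(k)
    }
  )
}

# Sylvester construction of the +/-1 Hadamard matrix of order n (power of 2)
hadamard_matrix <- function(n) {
  if (bitwAnd(n, n - 1L) != 0L) {
    stop("Hadamard order must be a power of two", call. = FALSE)
  }
  H <- matrix(1, 1, 1)
  while (nrow(H) < n) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}
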