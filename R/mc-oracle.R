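# Monte-Carlo oracles for the embedding and convergence probabilities.
# The central statistic is the distortion factor of one sketch draw,
#   epsilon = sigma_max(I_d - U'S'SU)
#           = max(|1 - lambda_min(U'S'SU)|, |1 - lambda_max(U'S'SU)|),
# the smallest epsilon for which that draw is an epsilon-subspace
# embedding.  All eigencomputations run on the d x d Gram matrix.

#' Orthonormal basis of the column space
#'
#' Computes the matrix of left singular vectors \eqn{U} of \code{A} and
#' its numerical rank (tolerance \code{max(n, d) * .Machine$double.eps *
#' max singular value}).  Theory operations require full column rank; a
#' rank-deficient input raises an error naming the deficiency.
#'
#' @param A numeric matrix with \code{nrow(A) >= ncol(A)}.
#' @param require_full_rank raise an error when rank < d (default TRUE).
#' @return A list with \code{U} (n x rank orthonormal columns) and
#'   \code{rank}.
#' @examples
#' ob <- orthonormal_basis(matrix(rnorm(250), 50, 5))
#' crossprod(ob$U)  # ~ identity
#' @export
orthonormal_basis <- function(A, require_full_rank = TRUE) {
  check_matrix(A)
  n <- nrow(A)
  d <- ncol(A)
  if (n < d) stop("'A' must be tall: nrow(A) >= ncol(A)", call. = FALSE)
  sv <- svd(A)
  tol <- max(n, d) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (require_full_rank && rank < d) {
    stop(sprintf("'A' is rank deficient: rank %d < %d columns (%d deficient)",
                 rank, d, d - rank), call. = FALSE)
  }
  list(U = sv$u[, seq_len(rank), drop = FALSE], rank = rank)
}

#' Distortion factor of a sketched basis
#'
#' Given an orthonormal basis \code{U} and its sketch \code{SU}, returns
#' \eqn{\max(|1 - \lambda_{min}(M)|, |1 - \lambda_{max}(M)|)} with
#' \eqn{M = (SU)'(SU)}, computed by a symmetric \eqn{d \times d}
#' eigendecomposition.  This equals \eqn{\sigma_{max}(I_d - M)}, the
#' smallest \eqn{\epsilon} for which this sketch realization is an
#' \eqn{\epsilon}-subspace embedding.
#'
#' @param U orthonormal basis (Gram deviation from the identity at most
#'   \code{1e-8} in max norm).
#' @param SU the sketched basis, \code{k x d}.
#' @return A non-negative scalar.
#' @examples
#' U <- qr.Q(qr(matrix(rnorm(80), 20, 4)))
#' distortion(U, sketch_apply(U, sketch_spec("gaussian", k = 100, seed = 1)))
#' @export
distortion <- function(U, SU) {
  check_matrix(U, "U")
  check_matrix(SU, "SU")
  if (ncol(SU) != ncol(U)) {
    stop("'U' and 'SU' must have the same number of columns", call. = FALSE)
  }
  gram_dev <- max(abs(crossprod(U) - diag(ncol(U))))
  if (gram_dev > 1e-8) {
    stop(sprintf("'U' is not orthonormal: max |U'U - I| = %.2e", gram_dev),
         call. = FALSE)
  }
  ev <- eigen(crossprod(SU), symmetric = TRUE, only.values = TRUE)$values
  max(abs(1 - ev[length(ev)]), abs(1 - ev[1]))
}

#' Simulate Gaussian-sketch distortions via the Wishart shortcut
#'
#' For the Gaussian sketch, \eqn{U'S'SU \sim Wishart(k, I_d/k)}
#' independently of \eqn{n} and of the data (pivotality), so distortions
#' can be simulated directly from \eqn{W = G'G} with \eqn{G} a \eqn{k
#' \times d} matrix of \eqn{N(0, 1/k)} entries, never forming an
#' \eqn{n}-dimensional object.
#'
#' @param k sketch size.
#' @param d number of variables.
#' @param B number of Monte-Carlo draws.
#' @param seed optional integer seed.
#' @return A \code{"distortion_sample"} object: list with \code{draws}
#'   (length \code{B}), \code{k}, \code{d}, \code{family}, \code{seed}.
#' @examples
#' ds <- simulate_gaussian_distortions(k = 200, d = 10, B = 100, seed = 1)
#' summary(ds$draws)
#' @export
simulate_gaussian_distortions <- function(k, d, B, seed = NULL) {
  stopifnot(k >= 1, d >= 1)  # k < d is allowed: rank deficiency forces
                             # lambda_min = 0 and so distortion >= 1
  if (!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B)) {
    stop("'B' must be a positive integer", call. = FALSE)
  }
  draws <- with_seed(seed, vapply(seq_len(B), function(b) {
    G <- matrix(stats::rnorm(k * d, sd = 1 / sqrt(k)), k, d)
    ev <- eigen(crossprod(G), symmetric = TRUE, only.values = TRUE)$values
    max(abs(1 - ev[d]), abs(1 - ev[1]))
  }, numeric(1)))
  new_distortion_sample(draws, k, d, "gaussian", seed)
}

#' Monte-Carlo distortions of a sketch family on a given dataset
#'
#' The oracle procedure: compute the orthonormal basis \eqn{U} of
#' \code{A} once, then for each of \code{B} independent sketch draws
#' record the distortion of \eqn{SU}.  Works for every sketch family;
#' for the Gaussian family the result is distributionally identical to
#' [simulate_gaussian_distortions()] regardless of \code{A}.
#'
#' @param A data matrix of full column rank.
#' @param spec a [sketch_spec()]; its \code{seed} field is ignored in
#'   favour of \code{seed} here, which seeds the whole loop.
#' @param B number of sketch draws.
#' @param seed optional integer seed for the whole loop.
#' @return A \code{"distortion_sample"} object.
#' @examples
#' A <- matrix(rnorm(2048 * 5), 2048, 5)
#' ds <- sketch_distortions(A, sketch_spec("clarkson_woodruff", k = 100),
#'                          B = 50, seed = 3)
#' @export
sketch_distortions <- function(A, spec, B, seed = NULL) {
  stopifnot(inherits(spec, "sketch_spec"))
  if (!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B)) {
    stop("'B' must be a positive integer", call. = FALSE)
  }
  U <- orthonormal_basis(A)$U
  spec_b <- spec
  spec_b$seed <- NULL  # draws come from the loop-level stream
  draws <- with_seed(seed, vapply(seq_len(B), function(b) {
    distortion(U, sketch_apply(U, spec_b))
  }, numeric(1)))
  new_distortion_sample(draws, spec$k, ncol(U), spec$family, seed)
}

new_distortion_sample <- function(draws, k, d, family, seed) {
  structure(list(draws = draws, k = k, d = d, family = family,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "distortion_sample")
}

#' @export
print.distortion_sample <- function(x, ...) {
  cat(sprintf("Distortion sample: B = %d draws, family = %s, k = %d, d = %d\n",
              length(x$draws), x$family, x$k, x$d))
  print(stats::quantile(x$draws, c(0.05, 0.25, 0.5, 0.75, 0.95)))
  invisible(x)
}

#' Monte-Carlo estimate of the convergence probability
#'
#' Estimates \eqn{\Pr(\lambda_{min}(W) > 1/2)} for \eqn{W \sim
#' Wishart(k, I_d/k)} by direct simulation.  For the Gaussian sketch
#' this is the exact convergence probability of the preconditioned
#' iteration; [convergence_prob_tw()] is its Tracy-Widom approximation.
#'
#' @inheritParams simulate_gaussian_distortions
#' @return The estimated probability (binomial standard error
#'   \eqn{\sqrt{p(1-p)/B}}).
#' @examples
#' mc_lambda_min_prob(400, 20, B = 200, seed = 1)   # near 1
#' @export
mc_lambda_min_prob <- function(k, d, B, seed = NULL) {
  check_kd(k, d, strict = TRUE)
  with_seed(seed, mean(vapply(seq_len(B), function(b) {
    G <- matrix(stats::rnorm(k * d, sd = 1 / sqrt(k)), k, d)
    min(eigen(crossprod(G), symmetric = TRUE, only.values = TRUE)$values) > 0.5
  }, logical(1))))
}

#' Empirical embedding probability
#'
#' The Monte-Carlo estimate \eqn{B^{-1}\sum_b 1(\epsilon^{[b]} \le
#' \epsilon)}: the fraction of simulated distortions at most
#' \code{epsilon}.  A right-continuous step function of \code{epsilon}.
#'
#' @param sample a \code{"distortion_sample"}.
#' @param epsilon tolerance value(s).
#' @return Estimated probabilities in \eqn{[0, 1]}.
#' @examples
#' ds <- simulate_gaussian_distortions(200, 10, 200, seed = 1)
#' empirical_embedding_prob(ds, embedding_quantile_tw(0.5, 200, 10))
#' @export
empirical_embedding_prob <- function(sample, epsilon) {
  stopifnot(inherits(sample, "distortion_sample"))
  vapply(epsilon, function(e) mean(sample$draws <= e), numeric(1))
}
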