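# Synthetic data emulating the study designs used to probe sketch
# behaviour: rows i.i.d. N(0, Sigma) with AR(1) column correlation
# Sigma_ij = rho^|i-j|, a linear-model response generator on top, uniform
# row bootstrapping, and leverage-score diagnostics.

#' Simulate a design matrix with AR(1) column correlation
#'
#' Rows are independent draws from \eqn{N(0, \Sigma)} with
#' \eqn{\Sigma_{ij} = \rho^{|i-j|}}, generated by the stationary AR(1)
#' recursion across columns (\eqn{O(nd)}; no \eqn{d \times d}
#' factorization).
#'
#' @param n number of rows (observations).
#' @param d number of columns (variables).
#' @param rho autoregressive correlation, \eqn{|\rho| < 1}; default 0.5.
#' @param seed optional integer seed.
#' @return An \code{n x d} numeric matrix.
#' @examples
#' X <- sim_ar1_design(1000, 10, rho = 0.5, seed = 1)
#' cor(X[, 1], X[, 2])  # ~ 0.5
#' @export
sim_ar1_design <- function(n, d, rho = 0.5, seed = NULL) {
  stopifnot(n >= 1, d >= 1)
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1) {
    stop("'rho' must satisfy |rho| < 1", call. = FALSE)
  }
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * d), n, d)
    if (d > 1L && rho != 0) {
      scale <- sqrt(1 - rho^2)
      for (j in 2:d) X[, j] <- rho * X[, j - 1L] + scale * X[, j]
    }
    X
  })
}

#' Simulate a linear regression problem
#'
#' Generates \code{X} from [sim_ar1_design()] and a response
#' \eqn{y = X\beta^* + \sigma z} with \eqn{\beta^*} and \eqn{z} standard
#' normal.  Randomness is consumed in the order: design entries, then
#' \eqn{\beta^*}, then noise, so the design is reproducible across
#' different noise settings at a fixed seed.
#'
#' @param n number of observations, \code{n > d}.
#' @param d number of predictors.
#' @param noise_sd residual standard deviation \eqn{\sigma}; default 1.
#'   \code{noise_sd = 0} puts \code{y} exactly in the column space of
#'   \code{X}.
#' @param rho AR(1) correlation of the design; default 0.5.
#' @param seed optional integer seed.
#' @return A list with \code{X} (n x d), \code{y} (length n) and
#'   \code{beta_star}.
#' @examples
#' sim <- sim_regression(200, 3, seed = 1)
#' coef(lm(sim$y ~ sim$X - 1))
#' @export
sim_regression <- function(n, d, noise_sd = 1, rho = 0.5, seed = NULL) {
  stopifnot(n > d, d >= 1, noise_sd >= 0)
  with_seed(seed, {
    X <- sim_ar1_design(n, d, rho = rho)
    beta_star <- stats::rnorm(d)
    y <- drop(X %*% beta_star)
    if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
    list(X = X, y = y, beta_star = beta_star)
  })
}

#' Leverage scores of a data matrix
#'
#' The leverage score of row \eqn{i} is \eqn{h_i = \|u_i\|_2^2}, the
#' squared norm of the \eqn{i}th row of the orthonormal basis of
#' \code{A}.  Scores lie in \eqn{[0, 1]}, sum to \eqn{rank(A)}, and
#' their maximum is at least the average \eqn{d/n}; a vanishing maximum
#' leverage is the regularity condition under which the structured
#' sketches inherit the Gaussian limit.
#'
#' @param A numeric matrix with \code{nrow(A) >= ncol(A)}; rank
#'   deficiency is allowed (the sum then equals the rank).
#' @return An object of class \code{"leverage_profile"}: list with
#'   \code{scores}, \code{max_score}, \code{sum_score}, \code{rank}.
#' @examples
#' lp <- leverage_scores(sim_ar1_design(100, 5, seed = 1))
#' lp$sum_score   # 5
#' @export
leverage_scores <- function(A) {
  ob <- orthonormal_basis(A, require_full_rank = FALSE)
  scores <- rowSums(ob$U^2)
  structure(list(scores = scores, max_score = max(scores),
                 sum_score = sum(scores), rank = ob$rank),
            class = "leverage_profile")
}

#' @export
print.leverage_profile <- function(x, ...) {
  cat(sprintf("Leverage profile: n = %d, rank = %d, sum = %.6f, max = %.6f\n",
              length(x$scores), x$rank, x$sum_score, x$max_score))
  invisible(x)
}

#' Enlarge a dataset by row bootstrapping
#'
#' Samples \code{factor * nrow(A)} rows of \code{A} uniformly with
#' replacement.  Bootstrapping a dataset to several times its size
#' spreads leverage mass over duplicated rows, which is the standard way
#' to probe how sketch behaviour improves as \eqn{n} grows with the
#' column structure held fixed.
#'
#' @param A numeric matrix.
#' @param factor integer enlargement factor, at least 1.
#' @param seed optional integer seed.
#' @return A matrix with \code{factor * nrow(A)} rows.
#' @examples
#' dim(bootstrap_rows(matrix(rnorm(20), 10, 2), factor = 10, seed = 1))
#' @export
bootstrap_rows <- function(A, factor, seed = NULL) {
  check_matrix(A)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stop("'factor' must be an integer >= 1", call. = FALSE)
  }
  n <- nrow(A)
  idx <- with_seed(seed, sample.int(n, factor * n, replace = TRUE))
  A[idx, , drop = FALSE]
}
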