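# Sketch-based least squares: the Hessian-sketch preconditioned iteration
#   beta <- beta + (Xs'Xs)^{-1} X'(y - X beta),   Xs = S X,
# which converges iff lambda_max((Xs'Xs)^{-1} X'X) < 2, and the one-shot
# sketch-and-solve estimator with its distortion-based error bound.

#' Sketched least squares
#'
#' Fits an ordinary least squares regression of \code{y} on \code{X}
#' using a random sketch, by one of two strategies:
#' \describe{
#'   \item{\code{"precondition"}}{the Hessian sketch: iterate
#'     \eqn{\beta^{(t+1)} = \beta^{(t)} + (\tilde X'\tilde X)^{-1}
#'     X'(y - X\beta^{(t)})} with \eqn{\tilde X = SX}, declaring
#'     convergence the first time \eqn{\|X'(y - X\beta^{(t)})\|_2 <}
#'     \code{tol}.  Converges to the exact OLS solution whenever
#'     \eqn{\lambda_{max}((\tilde X'\tilde X)^{-1}X'X) < 2}.}
#'   \item{\code{"solve"}}{sketch-and-solve: regress \eqn{Sy} on
#'     \eqn{SX}.  Fast but only approximate; the realized distortion
#'     \eqn{\epsilon} of the sketch on \eqn{(y, X)} bounds the error by
#'     \eqn{\|\beta_S - \beta_F\|_2^2 \le \epsilon^2
#'     RSS_F/\sigma_{min}^2(X)}.}
#' }
#'
#' @param X numeric design matrix (n x d, full column rank).
#' @param y numeric response vector of length \code{nrow(X)}.
#' @param spec a [sketch_spec()] describing the sketch.
#' @param method \code{"precondition"} (default) or \code{"solve"}.
#' @param beta0 starting value for the iteration (default zero vector).
#' @param tol absolute tolerance on the gradient norm
#'   \eqn{\|X'(y - X\beta)\|_2}; default \code{1e-6}.
#' @param max_iter iteration cap; default 2000.
#' @return An object of class \code{"sketch_lm"} with components
#'   \code{coefficients}, \code{fitted.values}, \code{residuals},
#'   \code{method}, \code{spec}, and, for \code{"precondition"},
#'   \code{converged}, \code{iterations}, \code{final_gradient_norm},
#'   \code{gradient_path}; for \code{"solve"}, \code{bound} (see
#'   [sketch_ols_bound()]).
#' @examples
#' sim <- sim_regression(n = 500, d = 5, seed = 1)
#' fit <- sketch_lm(sim$X, sim$y, sketch_spec("gaussian", k = 100, seed = 2))
#' coef(fit)
#' @seealso [convergence_condition()], [empirical_convergence_prob()]
#' @export
sketch_lm <- function(X, y, spec, method = c("precondition", "solve"),
                      beta0 = NULL, tol = 1e-6, max_iter = 2000) {
  method <- match.arg(method)
  check_matrix(X, "X")
  if (!is.numeric(y) || length(y) != nrow(X)) {
    stop("'y' must be a numeric vector with one element per row of 'X'",
         call. = FALSE)
  }
  fit <- if (method == "precondition") {
    hessian_sketch_iterate(X, y, spec, beta0 = beta0, tol = tol,
                           max_iter = max_iter)
  } else {
    sketch_ols_bound(X, y, spec)
  }
  beta <- if (method == "precondition") fit$beta else fit$beta_sketch
  out <- list(coefficients = beta,
              fitted.values = drop(X %*% beta),
              residuals = y - drop(X %*% beta),
              method = method, spec = spec, y = y)
  out <- c(out, fit[setdiff(names(fit), c("beta", "beta_sketch"))])
  class(out) <- "sketch_lm"
  out
}

#' Hessian-sketch preconditioned iteration
#'
#' The fixed-point iteration for the least-squares normal equations with
#' a sketched preconditioner.  Either a sketch specification or a
#' precomputed preconditioner Gram matrix \eqn{\tilde X'\tilde X} may be
#' supplied; the latter supports controlled experiments on the
#' convergence condition.  Convergence is declared the first time the
#' gradient norm drops below \code{tol}; iteration stops early, counted
#' as non-convergence, if the gradient norm exceeds \eqn{10^{12}} times
#' its initial value (divergence guard).
#'
#' @inheritParams sketch_lm
#' @param spec a [sketch_spec()], or \code{NULL} when \code{precond} is
#'   given.
#' @param precond optional \eqn{d \times d} preconditioner Gram matrix
#'   used in place of \eqn{(SX)'(SX)}.
#' @return A list: \code{beta}, \code{converged}, \code{iterations},
#'   \code{final_gradient_norm}, \code{gradient_path} (norms at each
#'   step, starting from the initial gradient).
#' @examples
#' sim <- sim_regression(300, 4, seed = 5)
#' hessian_sketch_iterate(sim$X, sim$y,
#'                        sketch_spec("gaussian", k = 80, seed = 6))$iterations
#' @export
hessian_sketch_iterate <- function(X, y, spec = NULL, precond = NULL,
                                   beta0 = NULL, tol = 1e-6,
                                   max_iter = 2000) {
  check_matrix(X, "X")
  d <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  if (is.null(precond)) {
    stopifnot(inherits(spec, "sketch_spec"))
    if (spec$k < d) {
      stop("sketch size k must be at least ncol(X) for an invertible preconditioner",
           call. = FALSE)
    }
    precond <- crossprod(sketch_apply(X, spec))
  }
  R <- tryCatch(chol(precond), error = function(e) {
    stop("preconditioner Gram matrix is singular (sketch lost rank)",
         call. = FALSE)
  })

  beta <- if (is.null(beta0)) numeric(d) else as.numeric(beta0)
  g <- Xty - drop(XtX %*% beta)
  gnorm <- sqrt(sum(g^2))
  path <- numeric(max_iter + 1L)
  path[1L] <- gnorm
  g0 <- max(gnorm, .Machine$double.xmin)
  iter <- 0L
  converged <- gnorm < tol
  while (!converged && iter < max_iter) {
    beta <- beta + backsolve(R, forwardsolve(t(R), g))
    iter <- iter + 1L
    g <- Xty - drop(XtX %*% beta)
    gnorm <- sqrt(sum(g^2))
    path[iter + 1L] <- gnorm
    if (gnorm < tol) {
      converged <- TRUE
    } else if (!is.finite(gnorm) || gnorm > 1e12 * g0) {
      break  # diverging; counts as non-convergence
    }
  }
  list(beta = beta, converged = converged, iterations = iter,
       final_gradient_norm = gnorm, gradient_path = path[seq_len(iter + 1L)])
}

#' Convergence condition for the preconditioned iteration
#'
#' Computes \eqn{\lambda_{max}((\tilde X'\tilde X)^{-1} X'X)} via the
#' symmetric generalized eigenproblem (Cholesky whitening, no explicit
#' inverse).  The iteration converges for every starting value if and
#' only if this eigenvalue is strictly below 2.
#'
#' @param XtX the exact Gram matrix \eqn{X'X} (symmetric positive
#'   definite).
#' @param sketched_XtX the preconditioner Gram matrix
#'   \eqn{\tilde X'\tilde X} (symmetric positive definite).
#' @return A list with \code{lambda_max} and \code{will_converge}.
#' @examples
#' convergence_condition(diag(2), diag(c(0.4, 1)))  # lambda_max 2.5: diverges
#' @export
convergence_condition <- function(XtX, sketched_XtX) {
  check_spd <- function(M, arg) {
    if (!is.matrix(M) || nrow(M) != ncol(M) ||
        max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
      stop(sprintf("'%s' must be a symmetric matrix", arg), call. = FALSE)
    }
    tryCatch(chol(M), error = function(e) {
      stop(sprintf("'%s' is not positive definite", arg), call. = FALSE)
    })
  }
  check_spd(XtX, "XtX")
  R <- check_spd(sketched_XtX, "sketched_XtX")
  # (Xs'Xs)^{-1} X'X is similar to R^{-T} X'X R^{-1}, which is symmetric
  W <- forwardsolve(t(R), XtX)
  W <- t(forwardsolve(t(R), t(W)))
  lam <- eigen(W, symmetric = TRUE, only.values = TRUE)$values[1L]
  list(lambda_max = lam, will_converge = lam < 2)
}

#' Empirical convergence probability of the preconditioned iteration
#'
#' Repeats the full pipeline (draw a sketch, build the preconditioner,
#' run the iteration) \code{R} times and reports the fraction of
#' converged runs with its binomial standard error.  A singular
#' preconditioner counts as non-convergence.
#'
#' @inheritParams sketch_lm
#' @param R number of independent replicates.
#' @param seed optional integer seed for the whole experiment.
#' @return A list: \code{estimate}, \code{se}, \code{n_converged},
#'   \code{R}.
#' @examples
#' sim <- sim_regression(1000, 5, seed = 1)
#' empirical_convergence_prob(sim$X, sim$y,
#'                            sketch_spec("gaussian", k = 100),
#'                            R = 20, seed = 2)
#' @export
empirical_convergence_prob <- function(X, y, spec, R, seed = NULL,
                                       tol = 1e-6, max_iter = 2000) {
  stopifnot(inherits(spec, "sketch_spec"))
  if (!is.numeric(R) || length(R) != 1L || R < 1 || R != round(R)) {
    stop("'R' must be a positive integer", call. = FALSE)
  }
  spec_b <- spec
  spec_b$seed <- NULL
  ok <- with_seed(seed, vapply(seq_len(R), function(r) {
    res <- tryCatch(
      hessian_sketch_iterate(X, y, spec_b, tol = tol, max_iter = max_iter),
      error = function(e) list(converged = FALSE)
    )
    isTRUE(res$converged)
  }, logical(1)))
  p <- mean(ok)
  list(estimate = p, se = sqrt(p * (1 - p) / R),
       n_converged = sum(ok), R = as.integer(R))
}

#' Sketch-and-solve OLS with its distortion error bound
#'
#' Solves the full and the sketched least-squares problems with one
#' sketch realization applied to the augmented matrix \eqn{A = (y, X)},
#' computes the realized distortion \eqn{\epsilon} of that same
#' realization, and checks the guarantee
#' \eqn{\|\beta_S - \beta_F\|_2^2 \le \epsilon^2 RSS_F /
#' \sigma_{min}^2(X)}, which holds for every
#' \eqn{\epsilon}-subspace embedding.
#'
#' @inheritParams sketch_lm
#' @return A list: \code{beta_full}, \code{beta_sketch},
#'   \code{rss_full}, \code{sigma_min_X}, \code{epsilon_used},
#'   \code{bound_satisfied}.
#' @examples
#' sim <- sim_regression(512, 5, seed = 1)
#' rep <- sketch_ols_bound(sim$X, sim$y, sketch_spec("gaussian", 50, seed = 2))
#' rep$bound_satisfied
#' @export
sketch_ols_bound <- function(X, y, spec) {
  check_matrix(X, "X")
  stopifnot(inherits(spec, "sketch_spec"))
  A <- cbind(y, X)
  sv <- svd(A)
  tolr <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tolr)
  if (r < ncol(X)) {
    stop("design matrix X is rank deficient", call. = FALSE)
  }
  # r may be d rather than d + 1 when y lies in col(X) (zero residual);
  # the embedding statement then concerns the rank-r basis of (y, X)
  SA <- sketch_apply(A, spec)
  idx <- seq_len(r)
  SU <- SA %*% sweep(sv$v[, idx, drop = FALSE], 2L, sv$d[idx], "/")
  eps <- distortion(sv$u[, idx, drop = FALSE], SU)

  ys <- SA[, 1L]
  Xs <- SA[, -1L, drop = FALSE]
  beta_full <- qr.coef(qr(X), y)
  qs <- qr(Xs)
  if (qs$rank < ncol(X)) {
    stop("sketched design matrix lost rank; increase k", call. = FALSE)
  }
  beta_sketch <- qr.coef(qs, ys)
  rss_full <- sum((y - X %*% beta_full)^2)
  smin <- min(svd(X, nu = 0, nv = 0)$d)
  lhs <- sum((beta_sketch - beta_full)^2)
  list(beta_full = beta_full, beta_sketch = beta_sketch,
       rss_full = rss_full, sigma_min_X = smin, epsilon_used = eps,
       bound_satisfied = lhs <= eps^2 * rss_full / smin^2 + 1e-12)
}

#' @export
print.sketch_lm <- function(x, ...) {
  cat("Sketched least squares (method =", x$method, ", family =",
      x$spec$family, ", k =", x$spec$k, ")\n")
  cat("Coefficients:\n")
  print(x$coefficients)
  if (x$method == "precondition") {
    cat(sprintf("%s after %d iterations (final gradient norm %.3e)\n",
                if (x$converged) "Converged" else "Did not converge",
                x$iterations, x$final_gradient_norm))
  } else {
    cat(sprintf("Realized distortion %.4f; error bound %s\n",
                x$epsilon_used,
                if (x$bound_satisfied) "satisfied" else "violated"))
  }
  invisible(x)
}

#' @export
summary.sketch_lm <- function(object, ...) {
  rss <- sum(object$residuals^2)
  out <- list(fit = object, rss = rss,
              sigma = sqrt(rss / max(1, length(object$y) -
                                        length(object$coefficients))))
  class(out) <- "summary.sketch_lm"
  out
}

#' @export
print.summary.sketch_lm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Residual sum of squares: %.6g (sigma %.6g)\n", x$rss, x$sigma))
  invisible(x)
}

#' @export
coef.sketch_lm <- function(object, ...) object$coefficients

#' @export
predict.sketch_lm <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  drop(as.matrix(newdata) %*% object$coefficients)
}

#' @export
residuals.sketch_lm <- function(object, ...) object$residuals

#' @export
fitted.sketch_lm <- function(object, ...) object$fitted.values
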