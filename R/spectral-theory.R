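# Closed-form Tracy-Widom approximations for the operating characteristics
# of Gaussian-type sketches.  For a Gaussian sketch of size k applied to an
# n x d dataset with orthonormal basis U, the sketched Gram matrix
# W = U' S' S U is Wishart(k, I_d / k); the embedding and convergence
# probabilities are events on the extreme eigenvalues of W, and the
# centered/scaled extreme eigenvalues converge to the Tracy-Widom law.

#' Centering and scaling constants for the largest Wishart eigenvalue
#'
#' Constants \eqn{\mu_{k,d}} and \eqn{\sigma_{k,d}} such that
#' \eqn{(\lambda_{max}(W) - \mu_{k,d})/\sigma_{k,d}} is asymptotically
#' Tracy-Widom \eqn{F_1} for \eqn{W \sim Wishart(k, I_d/k)}:
#' \deqn{\mu_{k,d} = k^{-1}(\sqrt{k - 1/2} + \sqrt{d - 1/2})^2}
#' \deqn{\sigma_{k,d} = k^{-1}(\sqrt{k-1/2} + \sqrt{d-1/2})
#'   \,(1/\sqrt{k-1/2} + 1/\sqrt{d-1/2})^{1/3}}
#' These are the second-order-accurate constants (error
#' \eqn{O(d^{-2/3})} for even d); note the cube-root factor multiplies,
#' mirroring the lower-edge constants of [convergence_constants()] —
#' only the product has the \eqn{\sqrt{k}\,d^{-1/6}}-type scale of the
#' Tracy-Widom fluctuation and reproduces the Wishart Monte-Carlo
#' (see the methods vignette).
#'
#' @param k sketch size, \code{k >= d}.
#' @param d number of columns (variables), \code{d >= 1}.
#' @return A list with components \code{mu} and \code{sigma}.
#' @examples
#' embedding_constants(400, 20)   # mu ~ 1.4888, sigma ~ 0.0397
#' @export
embedding_constants <- function(k, d) {
  check_kd(k, d, strict = FALSE)
  a <- sqrt(k - 0.5)
  b <- sqrt(d - 0.5)
  list(mu = (a + b)^2 / k,
       sigma = ((a + b) / k) * (1 / a + 1 / b)^(1 / 3))
}

#' Centering and scaling constants for the smallest Wishart eigenvalue
#'
#' Constants controlling the lower spectral edge of
#' \eqn{W \sim Wishart(k, I_d/k)}, used by [convergence_prob_tw()]:
#' \eqn{\mu_{k,d} = (\sqrt{k-1/2} - \sqrt{d-1/2})^2},
#' \eqn{\sigma_{k,d} = (\sqrt{k-1/2} - \sqrt{d-1/2})\,|1/\sqrt{k-1/2} -
#' 1/\sqrt{d-1/2}|^{1/3}}, \eqn{\tau_{k,d} = \sigma_{k,d}/\mu_{k,d}} and
#' \eqn{\nu_{k,d} = \log(\mu_{k,d}) - \log k - \tau_{k,d}^2/8} (natural
#' logarithms).
#'
#' The cube-root factor is taken in absolute value so that \eqn{\tau > 0};
#' with this (the original lower-edge ordering of the reciprocal square
#' roots) the approximated convergence probability increases to 1 as
#' \eqn{k/d} grows, matching both the Wishart Monte-Carlo and the
#' behaviour of the iteration.  See the methods vignette for why the
#' printed sign of this factor is a known ambiguity.
#'
#' @param k sketch size, strictly greater than \code{d} (the smallest
#'   eigenvalue is degenerate at \code{k = d}).
#' @param d number of variables.
#' @return A list with components \code{mu}, \code{sigma}, \code{tau},
#'   \code{nu}.
#' @examples
#' convergence_constants(400, 20)  # mu ~ 242.47, tau ~ 0.0360, nu ~ -0.5008
#' @export
convergence_constants <- function(k, d) {
  check_kd(k, d, strict = TRUE)
  a <- sqrt(k - 0.5)
  b <- sqrt(d - 0.5)
  mu <- (a - b)^2
  sigma <- (a - b) * abs(1 / a - 1 / b)^(1 / 3)
  tau <- sigma / mu
  list(mu = mu, sigma = sigma, tau = tau,
       nu = log(mu) - log(k) - tau^2 / 8)
}

#' Tracy-Widom approximation to the subspace-embedding probability
#'
#' Approximates \eqn{\Pr(S\ \mathrm{is\ an}\ \epsilon\mathrm{-subspace\
#' embedding\ for}\ A)} for a Gaussian sketch of size \code{k} on a
#' rank-\code{d} dataset by \eqn{F_1((\epsilon + 1 - \mu_{k,d}) /
#' \sigma_{k,d})}.  For the Hadamard and Clarkson-Woodruff sketches the
#' same value is the large-\eqn{n} limit under a vanishing
#' max-leverage condition.
#'
#' @param epsilon distortion tolerance, positive (vectorized).
#' @param k sketch size, \code{k >= d}.
#' @param d number of variables.
#' @return Probabilities in \eqn{[0, 1]}, non-decreasing in
#'   \code{epsilon}.
#' @examples
#' embedding_prob_tw(0.6, k = 400, d = 20)   # ~ 0.965
#' @export
embedding_prob_tw <- function(epsilon, k, d) {
  check_kd(k, d, strict = FALSE)
  if (!is.numeric(epsilon) || any(!is.finite(epsilon)) || any(epsilon <= 0)) {
    stop("'epsilon' must be positive and finite", call. = FALSE)
  }
  cc <- embedding_constants(k, d)
  ptw1((epsilon + 1 - cc$mu) / cc$sigma)
}

#' Distortion achievable at a target confidence
#'
#' Inverse of [embedding_prob_tw()] in \code{epsilon}: the distortion
#' \eqn{\epsilon} such that the Tracy-Widom approximation to the embedding
#' probability equals \code{p}.
#'
#' @param p target probability in \eqn{(0, 1)} (vectorized).
#' @inheritParams embedding_prob_tw
#' @return Distortion values \eqn{\epsilon > 0} (may exceed 1 when the
#'   sketch is small).
#' @examples
#' embedding_quantile_tw(0.5, k = 2000, d = 100)
#' @export
embedding_quantile_tw <- function(p, k, d) {
  check_kd(k, d, strict = FALSE)
  cc <- embedding_constants(k, d)
  qtw1(p) * cc$sigma + cc$mu - 1
}

#' Tracy-Widom approximation to the preconditioned-iteration convergence
#' probability
#'
#' The sketch-preconditioned least-squares iteration converges if and only
#' if \eqn{\lambda_{max}((\tilde X'\tilde X)^{-1} X'X) < 2}, i.e.
#' \eqn{\lambda_{min}(W) > 1/2} for the Gaussian sketch with
#' \eqn{W \sim Wishart(k, I_d/k)}.  This function approximates that
#' probability by \eqn{F_1((\nu_{k,d} - \log(1/2)) / \tau_{k,d})} using
#' [convergence_constants()].
#'
#' @param k sketch size, strictly greater than \code{d}.
#' @param d number of variables.
#' @return A probability in \eqn{[0, 1]}, increasing in \code{k} at fixed
#'   \code{d} with limit 1.
#' @examples
#' convergence_prob_tw(400, 20)   # > 0.999
#' @export
convergence_prob_tw <- function(k, d) {
  cc <- convergence_constants(k, d)
  ptw1((cc$nu - log(0.5)) / cc$tau)
}

#' Limiting spectral edges of the sketched Gram matrix
#'
#' In the proportional regime \eqn{d/n \to \gamma}, \eqn{k/n \to \xi},
#' \eqn{d/k \to \alpha}, the extreme eigenvalues of \eqn{U'S'SU} under the
#' Hadamard sketch (subsampling without replacement) converge to
#' \deqn{\lambda_{min} \to (\sqrt{1-\gamma} - \sqrt{(1-\xi)\alpha})^2,\quad
#'       \lambda_{max} \to (\sqrt{1-\gamma} + \sqrt{(1-\xi)\alpha})^2,}
#' and the distortion concentrates at \eqn{\sigma^* = \max(|1 -
#' \lambda_{min}|, |1 - \lambda_{max}|)}.  The resulting approximation to
#' the embedding probability is the step function returned by
#' [esd_embedding_prob()].
#'
#' @param gamma limit of \eqn{d/n}, in \eqn{(0, 1)}.
#' @param xi limit of \eqn{k/n}, in \eqn{(\gamma, 1)}.
#' @param alpha limit of \eqn{d/k}, in \eqn{(0, 1]}.
#' @return An object of class \code{"esd_limits"}: a list with
#'   \code{gamma}, \code{xi}, \code{alpha}, \code{lambda_min},
#'   \code{lambda_max}, \code{sigma_star}.
#' @examples
#' esd_limits(0.01, 0.2, 0.05)$sigma_star    # ~ 0.4280
#' @export
esd_limits <- function(gamma, xi, alpha) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0, gamma < 1,
            is.numeric(xi), length(xi) == 1L, xi > gamma, xi < 1,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  root <- sqrt((1 - xi) * alpha)
  lo <- (sqrt(1 - gamma) - root)^2
  hi <- (sqrt(1 - gamma) + root)^2
  structure(list(gamma = gamma, xi = xi, alpha = alpha,
                 lambda_min = lo, lambda_max = hi,
                 sigma_star = max(abs(1 - lo), abs(1 - hi))),
            class = "esd_limits")
}

#' @export
print.esd_limits <- function(x, ...) {
  cat("Limiting spectral edges (gamma =", x$gamma, ", xi =", x$xi,
      ", alpha =", x$alpha, ")\n")
  cat(sprintf("  lambda_min -> %.6f, lambda_max -> %.6f, sigma* = %.6f\n",
              x$lambda_min, x$lambda_max, x$sigma_star))
  invisible(x)
}

#' Step approximation to the embedding probability from the limiting
#' spectral distribution
#'
#' In the proportional regime the distortion is deterministic in the
#' limit, so the embedding probability degenerates to a step: 1 if
#' \eqn{\epsilon \ge \sigma^*}, else 0.
#'
#' @param epsilon distortion tolerance(s), positive.
#' @param limits an \code{"esd_limits"} object from [esd_limits()].
#' @return 0/1 vector.
#' @examples
#' lim <- esd_limits(0.01, 0.2, 0.05)
#' esd_embedding_prob(c(0.3, 0.5), lim)
#' @export
esd_embedding_prob <- function(epsilon, limits) {
  stopifnot(inherits(limits, "esd_limits"))
  if (!is.numeric(epsilon) || any(!is.finite(epsilon)) || any(epsilon <= 0)) {
    stop("'epsilon' must be positive and finite", call. = FALSE)
  }
  as.numeric(epsilon >= limits$sigma_star)
}

#' Sub-Gaussian deviation bound for the uniform sketch
#'
#' For an orthonormal \eqn{n \times d} basis \eqn{U} with all leverage
#' scores bounded by \code{r}, a uniform sketch of size \code{k} satisfies
#' with probability at least \eqn{1 - 2d\,e^{-c t^2}}
#' \deqn{1 - t\sqrt{rn/k} \le \sigma_{min}(SU) \le \sigma_{max}(SU)
#'       \le 1 + t\sqrt{rn/k}.}
#' The absolute constant \eqn{c} is not pinned down by the theory; it is
#' exposed as a parameter (default 1) and the bound should be read as
#' qualitative guidance rather than a sharp probability.
#'
#' @param r upper bound on the leverage scores; must be at least the
#'   average leverage \code{d/n}.
#' @param n,k,d problem dimensions.
#' @param t deviation parameter, \code{t >= 0}.
#' @param c absolute constant in the exponent, positive; default 1.
#' @return A list with \code{interval} (the singular-value interval) and
#'   \code{prob_lower} (the lower bound on the success probability,
#'   clamped at 0).
#' @examples
#' vershynin_bound(r = 20/1000, n = 1000, k = 100, d = 10, t = 2)
#' @export
vershynin_bound <- function(r, n, k, d, t, c = 1) {
  stopifnot(is.numeric(r), length(r) == 1L, is.numeric(t), t >= 0, c > 0,
            k >= 1, n >= d, d >= 1)
  if (r < d / n || r > 1) {
    stop("'r' must lie in [d/n, 1]: leverage scores average d/n and are at most 1",
         call. = FALSE)
  }
  half <- t * sqrt(r * n / k)
  list(interval = c(1 - half, 1 + half),
       prob_lower = max(0, 1 - 2 * d * exp(-c * t^2)))
}

check_kd <- function(k, d, strict) {
  if (!is.numeric(k) || !is.numeric(d) || length(k) != 1L || length(d) != 1L ||
      !is.finite(k) || !is.finite(d) || d < 1 || k < 1) {
    stop("'k' and 'd' must be positive finite scalars", call. = FALSE)
  }
  if (strict && k <= d) {
    stop("'k' must be strictly greater than 'd' (smallest eigenvalue degenerates at k = d)",
         call. = FALSE)
  }
  if (!strict && k < d) {
    stop("'k' must be at least 'd'", call. = FALSE)
  }
  invisible(NULL)
}
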