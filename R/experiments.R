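# Experiment drivers: empirical vs theoretical embedding and convergence
# probability curves, reproducible from (configuration, seed).

#' Embedding-probability experiment
#'
#' Estimates the empirical probability of obtaining an
#' \eqn{\epsilon}-subspace embedding over a grid of \eqn{\epsilon}
#' values and compares it with the Tracy-Widom approximation
#' ([embedding_prob_tw()]) and, when a proportional-regime configuration
#' is available (\code{n} supplied), with the limiting-spectral-
#' distribution step at \eqn{\sigma^*} ([esd_limits()]).
#'
#' For the Gaussian family with no data matrix the Wishart shortcut is
#' used (no \eqn{n}-dimensional object is ever formed).  Otherwise the
#' sketch is applied to \code{A}, or to a simulated AR(1) design of size
#' \code{n x d} when \code{A} is missing.
#'
#' @param d number of variables.
#' @param k sketch size.
#' @param family sketch family (see [sketch_spec()]).
#' @param B number of sketch draws; default 1000.
#' @param n number of rows for simulated data (ignored when \code{A} is
#'   given; optional for the Gaussian family).
#' @param A optional user data matrix (overrides \code{n}).
#' @param epsilon_grid grid of tolerances; default 200 equally spaced
#'   points spanning the 0.001-0.999 Tracy-Widom quantile range for
#'   \code{(k, d)}.
#' @param rho AR(1) correlation for simulated data; default 0.5.
#' @param row_sampling Hadamard row sampling (see [sketch_spec()]).
#' @param seed optional integer seed covering data generation and all
#'   sketch draws.
#' @return An object of class \code{"sketch_experiment"} (type
#'   \code{"embedding"}): configuration, \code{epsilon} grid,
#'   \code{empirical} and \code{theoretical} curves, the distortion
#'   \code{sample}, \code{sup_distance} between the curves, and, when
#'   \code{n} is known, the \code{esd} limits and step curve.
#' @examples
#' ex <- experiment_embedding(d = 10, k = 200, B = 200, seed = 1)
#' ex$sup_distance
#' @export
experiment_embedding <- function(d, k, family = "gaussian", B = 1000,
                                 n = NULL, A = NULL, epsilon_grid = NULL,
                                 rho = 0.5,
                                 row_sampling = "with_replacement",
                                 seed = NULL) {
  spec <- sketch_spec(family, k = k, row_sampling = row_sampling)
  if (is.null(epsilon_grid)) {
    lim <- embedding_quantile_tw(c(0.001, 0.999), k, d)
    epsilon_grid <- seq(max(lim[1], 1e-6), lim[2], length.out = 200L)
  }
  sample <- with_seed(seed, {
    if (is.null(A) && spec$family == "gaussian") {
      simulate_gaussian_distortions(k, d, B)
    } else {
      if (is.null(A)) {
        if (is.null(n)) {
          stop("supply 'n' or 'A' for non-Gaussian families", call. = FALSE)
        }
        A <- sim_ar1_design(n, d, rho = rho)
      }
      sketch_distortions(A, spec, B)
    }
  })
  if (!is.null(A)) n <- nrow(A)
  empirical <- empirical_embedding_prob(sample, epsilon_grid)
  theoretical <- embedding_prob_tw(epsilon_grid, k, d)
  out <- list(type = "embedding",
              config = list(n = n, d = d, k = k, family = spec$family,
                            row_sampling = spec$row_sampling, B = B,
                            rho = rho, seed = seed),
              epsilon = epsilon_grid, empirical = empirical,
              theoretical = theoretical, sample = sample,
              sup_distance = max(abs(empirical - theoretical)))
  if (!is.null(n)) {
    out$esd <- esd_limits(d / n, k / n, d / k)
    out$esd_curve <- esd_embedding_prob(epsilon_grid, out$esd)
  }
  structure(out, class = "sketch_experiment")
}

#' Convergence-probability experiment
#'
#' For each sketch size in \code{k_grid}, runs the preconditioned
#' iteration \code{R} times on one simulated regression problem and
#' compares the empirical convergence frequency (with binomial standard
#' errors) to the Tracy-Widom approximation
#' ([convergence_prob_tw()]).
#'
#' @param n,d dimensions of the simulated regression problem.
#' @param k_grid vector of sketch sizes (each \code{> d}).
#' @param family sketch family.
#' @param R replicates per sketch size; default 100.
#' @param A,y optional user design matrix and response (override
#'   simulation).
#' @param rho,noise_sd simulation parameters (see [sim_regression()]).
#' @param tol,max_iter iteration controls (see [sketch_lm()]).
#' @param seed optional integer seed.
#' @return An object of class \code{"sketch_experiment"} (type
#'   \code{"convergence"}): configuration, \code{k} grid,
#'   \code{empirical} frequencies, \code{se}, and \code{theoretical}
#'   values.
#' @examples
#' ex <- experiment_convergence(500, 5, k_grid = c(15, 60), R = 20, seed = 1)
#' cbind(ex$k, ex$empirical, ex$theoretical)
#' @export
experiment_convergence <- function(n, d, k_grid, family = "gaussian",
                                   R = 100, A = NULL, y = NULL, rho = 0.5,
                                   noise_sd = 1, tol = 1e-6,
                                   max_iter = 2000, seed = NULL) {
  stopifnot(all(k_grid > d))
  res <- with_seed(seed, {
    if (is.null(A)) {
      sim <- sim_regression(n, d, noise_sd = noise_sd, rho = rho)
      A <- sim$X
      y <- sim$y
    }
    lapply(k_grid, function(k) {
      empirical_convergence_prob(A, y, sketch_spec(family, k = k), R = R,
                                 tol = tol, max_iter = max_iter)
    })
  })
  structure(list(
    type = "convergence",
    config = list(n = n, d = d, family = family, R = R, rho = rho,
                  noise_sd = noise_sd, tol = tol, max_iter = max_iter,
                  seed = seed),
    k = as.numeric(k_grid),
    empirical = vapply(res, `[[`, numeric(1), "estimate"),
    se = vapply(res, `[[`, numeric(1), "se"),
    theoretical = vapply(k_grid, convergence_prob_tw, numeric(1), d = d)
  ), class = "sketch_experiment")
}

#' @export
print.sketch_experiment <- function(x, ...) {
  cfg <- x$config
  if (x$type == "embedding") {
    cat(sprintf("Embedding experiment: family = %s, d = %d, k = %d, B = %d%s\n",
                cfg$family, cfg$d, cfg$k, cfg$B,
                if (is.null(cfg$n)) "" else sprintf(", n = %d", cfg$n)))
    cat(sprintf("  sup |empirical - Tracy-Widom| = %.4f\n", x$sup_distance))
    if (!is.null(x$esd)) {
      cat(sprintf("  limiting-spectral step at sigma* = %.4f\n",
                  x$esd$sigma_star))
    }
  } else {
    cat(sprintf("Convergence experiment: family = %s, n = %d, d = %d, R = %d\n",
                cfg$family, cfg$n, cfg$d, cfg$R))
    print(data.frame(k = x$k, empirical = x$empirical, se = x$se,
                     theoretical = x$theoretical))
  }
  invisible(x)
}

#' @export
plot.sketch_experiment <- function(x, ...) {
  if (x$type == "embedding") {
    graphics::plot(x$epsilon, x$empirical, type = "s", ylim = c(0, 1),
                   xlab = expression(epsilon),
                   ylab = "embedding probability", ...)
    graphics::lines(x$epsilon, x$theoretical, lty = 2)
    leg <- c("empirical", "Tracy-Widom")
    lty <- c(1, 2)
    if (!is.null(x$esd_curve)) {
      graphics::lines(x$epsilon, x$esd_curve, lty = 3)
      leg <- c(leg, "spectral-limit step")
      lty <- c(lty, 3)
    }
    graphics::legend("bottomright", legend = leg, lty = lty, bty = "n")
  } else {
    graphics::plot(x$k, x$empirical, ylim = c(0, 1), pch = 19,
                   xlab = "sketch size k",
                   ylab = "convergence probability", ...)
    has_se <- x$se > 0
    if (any(has_se)) {
      graphics::arrows(x$k[has_se],
                       pmax(0, x$empirical - 2 * x$se)[has_se],
                       x$k[has_se],
                       pmin(1, x$empirical + 2 * x$se)[has_se],
                       angle = 90, code = 3, length = 0.03)
    }
    kk <- seq(min(x$k), max(x$k), length.out = 200)
    graphics::lines(kk, vapply(kk, convergence_prob_tw, numeric(1),
                               d = x$config$d), lty = 2)
    graphics::legend("bottomright",
                     legend = c("empirical (±2 SE)", "Tracy-Widom"),
                     pch = c(19, NA), lty = c(NA, 2), bty = "n")
  }
  invisible(x)
}
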