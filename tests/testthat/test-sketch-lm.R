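test_that("exact preconditioner converges in one step", {
  sim <- sim_regression(300, 6, seed = 2)
  res <- hessian_sketch_iterate(sim$X, sim$y, precond = crossprod(sim$X),
                                tol = 1e-10)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_lt(res$final_gradient_norm, 1e-10)
  expect_equal(res$beta, qr.coef(qr(sim$X), sim$y), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("noiseless systems are interpolated exactly under a valid preconditioner", {
  sim <- sim_regression(400, 5, noise_sd = 0, seed = 3)
  res <- hessian_sketch_iterate(sim$X, sim$y,
                                sketch_spec("gaussian", k = 250, seed = 4))
  expect_true(res$converged)
  expect_equal(res$beta, sim$beta_star, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("spectral radius above one makes the iteration diverge", {
  # diagonal problem: X'X = I2, preconditioner diag(0.4, 1) has
  # lambda_max = 2.5 so the error component is amplified by |1 - 2.5|
  X <- diag(2)
  y <- c(1, -1)
  res <- hessian_sketch_iterate(X, y, precond = diag(c(0.4, 1)),
                                max_iter = 500)
  expect_false(res$converged)
  expect_gt(res$final_gradient_norm, res$gradient_path[1])
})

test_that("convergence condition computes the generalized eigenvalue", {
  set.seed(23)
  M <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  expect_equal(convergence_condition(M, M)$lambda_max, 1, tolerance = 1e-10)
  expect_true(convergence_condition(M, M)$will_converge)
  # halving the preconditioner exactly doubles lambda_max
  expect_equal(convergence_condition(M, M / 2)$lambda_max, 2,
               tolerance = 1e-10)
  # strictness of the inequality at an exactly representable boundary
  expect_false(convergence_condition(diag(c(2, 1)), diag(2))$will_converge)
  expect_true(convergence_condition(diag(c(1.99, 1)), diag(2))$will_converge)
  expect_error(convergence_condition(M, -M), "positive definite")
})

test_that("condition lambda_max < 2 exactly separates convergence from divergence", {
  # constructed diagonal preconditioners with lambda_max on a grid
  X <- diag(2)
  y <- c(0.3, -0.7)
  for (lam in c(1.5, 1.9, 1.99, 2.01, 2.5)) {
    res <- hessian_sketch_iterate(X, y, precond = diag(c(1 / lam, 1)),
                                  tol = 1e-9, max_iter = 5000)
    expect_equal(res$converged, lam < 2, info = paste("lambda", lam))
  }
})

test_that("condition verdict matches observed iteration behaviour on random problems", {
  set.seed(17)
  agree <- 0L
  for (i in 1:50) {
    sim <- sim_regression(120, 3, seed = 1000 + i)
    spec <- sketch_spec("gaussian", k = sample(4:12, 1), seed = 2000 + i)
    P <- crossprod(sketch_apply(sim$X, spec))
    verdict <- convergence_condition(crossprod(sim$X), P)$will_converge
    res <- hessian_sketch_iterate(sim$X, sim$y, precond = P,
                                  tol = 1e-8, max_iter = 4000)
    agree <- agree + as.integer(verdict == res$converged)
  }
  expect_equal(agree, 50L)
})

test_that("sketch-and-solve error bound holds on random instances", {
  ok <- logical(100)
  eps_ok <- logical(100)
  for (i in 1:100) {
    sim <- sim_regression(512, 5, seed = 3000 + i)
    rep <- sketch_ols_bound(sim$X, sim$y,
                            sketch_spec("gaussian", k = 50, seed = 4000 + i))
    ok[i] <- rep$bound_satisfied
    eps_ok[i] <- rep$epsilon_used > 0
  }
  expect_true(all(ok))
  expect_true(all(eps_ok))
})

test_that("noiseless sketch-and-solve recovers the exact solution", {
  sim <- sim_regression(256, 4, noise_sd = 0, seed = 6)
  rep <- sketch_ols_bound(sim$X, sim$y, sketch_spec("gaussian", 40, seed = 7))
  expect_equal(rep$rss_full, 0, tolerance = 1e-16)
  expect_equal(rep$beta_sketch, rep$beta_full, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(rep$bound_satisfied)
})

test_that("empirical convergence probability hits the extremes", {
  sim <- sim_regression(600, 20, seed = 8)
  hi <- empirical_convergence_prob(sim$X, sim$y,
                                   sketch_spec("gaussian", k = 1000),
                                   R = 50, seed = 9)
  expect_equal(hi$estimate, 1)
  lo <- empirical_convergence_prob(sim$X, sim$y,
                                   sketch_spec("gaussian", k = 21),
                                   R = 50, seed = 10)
  expect_equal(lo$estimate, 0)
  one <- empirical_convergence_prob(sim$X, sim$y,
                                    sketch_spec("gaussian", k = 1000),
                                    R = 1, seed = 11)
  expect_equal(one$se, 0)
})

test_that("epsilon-embedding with distortion below one half guarantees convergence", {
  # worst case: lambda_min(U'S'SU) = 1 - eps exactly (diagonal construction)
  X <- diag(3)
  for (eps in c(0.1, 0.3, 0.49, 0.51, 0.7)) {
    P <- diag(c(1 - eps, 1, 1 + eps))   # sketched Gram in the singular basis
    cc <- convergence_condition(crossprod(X), P)
    expect_equal(cc$will_converge, eps < 0.5, info = paste("eps", eps))
  }
})

test_that("sketch_lm returns a usable fitted-model object", {
  sim <- sim_regression(400, 4, seed = 12)
  fit <- sketch_lm(sim$X, sim$y, sketch_spec("gaussian", 200, seed = 13))
  expect_s3_class(fit, "sketch_lm")
  expect_true(fit$converged)
  expect_length(coef(fit), 4L)
  expect_equal(coef(fit), qr.coef(qr(sim$X), sim$y), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fitted(fit) + residuals(fit), sim$y, tolerance = 1e-12)
  expect_equal(predict(fit, sim$X[1:5, ]), fitted(fit)[1:5],
               tolerance = 1e-12)
  expect_output(print(fit), "Converged")
  expect_output(print(summary(fit)), "Residual sum of squares")

  fs <- sketch_lm(sim$X, sim$y, sketch_spec("gaussian", 100, seed = 14),
                  method = "solve")
  expect_true(fs$bound_satisfied)
  expect_output(print(fs), "distortion")
})
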