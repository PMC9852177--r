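test_that("distortion statistic matches its eigenvalue definition and SVD oracle", {
  # identity Gram: zero distortion
  expect_equal(distortion(diag(3), diag(3)), 0)
  # diagonal Gram diag(0.5, 1.6): distortion max(0.5, 0.6)
  expect_equal(distortion(diag(2), diag(sqrt(c(0.5, 1.6)))), 0.6,
               tolerance = 1e-12)
  # equals sigma_max(I - (SU)'(SU)) by full SVD on random instances
  set.seed(31)
  for (i in 1:20) {
    U <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
    SU <- matrix(rnorm(5 * 3, sd = 0.6), 5, 3)
    expect_equal(distortion(U, SU),
                 max(svd(diag(3) - crossprod(SU))$d), tolerance = 1e-10)
  }
  expect_error(distortion(matrix(rnorm(12), 4, 3), diag(3)),
               "not orthonormal")
})

test_that("orthonormal basis spans the column space with rank detection", {
  set.seed(5)
  A <- matrix(rnorm(250), 50, 5)
  ob <- orthonormal_basis(A)
  expect_equal(ob$rank, 5L)
  expect_lt(max(abs(crossprod(ob$U) - diag(5))), 1e-12)
  # projection of A onto U reproduces A
  expect_equal(ob$U %*% crossprod(ob$U, A), A, tolerance = 1e-10)
  # orthonormal input: basis spans the same space (projectors agree)
  Q <- qr.Q(qr(A))
  UQ <- orthonormal_basis(Q)$U
  expect_equal(tcrossprod(UQ), tcrossprod(Q), tolerance = 1e-10)
  # duplicated column: named rank-deficiency error
  a <- rnorm(20)
  expect_error(orthonormal_basis(cbind(a, 2 * a)), "rank deficient")
  expect_equal(orthonormal_basis(cbind(a, 2 * a),
                                 require_full_rank = FALSE)$rank, 1L)
})

test_that("Wishart-shortcut distortions behave like the sketched-basis oracle", {
  # mean lambda_max tracks the upper-edge centering constant
  k <- 500; d <- 25; B <- 800
  set.seed(8)
  lmax <- replicate(B, {
    G <- matrix(rnorm(k * d, sd = 1 / sqrt(k)), k, d)
    eigen(crossprod(G), symmetric = TRUE, only.values = TRUE)$values[1]
  })
  cc <- embedding_constants(k, d)
  expect_lt(abs(mean(lmax) - cc$mu), 4 * sd(lmax) / sqrt(B) + 2 * cc$sigma)
  # seed reproducibility at B = 1
  d1 <- simulate_gaussian_distortions(50, 5, 1, seed = 4)
  d2 <- simulate_gaussian_distortions(50, 5, 1, seed = 4)
  expect_identical(d1$draws, d2$draws)
  # k < d forces rank deficiency: every distortion at least 1
  dl <- simulate_gaussian_distortions(3, 6, 50, seed = 9)
  expect_true(all(dl$draws >= 1))
  expect_error(simulate_gaussian_distortions(50, 5, 0), "positive integer")
})

test_that("Gaussian distortion law is pivotal: independent of the dataset", {
  k <- 80; d <- 5; B <- 2000
  A1 <- sim_ar1_design(256, d, rho = 0, seed = 1)
  A2 <- 50 * sim_ar1_design(256, d, rho = 0.9, seed = 2)
  s1 <- sketch_distortions(A1, sketch_spec("gaussian", k), B, seed = 3)
  s2 <- sketch_distortions(A2, sketch_spec("gaussian", k), B, seed = 4)
  # 1% two-sample KS critical value: 1.63 sqrt(2/B)
  expect_lt(ks_two_sample(s1$draws, s2$draws), 1.63 * sqrt(2 / B))
  # and identical in law to the Wishart shortcut
  s3 <- simulate_gaussian_distortions(k, d, B, seed = 5)
  expect_lt(ks_two_sample(s1$draws, s3$draws), 1.63 * sqrt(2 / B))
})

test_that("uniform sketch degrades on a high-leverage matrix", {
  # one row carries essentially all the mass of its direction
  set.seed(12)
  A <- matrix(rnorm(64 * 3, sd = 0.05), 64, 3)
  A[1, ] <- c(30, 0, 0)
  lp <- leverage_scores(A)
  expect_gt(lp$max_score, 0.95)
  du <- sketch_distortions(A, sketch_spec("uniform", 32), B = 300, seed = 1)
  dg <- sketch_distortions(A, sketch_spec("gaussian", 32), B = 300, seed = 2)
  expect_gt(median(du$draws), median(dg$draws))
})

test_that("empirical embedding probability is the draw-counting step function", {
  ds <- sketchtw:::new_distortion_sample(c(0.1, 0.3), 10, 2, "gaussian", NULL)
  expect_equal(empirical_embedding_prob(ds, 0.2), 0.5)
  expect_equal(empirical_embedding_prob(ds, 0.05), 0)
  expect_equal(empirical_embedding_prob(ds, 0.5), 1)
  # right continuity: at a draw the draw counts
  expect_equal(empirical_embedding_prob(ds, 0.3), 1)
  expect_error(sketch_distortions(matrix(rnorm(20), 10, 2),
                                  sketch_spec("gaussian", 5), B = 0),
               "positive integer")
})

test_that("Monte-Carlo convergence probability is coherent with distortions", {
  # every draw with distortion below 1/2 implies lambda_min above 1/2,
  # so Pr(lambda_min > 1/2) >= Pr(distortion < 1/2)
  k <- 120; d <- 10; B <- 400
  p_lam <- mc_lambda_min_prob(k, d, B, seed = 21)
  ds <- simulate_gaussian_distortions(k, d, B, seed = 21)
  expect_gte(p_lam, empirical_embedding_prob(ds, 0.499))
})
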