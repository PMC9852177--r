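test_that("upper-edge constants match direct arithmetic and their limits", {
  cc <- embedding_constants(400, 20)
  a <- sqrt(399.5)
  b <- sqrt(19.5)
  expect_equal(cc$mu, (a + b)^2 / 400, tolerance = 1e-12)
  expect_equal(cc$mu, 1.48881, tolerance = 1e-5)
  expect_equal(cc$sigma, ((a + b) / 400) * (1 / a + 1 / b)^(1 / 3),
               tolerance = 1e-12)
  # symmetric case k = d
  cs <- embedding_constants(50, 50)
  expect_equal(cs$mu, 4 * 49.5 / 50, tolerance = 1e-12)
  # k -> infinity at fixed d: mu -> 1, sigma -> 0
  cb <- embedding_constants(1e8, 20)
  expect_equal(cb$mu, 1, tolerance = 1e-3)
  expect_lt(cb$sigma, 1e-3)
  expect_error(embedding_constants(10, 20), "at least")
})

test_that("lower-edge constants match direct arithmetic and their limits", {
  cc <- convergence_constants(400, 20)
  expect_equal(cc$mu, 242.475, tolerance = 1e-5)
  expect_equal(cc$tau, 0.036018, tolerance = 1e-4)
  expect_equal(cc$nu, -0.50073, tolerance = 1e-4)
  expect_gt(cc$tau, 0)
  # mu < k always (so nu's log ratio is negative before the tau correction)
  expect_lt(cc$mu, 400)
  # k -> infinity: lambda_min concentrates at 1, nu and tau vanish
  cb <- convergence_constants(1e8, 20)
  expect_lt(abs(cb$nu), 1e-3)
  expect_lt(cb$tau, 1e-3)
  expect_error(convergence_constants(20, 20), "strictly greater")
})

test_that("embedding probability is a proper monotone cdf-type surface", {
  # monotone in epsilon
  eps <- seq(0.05, 2, length.out = 50)
  p <- embedding_prob_tw(eps, 400, 20)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  # -> 1 as epsilon grows
  expect_gt(embedding_prob_tw(50, 400, 20), 1 - 1e-6)
  # at epsilon = mu - 1 the argument is zero: F1(0) ~ 0.83
  cc <- embedding_constants(400, 20)
  expect_equal(embedding_prob_tw(cc$mu - 1, 400, 20), 0.8319,
               tolerance = 1e-3)
  # monotone in k at fixed d for epsilon above the typical distortion
  # (saturates at 1 once the sketch is comfortably large)
  ks <- c(500, 1000, 2000, 4000)
  pk <- vapply(ks, function(k) embedding_prob_tw(0.45, k, 20), numeric(1))
  expect_true(all(diff(pk) >= 0))
  expect_gt(pk[2], pk[1])
  expect_error(embedding_prob_tw(-0.1, 400, 20), "positive")
})

test_that("embedding quantile inverts the embedding probability", {
  for (p in c(0.1, 0.5, 0.9)) {
    e <- embedding_quantile_tw(p, 400, 20)
    expect_equal(embedding_prob_tw(e, 400, 20), p, tolerance = 1e-6)
  }
  # larger sketches achieve smaller distortion at the same confidence
  expect_lt(embedding_quantile_tw(0.5, 800, 20),
            embedding_quantile_tw(0.5, 400, 20))
  # at fixed aspect ratio d/k the median distortion approaches the
  # deterministic edge (1 + sqrt(d/k))^2 - 1 from below as d grows,
  # because the Tracy-Widom fluctuation term shrinks
  edge <- (1 + sqrt(1 / 20))^2 - 1
  q20 <- embedding_quantile_tw(0.5, 400, 20)
  q100 <- embedding_quantile_tw(0.5, 2000, 100)
  expect_true(q20 < q100 && q100 < edge)
})

test_that("convergence probability increases in k with unit limit", {
  d <- 20
  ks <- c(150, 200, 300, 500, 1000)
  p <- vapply(ks, convergence_prob_tw, numeric(1), d = d)
  expect_true(all(diff(p) > 0))
  expect_gt(convergence_prob_tw(10000, d), 1 - 1e-9)
  expect_gt(convergence_prob_tw(400, 20), 0.999)
  expect_error(convergence_prob_tw(20, 20), "strictly greater")
})

test_that("limiting spectral edges match the closed form", {
  lim <- esd_limits(0.01, 0.2, 0.05)
  expect_equal(lim$lambda_min, (sqrt(0.99) - 0.2)^2, tolerance = 1e-12)
  expect_equal(lim$lambda_max, (sqrt(0.99) + 0.2)^2, tolerance = 1e-12)
  expect_equal(lim$sigma_star, 0.427995, tolerance = 1e-6)
  # xi -> 1: both edges collapse to 1 - gamma
  lim1 <- esd_limits(0.1, 1 - 1e-12, 0.05)
  expect_equal(lim1$lambda_min, 0.9, tolerance = 1e-5)
  expect_equal(lim1$lambda_max, 0.9, tolerance = 1e-5)
  expect_equal(lim1$sigma_star, 0.1, tolerance = 1e-5)
  # alpha -> 0 likewise
  lim0 <- esd_limits(0.1, 0.5, 1e-14)
  expect_equal(lim0$lambda_min, 0.9, tolerance = 1e-6)
  expect_error(esd_limits(0.3, 0.2, 0.5))
})

test_that("spectral-limit embedding probability is the step at sigma*", {
  lim <- esd_limits(0.01, 0.2, 0.05)
  s <- lim$sigma_star
  expect_equal(esd_embedding_prob(c(s / 2, s, 2 * s), lim), c(0, 1, 1))
})

test_that("uniform-sketch deviation bound behaves as stated", {
  b0 <- vershynin_bound(r = 0.05, n = 1000, k = 100, d = 10, t = 0)
  expect_equal(b0$interval, c(1, 1))
  expect_equal(b0$prob_lower, 0)    # 1 - 2d clamps to zero
  b1 <- vershynin_bound(r = 0.05, n = 1000, k = 100, d = 10, t = 2)
  b2 <- vershynin_bound(r = 0.10, n = 1000, k = 100, d = 10, t = 2)
  expect_equal(diff(b2$interval) / diff(b1$interval), sqrt(2),
               tolerance = 1e-12)
  # flattest possible leverage: width t sqrt(d/k)
  bf <- vershynin_bound(r = 10 / 1000, n = 1000, k = 100, d = 10, t = 1)
  expect_equal(diff(bf$interval), 2 * sqrt(10 / 100), tolerance = 1e-12)
  expect_error(vershynin_bound(r = 0.001, n = 1000, k = 100, d = 10, t = 1),
               "d/n")
})
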