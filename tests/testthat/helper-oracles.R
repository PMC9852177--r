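# Independent numerical oracles used across the test files.

# Kolmogorov-Smirnov distance between an empirical sample and the
# Tracy-Widom approximation to the distortion cdf at (k, d).
ks_to_tw <- function(draws, k, d) {
  eg <- sort(draws)
  B <- length(eg)
  emp <- seq_len(B) / B
  th <- embedding_prob_tw(eg, k, d)
  max(pmax(abs(emp - th), abs(emp - 1 / B - th)))
}

# Two-sample Kolmogorov-Smirnov statistic (no ties assumed).
ks_two_sample <- function(x, y) {
  unname(suppressWarnings(stats::ks.test(x, y)$statistic))
}

# --- Airy function by its large-argument asymptotic series (x >= 6) -------
# Ai(x) ~ e^{-z}/(2 sqrt(pi) x^{1/4}) * sum (-1)^j u_j z^-j,  z = (2/3)x^{3/2}
# Ai'(x) ~ -x^{1/4} e^{-z}/(2 sqrt(pi)) * sum (-1)^j v_j z^-j,
# u_0 = v_0 = 1, u_{j+1} = u_j (3j+2.5)(3j+1.5)(3j+0.5)/(54 (j+1)(j+0.5)),
# v_j = (6j+1)/(1-6j) u_j.  At x >= 6 eight terms give ~1e-9 relative error.
airy_asym <- function(x, nterm = 9L) {
  z <- (2 / 3) * x^1.5
  u <- 1
  su <- 1
  sv <- 1
  for (j in 0:(nterm - 1L)) {
    u_next <- u * (3 * j + 2.5) * (3 * j + 1.5) * (3 * j + 0.5) /
      (54 * (j + 1) * (j + 0.5))
    su <- su + (-1)^(j + 1) * u_next / z^(j + 1)
    v_next <- (6 * (j + 1) + 1) / (1 - 6 * (j + 1)) * u_next
    sv <- sv + (-1)^(j + 1) * v_next / z^(j + 1)
    u <- u_next
  }
  pre <- exp(-z) / (2 * sqrt(pi))
  list(ai = pre * su / x^0.25, aip = -pre * sv * x^0.25)
}

# --- Tracy-Widom F1 oracle: Painleve II via deSolve --------------------
# Independent of the shipped grid: Hastings-McLeod solution q of
# q'' = s q + 2 q^3 started from asymptotic Airy values at s0 = 7,
# integrated down with lsoda alongside I = int q, K = int q^2,
# J = int (x - s) q^2; then F1(s) = exp(-I/2 - J/2).
tw1_oracle_cdf <- function(s_eval) {
  s0 <- 7
  a0 <- airy_asym(s0)
  I0 <- stats::integrate(function(x) airy_asym(x)$ai, s0, Inf,
                         rel.tol = 1e-12)$value
  K0 <- stats::integrate(function(x) airy_asym(x)$ai^2, s0, Inf,
                         rel.tol = 1e-12)$value
  J0 <- stats::integrate(function(x) (x - s0) * airy_asym(x)$ai^2, s0, Inf,
                         rel.tol = 1e-12)$value
  rhs <- function(t, y, parms) {
    list(c(y[2], t * y[1] + 2 * y[1]^3, -y[1], -y[1]^2, -y[4]))
  }
  times <- c(s0, sort(s_eval, decreasing = TRUE))
  sol <- deSolve::lsoda(c(q = a0$ai, p = a0$aip, I = I0, K = K0, J = J0),
                        times, rhs, rtol = 1e-11, atol = 1e-13)
  f1 <- exp(-sol[-1, "I"] / 2 - sol[-1, "J"] / 2)
  f1[match(s_eval, times[-1])]
}
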