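---
title: "Sketching diagnostics via the Tracy-Widom law: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketching diagnostics via the Tracy-Widom law: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sketchtw)
```

## The model

A data-oblivious sketch compresses an $n \times d$ matrix $A$ to
$\tilde A = SA$ with a random $k \times n$ matrix $S$ whose law does not
depend on $A$. Four families are implemented:

* **Gaussian**: i.i.d. $N(0, 1/k)$ entries;
* **Hadamard (SRHT)**: $S = \Phi H D/\sqrt k$ with a Rademacher diagonal
  $D$, a Sylvester Hadamard matrix $H$ of order $n' = 2^{\lceil \log_2 n
  \rceil}$ acting on zero-padded data, and $\Phi$ sampling $k$ rows of $H$
  (with replacement by default; a without-replacement variant is provided);
* **Clarkson–Woodruff (CountSketch)**: one $\pm 1$ per column of $S$, at a
  uniformly chosen row — applied in $O(nd)$ by bucket accumulation;
* **uniform**: $\sqrt{n/k}$-rescaled row subsampling with replacement.

Sketch quality is summarized by the distortion
$\varepsilon = \sigma_{\max}(I - U^\top S^\top S U)$, where $U$ is the
left-singular basis of $A$: the sketch is an $\varepsilon'$-subspace
embedding exactly for $\varepsilon' \ge \varepsilon$. For the Gaussian
family $W = U^\top S^\top S U \sim \mathrm{Wishart}(k, I_d/k)$ independent
of $A$ and $n$ (pivotality), so both diagnostics of interest are Wishart
edge-eigenvalue probabilities:

* embedding probability
  $\psi = \Pr(|1 - \lambda_{\min}(W)| \le \varepsilon,\;
              |1 - \lambda_{\max}(W)| \le \varepsilon)$,
* convergence probability of the preconditioned least-squares iteration
  $\beta^{(t+1)} = \beta^{(t)} + (\tilde X^\top \tilde X)^{-1}
  X^\top(y - X\beta^{(t)})$, which converges for every start iff
  $\lambda_{\max}((\tilde X^\top \tilde X)^{-1} X^\top X) < 2$, i.e.
  $\gamma = \Pr(\lambda_{\min}(W) > 1/2)$.

In the compression regime $n \gg k$, $d/k \to \alpha \in (0,1]$, the
centered and scaled edges are Tracy–Widom $F_1$, giving the closed forms in
`embedding_prob_tw()` and `convergence_prob_tw()`. The same limits apply to
the Hadamard and CountSketch families as $n \to \infty$ with $k, d$ fixed,
provided the maximum leverage score $\max_i \|u_i\|_2^2 \to 0$ — the
negligibility condition under which no single observation matters. The
uniform sketch satisfies no such universality; only a sub-Gaussian
deviation bound with an unpinned absolute constant is available
(`vershynin_bound()`, constant exposed as a parameter defaulting to 1, to
be read qualitatively).

### The scaling constants, and two typographic traps

For the upper edge we use
$$\mu_{k,d} = k^{-1}(\sqrt{k - 1/2} + \sqrt{d - 1/2})^2, \qquad
  \sigma_{k,d} = k^{-1}(\sqrt{k - 1/2} + \sqrt{d - 1/2})
  \left(\tfrac{1}{\sqrt{k-1/2}} + \tfrac{1}{\sqrt{d-1/2}}\right)^{1/3},$$
the second-order-accurate constants with error $O(d^{-2/3})$ for even $d$.
Two conventions deserve an explicit note because printed sources differ:

1. **The cube-root factor multiplies.** Only the product form has the
   $\sqrt k\, d^{-1/6}$ scale of the edge fluctuation, mirrors the
   lower-edge constants, and reproduces the Wishart Monte-Carlo: at
   $k = 400, d = 20$ the simulated median of $\lambda_{\max}$ is
   $\approx 1.44$, matching $\mu + \sigma\,q_{F_1}(0.5)$ with
   $\sigma \approx 0.0397$ (product), not $\sigma \approx 0.0936$
   (quotient). A quotient version appears in print; it fails this
   Monte-Carlo check by almost a full fluctuation scale.
2. **The lower-edge cube-root factor is taken in absolute value.** With
   $\mu^-_{k,d} = (\sqrt{k-1/2} - \sqrt{d-1/2})^2$,
   $\sigma^-_{k,d} = (\sqrt{k-1/2} - \sqrt{d-1/2})\,
   |1/\sqrt{k-1/2} - 1/\sqrt{d-1/2}|^{1/3}$,
   $\tau = \sigma^-/\mu^-$ and $\nu = \log \mu^- - \log k - \tau^2/8$, the
   convergence approximation $F_1((\nu - \log\tfrac12)/\tau)$ increases to
   1 as $k/d \to \infty$, as it must; the literal signed factor (negative
   for $k > d$) would drive it to 0. The adopted positive-$\tau$
   convention is validated in the tests against Monte-Carlo
   $\Pr(\lambda_{\min}(W) > 1/2)$.

A consequence of (1) worth knowing: at fixed aspect ratio $\alpha = d/k$,
the median distortion *rises* with $d$ toward the deterministic edge
$(1 + \sqrt\alpha)^2 - 1$, because the $F_1$ term $\sigma\,q_{F_1}(0.5)$
(negative) shrinks.

In the proportional regime ($d/n \to \gamma$, $k/n \to \xi$) the Hadamard
sketch concentrates faster than the Wishart law predicts: the limiting
spectral edges are $(\sqrt{1-\gamma} \mp \sqrt{(1-\xi)\alpha})^2$
(`esd_limits()`), the distortion degenerates to
$\sigma^* = \max(|1-\lambda_{\min}|, |1-\lambda_{\max}|)$, and the
embedding probability becomes a step at $\sigma^*$
(`esd_embedding_prob()`). These limits are derived for the
without-replacement variant; the functions evaluate the formula for any
configuration and leave the interpretation to the caller.

## The Tracy–Widom evaluation

`ptw1()` interpolates a precomputed grid of $F_1$ on $[-7.2, 6.5]$ at step
$0.01$ (`inst/extdata/tw1_cdf_grid.tsv`) with a Hyman-filtered monotone
cubic spline; outside the grid the leading-order tail asymptotics
$\log F_1 \sim -|s|^3/24$ and $\log(1-F_1) \sim -\tfrac23 s^{3/2}$ are used
with two coefficients matched to the value and slope at the grid edge, and
results are clamped to $[0,1]$. The grid derives from the Painlevé II
representation (Hastings–McLeod solution started from Airy initial values,
with the determinant integrals carried along the ODE), generated by
`tools/make_tw1_grid.py`; two independent integrators agree to
$5 \times 10^{-7}$ on the grid, and the backward integration is stopped at
$s = -7.2$, where $F_1 \approx 10^{-10}$, before the well-known instability
of the Hastings–McLeod branch sets in. The test suite regenerates a coarse
reference with a *separate* implementation (asymptotic-series Airy values,
`deSolve::lsoda`) and requires agreement to $10^{-4}$; `qtw1()` inverts the
cdf by bisection to $10^{-6}$ roundtrip accuracy.

## Parameters that matter

* `k` (sketch size): the only real budget knob. Rules of thumb visible in
  the formulas: $k \approx 20d$ gives convergence probability near 1 and
  median distortion near $(1 + \sqrt{1/20})^2 - 1 \approx 0.5$.
* `tol = 1e-6`, `max_iter = 2000`, zero start: the iteration's stopping
  protocol; convergence is declared at the first time the unnormalized
  gradient norm $\|X^\top(y - X\beta)\|_2$ drops below `tol`. A relative
  criterion is deliberately not the default. A divergence guard stops the
  loop when the gradient exceeds $10^{12}$ times its initial value
  (counted as non-convergence) — this guard is an implementation safety
  net, not part of the convergence definition.
* `rho = 0.5`: AR(1) column correlation of the synthetic design
  (`sim_ar1_design()`), the standard moderately-collinear testbed.
* `row_sampling`: Hadamard rows drawn with replacement (the family's
  definition) or without (the variant under which the proportional-regime
  spectral limits are exact).

## What the synthetic data emulates — and what it does not

`sim_ar1_design()` draws i.i.d. rows from $N(0, \Sigma)$,
$\Sigma_{ij} = \rho^{|i-j|}$, via the stationary AR(1) recursion; rows are
exchangeable and leverage is nearly flat ($\max_i h_i \approx d/n$). This
matches the homogeneous-population regime in which the universality
results are cleanest. Real genomic designs are *not* this benign: allele
frequencies skew leverage, and a handful of subjects can dominate. Tests
that specifically probe leverage sensitivity therefore construct their own
high-leverage matrices (a row of mass $\approx 1$ for the uniform-sketch
failure mode; a block of fixed-magnitude outlier rows, whose leverage
$\approx 400d/n$ provably dilutes as $n$ grows, for the universality
trend). Passing tests on AR(1) data alone would say little about
leverage-fragile regimes; passing both kinds says the implementation
respects the mechanism, not that any particular real dataset is safe.
`bootstrap_rows()` reproduces the device of enlarging a dataset by
resampling, which spreads leverage over duplicates.

## Numerical choices

* All eigencomputations run on $d \times d$ symmetric matrices (never an
  $n \times n$ projector); the preconditioner is Cholesky-factorized once
  and reused; the convergence condition whitens with the Cholesky factor
  rather than inverting.
* Numerical rank uses the SVD with tolerance $\max(n,d)\,\epsilon_{mach}
  \sigma_1$; orthonormality of $U$ is enforced to $10^{-8}$ in max norm.
* The CountSketch applies through a `Matrix::sparseMatrix` product; the
  Hadamard transform is a vectorized butterfly over all columns at once
  ($O(n' d \log n')$). Dense operators (`sketch_matrix()`) exist as
  testing oracles and reproduce the identical realization from the same
  seed (randomness is consumed in a documented fixed order: signs, then
  row choices).
* Strict inequality at the convergence boundary ($\lambda_{\max} = 2$
  diverges) is preserved; boundary tests use exactly representable
  constructions because a generic matrix lands on either side of 2 by
  floating-point accident.
* `k = d` is accepted for the upper-edge constants ($\alpha = 1$) but
  rejected for the lower-edge ones, where $\lambda_{\min}$ degenerates.

## Study scales in the test suite

The end-to-end checks run at sizes chosen to finish in minutes while
keeping each comparison's noise well below its tolerance: the
Tracy–Widom-vs-Wishart curve comparison at $d = 100$, $k = 2000$,
$B = 10{,}000$ (sup-distance tolerance 0.02); the convergence-probability
cross-check at $k = 560$, $d = 50$, $B = 5000$ Wishart draws (3 binomial
standard errors) plus a full pipeline at $n = 5000$, $d = 20$, $R = 200$
replicates; the universality trend at $d = 20$, $k = 400$ between
$n = 2^{12}$ and $2^{15}$ with $B = 500$ distortions per sample (averaged
over three samples per point for the CountSketch, whose deviation is the
smaller of the two); and the proportional-regime bracketing at $d = 50$,
$k = 1000$, $n = 5000$, $B = 1000$. The convergence-probability
cross-check sits at $d = 50$ rather than $d = 20$ because the $O(d^{-2/3})$
bias of the $F_1$ approximation at $d = 20$ ($\approx +0.01$) is
comparable to 3 binomial standard errors at $B = 5000$; at $d = 50$ the
bias is well inside the band. That bias is a property of the
approximation, not of the implementation.

## Known limitations

* The $F_1$ approximations are asymptotic; at small $d$ (say $d < 20$)
  the convergence-probability approximation can be off by a percent or
  two — enough to matter if the answer is used as a guarantee rather than
  a guide.
* No universality claim covers the uniform sketch; its bound is
  qualitative.
* The solver implements the basic preconditioned iteration only; no
  momentum/acceleration, no sketch refreshing, and no iterative
  extreme-eigenvalue machinery for very large $d$ (the dense $d \times d$
  eigensolver is the deliberate scope).
* Matrices are in-memory; out-of-core streaming is out of scope.
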