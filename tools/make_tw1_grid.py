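#!/usr/bin/env python
"""Generate the Tracy-Widom F1 cdf reference grid shipped in inst/extdata/.

Method: the Hastings-McLeod solution q(s) of Painleve II, q'' = s q + 2 q^3,
with boundary condition q(s) ~ Ai(s) as s -> +inf, gives the Tracy-Widom
distributions through

    F2(s) = exp( -J(s) ),            J(s) = int_s^inf (x - s) q(x)^2 dx
    F1(s) = exp( -I(s)/2 ) sqrt(F2(s)),  I(s) = int_s^inf q(x) dx

The integrals are carried along with the ODE: with K(s) = int_s^inf q^2 dx,
the augmented system is q' = p, p' = s q + 2 q^3, I' = -q, K' = -q^2,
J' = -K.  Initial conditions at s0 use Ai and quadrature of Ai / Ai^2.

Run from the repository root:  python tools/make_tw1_grid.py
Writes inst/extdata/tw1_cdf_grid.tsv (two columns: s, F1(s)).
"""
import numpy as np
from scipy.integrate import solve_ivp, quad
from scipy.special import airy

S0 = 8.0          # start of the backward integration; Ai(8) ~ 4e-9
# The backward IVP falls off the Hastings-McLeod branch near s ~ -7.4
# (classical instability); F1(-7.2) ~ 1e-10 so the grid stops safely at -7.2.
S_LO, S_HI, STEP = -7.2, 6.5, 0.01


def rhs(s, y):
    q, p, I, K, J = y
    return [p, s * q + 2.0 * q ** 3, -q, -q ** 2, -K]


def main():
    ai0, aip0, _, _ = airy(S0)
    I0 = quad(lambda x: airy(x)[0], S0, np.inf)[0]
    K0 = quad(lambda x: airy(x)[0] ** 2, S0, np.inf)[0]
    J0 = quad(lambda x: (x - S0) * airy(x)[0] ** 2, S0, np.inf)[0]

    grid = np.round(np.arange(S_HI, S_LO - STEP / 2, -STEP), 10)
    y0 = [ai0, aip0, I0, K0, J0]
    sol = solve_ivp(rhs, (S0, S_LO), y0, t_eval=grid,
                    method="LSODA", rtol=1e-12, atol=1e-14)
    assert sol.success
    q, p, I, K, J = sol.y
    f1 = np.exp(-0.5 * I - 0.5 * J)

    # independent-solver consistency check
    chk = solve_ivp(rhs, (S0, S_LO), y0, t_eval=grid,
                    method="DOP853", rtol=1e-11, atol=1e-13)
    f1_chk = np.exp(-0.5 * chk.y[2] - 0.5 * chk.y[4])
    print(f"max |LSODA - DOP853| on grid: {np.max(np.abs(f1 - f1_chk)):.3e}")

    s = sol.t[::-1]
    f1 = f1[::-1]

    # diagnostics against well-known F1 facts
    cdf = lambda x: np.interp(x, s, f1)
    mids = 0.5 * (s[1:] + s[:-1])
    mean = np.sum(mids * np.diff(f1))
    print(f"F1(0)      = {cdf(0.0):.6f}   (expect ~0.831908)")
    print(f"F1(0.9793) = {cdf(0.9793):.6f} (expect ~0.950)")
    print(f"median     = {np.interp(0.5, f1, s):.4f}  (expect ~-1.2686)")
    print(f"mean       = {mean:.6f} (expect ~-1.206534)")

    out = "inst/extdata/tw1_cdf_grid.tsv"
    with open(out, "w") as fh:
        fh.write("# Tracy-Widom F1 cdf grid; columns: s  F1(s)\n")
        fh.write("# generated by tools/make_tw1_grid.py\n")
        for si, fi in zip(s, f1):
            fh.write(f"{si:.2f}\t{fi:.12e}\n")
    print(f"wrote {out}: {len(s)} rows, range [{s[0]}, {s[-1]}]")


if __name__ == "__main__":
    main()
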