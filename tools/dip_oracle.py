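#!/usr/bin/env python
"""Reference oracle for the dip statistic.

Computes min over unimodal CDFs G of sup_x |F_n(x) - G(x)| by direct
linear programming. A unimodal CDF is convex to the left of its mode and
concave to the right, with at most one atom, located at the mode. For the
empirical CDF of a sample with distinct sorted values u_1..u_k and
cumulative fractions c_1..c_k (c_0 = 0), place the mode at each knot u_m
in turn and solve the LP

    minimise t over (g_1..g_k, l, t) subject to
      c_j - t <= g_j                      (band below, all j)
      g_j <= c_{j-1} + t                  (band above; j != m, continuity)
      c_m - t <= g_m <= c_m + t           (atom allowed at the mode)
      c_{m-1} - t <= l <= c_{m-1} + t     (left limit at the mode)
      g_{j-1} <= g_j,  g_{m-1} <= l <= g_m,  0 <= g, l <= 1
      slopes of (u_1,g_1)..(u_{m-1},g_{m-1}),(u_m,l) non-decreasing
      slopes of (u_m,g_m)..(u_k,g_k) non-increasing

and report the minimum over modes. A mode placed between knots is
equivalent to a mode at the right knot with an atom, so knot modes cover
all cases. Usage: dip_oracle.py < file-with-one-sample-per-line (values
whitespace-separated); prints one dip per line.
"""
import sys
import numpy as np
from scipy.optimize import linprog


def dip_lp(x):
    x = np.sort(np.asarray(x, dtype=float))
    n = x.size
    u, counts = np.unique(x, return_counts=True)
    k = u.size
    c = np.cumsum(counts) / n          # c_1..c_k
    c0 = np.concatenate([[0.0], c])    # c_0..c_k
    if k == 1:
        return 0.0
    best = np.inf
    nv = k + 2  # g_1..g_k, l, t
    L, T = k, k + 1
    for m in range(1, k + 1):
        A_ub, b_ub = [], []

        def le(coeffs, rhs):
            row = np.zeros(nv)
            for i, v in coeffs:
                row[i] = v
            A_ub.append(row)
            b_ub.append(rhs)

        for j in range(1, k + 1):
            gj = j - 1
            le([(gj, -1.0), (T, -1.0)], -c0[j])          # g_j >= c_j - t
            if j == m:
                le([(gj, 1.0), (T, -1.0)], c0[j])        # g_m <= c_m + t
            else:
                le([(gj, 1.0), (T, -1.0)], c0[j - 1])    # g_j <= c_{j-1} + t
        le([(L, 1.0), (T, -1.0)], c0[m - 1])             # l <= c_{m-1} + t
        le([(L, -1.0), (T, -1.0)], -c0[m - 1])           # l >= c_{m-1} - t
        for j in range(1, k):                            # monotone g
            le([(j - 1, 1.0), (j, -1.0)], 0.0)
        le([(L, 1.0), (m - 1, -1.0)], 0.0)               # l <= g_m
        if m >= 2:
            le([(m - 2, 1.0), (L, -1.0)], 0.0)           # g_{m-1} <= l

        # left chain points: (u_j, g_j) j<m plus (u_m, l); convex slopes
        lx = list(u[:m - 1]) + [u[m - 1]]
        li = list(range(m - 1)) + [L]
        for a in range(len(lx) - 2):
            d1 = lx[a + 1] - lx[a]
            d2 = lx[a + 2] - lx[a + 1]
            # (p2-p1)/d1 <= (p3-p2)/d2  ->  d2*p2 - d2*p1 - d1*p3 + d1*p2 <= 0
            le([(li[a], -d2), (li[a + 1], d1 + d2), (li[a + 2], -d1)], 0.0)
        # right chain points: (u_j, g_j) j>=m; concave slopes
        rx = list(u[m - 1:])
        ri = list(range(m - 1, k))
        for a in range(len(rx) - 2):
            d1 = rx[a + 1] - rx[a]
            d2 = rx[a + 2] - rx[a + 1]
            le([(ri[a], d2), (ri[a + 1], -(d1 + d2)), (ri[a + 2], d1)], 0.0)

        cvec = np.zeros(nv)
        cvec[T] = 1.0
        bounds = [(0.0, 1.0)] * (k + 1) + [(0.0, 1.0)]
        res = linprog(cvec, A_ub=np.array(A_ub), b_ub=np.array(b_ub),
                      bounds=bounds, method="highs")
        if res.status == 0 and res.fun < best:
            best = res.fun
    return best


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        x = np.array([float(v) for v in line.split()])
        print(f"{dip_lp(x):.12f}")


if __name__ == "__main__":
    main()
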