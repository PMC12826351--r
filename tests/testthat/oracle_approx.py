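"""Independent oracle for the L1-penalized balancing dual.

Positive/negative-part reformulation: theta = p - m with p, m >= 0 turns
  f(theta) + delta' |theta|,  f(theta) = mean(exp(Z theta)) - c' theta,
into a smooth bound-constrained program solved by a general solver
(scipy L-BFGS-B).
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize


def main(inp, outp):
    with open(inp) as fh:
        d = json.load(fh)
    Z = np.array(d["Z"], dtype=float)
    c = np.array(d["c"], dtype=float)
    delta = np.array(d["delta"], dtype=float)
    n, dd = Z.shape

    def fg(par):
        theta = par[:dd] - par[dd:]
        eta = np.minimum(Z @ theta, 500.0)
        u = np.exp(eta)
        f = u.mean() - c @ theta + delta @ (par[:dd] + par[dd:])
        g = Z.T @ u / n - c
        return f, np.concatenate([g + delta, -g + delta])

    res = minimize(fg, np.zeros(2 * dd), jac=True, method="L-BFGS-B",
                   bounds=[(0.0, None)] * (2 * dd),
                   options={"maxiter": 5000, "ftol": 1e-16, "gtol": 1e-12})
    theta = res.x[:dd] - res.x[dd:]
    u = np.exp(Z @ theta)
    value = float(u.mean() - c @ theta + delta @ np.abs(theta))
    with open(outp, "w") as fh:
        json.dump({"objective": value,
                   "theta": [float(x) for x in theta],
                   "success": bool(res.success)}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
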