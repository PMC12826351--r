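"""Independent oracle: solve the primal entropy-balancing problem directly.

Minimize sum w log w over w >= 0 subject to
  (1/n) H1' w1 = hbar,  (1/n) H0' w0 = hbar,  (1/n)(G1' w1 - G0' w0) = 0,
using a general-purpose constrained solver (scipy SLSQP). Used only as a
cross-check on tiny instances.
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize


def main(inp, outp):
    with open(inp) as fh:
        d = json.load(fh)
    H1 = np.atleast_2d(np.array(d["H1"], dtype=float))
    H0 = np.atleast_2d(np.array(d["H0"], dtype=float))
    G1 = np.atleast_2d(np.array(d["G1"], dtype=float))
    G0 = np.atleast_2d(np.array(d["G0"], dtype=float))
    hbar = np.array(d["hbar"], dtype=float)
    n1, n0 = H1.shape[0], H0.shape[0]
    n = n1 + n0
    q = G1.shape[1] if G1.size else 0

    def split(w):
        return w[:n1], w[n1:]

    def objective(w):
        return float(np.sum(w * np.log(w)))

    def obj_grad(w):
        return np.log(w) + 1.0

    cons = []
    p = H1.shape[1]
    for k in range(p):
        cons.append({
            "type": "eq",
            "fun": (lambda w, k=k: float(H1[:, k] @ split(w)[0] / n - hbar[k])),
            "jac": (lambda w, k=k: np.concatenate([H1[:, k] / n,
                                                   np.zeros(n0)])),
        })
        cons.append({
            "type": "eq",
            "fun": (lambda w, k=k: float(H0[:, k] @ split(w)[1] / n - hbar[k])),
            "jac": (lambda w, k=k: np.concatenate([np.zeros(n1),
                                                   H0[:, k] / n])),
        })
    for k in range(q):
        cons.append({
            "type": "eq",
            "fun": (lambda w, k=k: float((G1[:, k] @ split(w)[0]
                                          - G0[:, k] @ split(w)[1]) / n)),
            "jac": (lambda w, k=k: np.concatenate([G1[:, k] / n,
                                                   -G0[:, k] / n])),
        })

    res = minimize(objective, np.ones(n), jac=obj_grad, method="SLSQP",
                   bounds=[(1e-10, None)] * n, constraints=cons,
                   options={"maxiter": 2000, "ftol": 1e-14})
    with open(outp, "w") as fh:
        json.dump({"objective": float(res.fun),
                   "weights": [float(x) for x in res.x],
                   "success": bool(res.success)}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
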