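"""HiGHS backend for the minimum weighted proportional shortfall problem.

Reads a JSON batch of problem instances, solves each with
scipy.optimize.linprog (method="highs"; MILP via the integrality
argument when binary decisions are requested), and writes a JSON batch
of solutions. Variables are the per-unit decision proportions x_i
followed by the per-active-feature shortfalls y_j.

Usage: python lp_backend.py <input.json> <output.json>
"""

import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve_one(costs, targets, rij, problem):
    n = costs.shape[0]
    weights = np.atleast_1d(np.asarray(problem["weights"], dtype=float))
    budget = float(problem["budget"])
    binary = bool(problem.get("binary", False))

    active = np.where((weights > 0) & (targets > 0))[0]
    m = active.size
    if m == 0:
        return {"status": "error", "message": "no active feature", "objective": None, "x": None}

    t_act = targets[active]
    # objective: 0 on x, w_j / t_j on y_j
    c = np.concatenate([np.zeros(n), weights[active] / t_act])

    # shortfall rows: -r_j . x - y_j <= -t_j ; budget row: c . x <= B
    a_ub = np.zeros((m + 1, n + m))
    a_ub[:m, :n] = -rij[active, :]
    a_ub[:m, n:] = -np.eye(m)
    a_ub[m, :n] = costs
    b_ub = np.concatenate([-t_act, [budget]])

    bounds = [(0.0, 1.0)] * n + [(0.0, float(t)) for t in t_act]
    integrality = None
    if binary:
        integrality = np.concatenate([np.ones(n), np.zeros(m)])

    res = linprog(c, A_ub=a_ub, b_ub=b_ub, bounds=bounds,
                  method="highs", integrality=integrality)
    if res.status != 0:
        return {"status": "error", "message": str(res.message),
                "objective": None, "x": None}
    x = np.clip(res.x[:n], 0.0, 1.0)
    if binary:
        x = np.round(x)
    return {"status": "optimal", "message": "",
            "objective": float(res.fun), "x": x.tolist()}


def main(path_in, path_out):
    with open(path_in) as fh:
        batch = json.load(fh)
    out = {"instances": []}
    for inst in batch["instances"]:
        costs = np.atleast_1d(np.asarray(inst["costs"], dtype=float))
        targets = np.atleast_1d(np.asarray(inst["targets"], dtype=float))
        rij = np.asarray(inst["rij"], dtype=float)  # J x n (feature rows)
        if rij.ndim < 2:
            rij = rij.reshape(1, -1)
        sols = [solve_one(costs, targets, rij, p) for p in inst["problems"]]
        out["instances"].append({"solutions": sols})
    with open(path_out, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
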