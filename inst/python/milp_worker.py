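"""LP/MILP solver worker.

Reads a JSON problem file (argv[1]), solves every problem with HiGHS via
scipy.optimize.milp, writes a JSON result file (argv[2]).

Two modes per problem:

  batch      -- one base problem plus a list of variants; each variant may
                patch variable bounds and/or replace the objective.  Used for
                FBA/FVA, feasibility screens of reaction subsets, and L1
                net-flux minimization.
  enumerate  -- integer-cut enumeration: solve, read off the active set
                (gate variables at 0), append the cut sum_{k in active} z_k >= 1,
                repeat until the stopping rule fires.

All indices are 0-based.  |bound| >= 1e29 means +/- infinity.
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import LinearConstraint, Bounds, milp

INF_SENTINEL = 1e29


def _definitize(arr):
    a = np.asarray(arr, dtype=float)
    a[a >= INF_SENTINEL] = np.inf
    a[a <= -INF_SENTINEL] = -np.inf
    return a


def _build_matrix(spec):
    return sparse.csc_matrix(
        (np.asarray(spec["x"], dtype=float),
         (np.asarray(spec["i"], dtype=int), np.asarray(spec["j"], dtype=int))),
        shape=(int(spec["nrow"]), int(spec["ncol"])))


def _solve(c, sense, A, rlb, rub, lb, ub, integrality, extra_rows=None):
    """One (MI)LP solve; returns (status, objective, x)."""
    sign = -1.0 if sense == "max" else 1.0
    if extra_rows:
        eA = sparse.vstack([A] + [r[0] for r in extra_rows], format="csc")
        erlb = np.concatenate([rlb] + [[r[1]] for r in extra_rows])
        erub = np.concatenate([rub] + [[r[2]] for r in extra_rows])
    else:
        eA, erlb, erub = A, rlb, rub
    cons = LinearConstraint(eA, erlb, erub)
    res = milp(c=sign * np.asarray(c, dtype=float),
               constraints=cons,
               bounds=Bounds(lb, ub),
               integrality=np.asarray(integrality, dtype=int),
               options={"mip_rel_gap": 0.0, "presolve": True})
    if res.status == 0:
        return "optimal", float(sign * res.fun), [float(v) for v in res.x]
    if res.status == 2:
        return "infeasible", None, None
    return "status_%d" % res.status, None, None


def _run_batch(p, A, rlb, rub, lb, ub):
    base_c = np.asarray(p["c"], dtype=float)
    sols = []
    for var in p["variants"]:
        vlb, vub = lb.copy(), ub.copy()
        idx = np.asarray(var.get("bidx", []), dtype=int)
        if idx.size:
            vlb[idx] = _definitize(var["blb"])
            vub[idx] = _definitize(var["bub"])
        c = np.asarray(var["c"], dtype=float) if "c" in var else base_c
        sense = var.get("sense", p.get("sense", "min"))
        status, obj, x = _solve(c, sense, A, rlb, rub, vlb, vub,
                                p["integrality"])
        out = {"status": status}
        if status == "optimal":
            out["objective"] = obj
            if var.get("want_x", False):
                out["x"] = x
        sols.append(out)
    return {"solutions": sols}


def _run_enumerate(p, A, rlb, rub, lb, ub):
    gate = np.asarray(p["gate_idx"], dtype=int)
    stop = p.get("stop", "minimal-only")
    size_cap = int(p.get("size_cap", -1))
    max_count = int(p.get("max_count", 1000))
    n = A.shape[1]
    cuts = []
    sols = []
    truncated = False
    smin = None
    while True:
        status, obj, x = _solve(p["c"], p.get("sense", "max"), A, rlb, rub,
                                lb, ub, p["integrality"], extra_rows=cuts)
        if status != "optimal":
            break
        xv = np.asarray(x)
        active = gate[xv[gate] < 0.5]          # z = 0 <=> reaction used
        size = int(active.size)
        if smin is None:
            smin = size
        cap = smin if stop == "minimal-only" else size_cap
        if size > cap:
            break
        sols.append({"size": size,
                     "objective": obj,
                     "active": [int(k) for k in active],
                     "x": [float(v) for v in xv]})
        if len(sols) >= max_count:
            truncated = True
            break
        if size == 0:
            break                               # empty set has no cut
        row = sparse.csc_matrix(
            (np.ones(size), (np.zeros(size, dtype=int), active)), shape=(1, n))
        cuts.append((row, 1.0, np.inf))
    return {"solutions": sols, "truncated": truncated, "smin": smin}


def main(argv):
    with open(argv[1]) as fh:
        payload = json.load(fh)
    results = []
    for p in payload["problems"]:
        A = _build_matrix(p["A"])
        rlb, rub = _definitize(p["rlb"]), _definitize(p["rub"])
        lb, ub = _definitize(p["lb"]), _definitize(p["ub"])
        if p["mode"] == "batch":
            results.append(_run_batch(p, A, rlb, rub, lb, ub))
        elif p["mode"] == "enumerate":
            results.append(_run_enumerate(p, A, rlb, rub, lb, ub))
        else:
            raise ValueError("unknown mode: %r" % p["mode"])
    with open(argv[2], "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main(sys.argv)
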