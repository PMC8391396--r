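"""Batch LP/MILP backend.

Reads a JSON job list, solves each problem with scipy's HiGHS interface
(scipy.optimize.milp) and writes a JSON result list.  A problem consists of

  * column bounds ``lb``/``ub`` and 0/1 ``integrality`` flags,
  * a sparse constraint matrix ``A`` (1-based triplets) with row bounds
    ``rlb``/``rub``,
  * ``stages``: a lexicographic list of objectives; after a stage with
    ``fix: true`` the achieved optimum is appended as a constraint
    (>= opt - tol for "max", <= opt + tol for "min") before the next
    stage or the queries are solved,
  * ``queries``: independent objectives all solved under the final
    constraint set (this is how a flux variability analysis is batched).

Infinities are encoded as +/-1e30.  Everything is solved single-threaded,
so repeated runs are bit-reproducible.
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e30

STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded", 4: "error"}


def _decode_inf(v):
    # auto-unboxed JSON serializes length-1 vectors as scalars
    a = np.atleast_1d(np.asarray(v, dtype=float))
    a[a >= INF] = np.inf
    a[a <= -INF] = -np.inf
    return a


def _obj_vector(ncol, spec):
    c = np.zeros(ncol)
    ind = np.atleast_1d(np.asarray(spec.get("ind", []), dtype=int)) - 1
    val = np.atleast_1d(np.asarray(spec.get("val", []), dtype=float))
    c[ind] = val
    return c


def _solve(c, sense, A, rlb, rub, lb, ub, integrality, options):
    sign = -1.0 if sense == "max" else 1.0
    cons = LinearConstraint(A, rlb, rub) if A.shape[0] else None
    res = milp(
        sign * c,
        constraints=cons,
        bounds=Bounds(lb, ub),
        integrality=integrality,
        options=options,
    )
    status = STATUS.get(res.status, "error")
    out = {"status": status}
    if status == "optimal":
        out["objective"] = float(sign * res.fun)
        out["x"] = [float(v) for v in res.x]
    return out


def solve_problem(p):
    ncol = int(p["ncol"])
    lb = _decode_inf(p["lb"])
    ub = _decode_inf(p["ub"])
    integrality = np.atleast_1d(np.asarray(p.get("integrality", [0] * ncol),
                                           dtype=int))
    a = p.get("A") or {}
    nrow = int(a.get("nrow", 0))
    if nrow:
        A = sparse.csc_matrix(
            (
                np.atleast_1d(np.asarray(a["x"], dtype=float)),
                (
                    np.atleast_1d(np.asarray(a["i"], dtype=int)) - 1,
                    np.atleast_1d(np.asarray(a["j"], dtype=int)) - 1,
                ),
            ),
            shape=(nrow, ncol),
        )
        rlb = _decode_inf(p["rlb"])
        rub = _decode_inf(p["rub"])
    else:
        A = sparse.csc_matrix((0, ncol))
        rlb = np.zeros(0)
        rub = np.zeros(0)

    opts = {"presolve": True}
    opts.update(p.get("options") or {})

    stage_out = []
    dead = None
    for st in p.get("stages", []):
        if dead is not None:
            stage_out.append({"status": dead})
            continue
        c = _obj_vector(ncol, st)
        res = _solve(c, st.get("sense", "min"), A, rlb, rub, lb, ub, integrality, opts)
        stage_out.append(res)
        if res["status"] != "optimal":
            dead = res["status"]
            continue
        if st.get("fix", False):
            tol = float(st.get("tol", 1e-9))
            row = sparse.csc_matrix(c.reshape(1, -1))
            A = sparse.vstack([A, row], format="csc")
            if st.get("sense", "min") == "max":
                rlb = np.append(rlb, res["objective"] - tol)
                rub = np.append(rub, np.inf)
            else:
                rlb = np.append(rlb, -np.inf)
                rub = np.append(rub, res["objective"] + tol)

    query_out = []
    for q in p.get("queries", []):
        if dead is not None:
            query_out.append({"status": dead})
            continue
        c = _obj_vector(ncol, q)
        query_out.append(
            _solve(c, q.get("sense", "min"), A, rlb, rub, lb, ub, integrality, opts)
        )

    return {"stages": stage_out, "queries": query_out}


def main(argv):
    with open(argv[1]) as fh:
        payload = json.load(fh)
    out = {"problems": [solve_problem(p) for p in payload["problems"]]}
    with open(argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv)
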