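"""Exact 0/1 integer-programming backend for contact-map decoding.

Reads a JSON file with a list of problems, each
    {"u": [...], "v": [...], "w": [[row-major |P| x |R|]],
     "xcap": number | [..] | null, "ycap": number | [..] | null}
and writes a JSON file with one result per problem:
    {"status": int, "objective": float, "contacts": [[i, j], ...]}  (1-based)

The model maximized is
    sum_i u_i x_i + sum_j v_j y_j + sum_ij w_ij z_ij
subject to   x_i + y_j >= 2 z_ij            (link)
             x_i <= sum_j z_ij              (residue coverage)
             y_j <= sum_i z_ij              (base coverage)
             y_{j-1} + (1 - y_j) + y_{j+1} >= 1   (no isolated bound base,
                                             out-of-range terms = 0)
             sum_j z_ij <= X_i,  sum_i z_ij <= Y_j.
Solved with HiGHS branch-and-cut (scipy.optimize.milp) at zero MIP gap.
"""
import json
import sys

import numpy as np
import scipy.sparse as sp
from scipy.optimize import Bounds, LinearConstraint, milp


def solve_one(prob):
    u = np.asarray(prob["u"], dtype=float)
    v = np.asarray(prob["v"], dtype=float)
    nP, nR = len(u), len(v)
    w = np.asarray(prob["w"], dtype=float).reshape(nP, nR)

    def caps(raw, n):
        if raw is None:
            return None
        arr = np.broadcast_to(np.asarray(raw, dtype=float), (n,))
        if np.all(np.isinf(arr)):
            return None
        return np.minimum(arr, nP * nR)

    xcap = caps(prob.get("xcap"), nP)
    ycap = caps(prob.get("ycap"), nR)

    def zvar(i, j):
        return nP + nR + i * nR + j

    nvar = nP + nR + nP * nR
    rows, cols, vals, lo, hi = [], [], [], [], []
    r = 0
    for i in range(nP):
        for j in range(nR):
            rows += [r, r, r]
            cols += [i, nP + j, zvar(i, j)]
            vals += [1.0, 1.0, -2.0]
            lo.append(0.0)
            hi.append(np.inf)
            r += 1
    for i in range(nP):
        rows.append(r); cols.append(i); vals.append(-1.0)
        for j in range(nR):
            rows.append(r); cols.append(zvar(i, j)); vals.append(1.0)
        lo.append(0.0); hi.append(np.inf); r += 1
    for j in range(nR):
        rows.append(r); cols.append(nP + j); vals.append(-1.0)
        for i in range(nP):
            rows.append(r); cols.append(zvar(i, j)); vals.append(1.0)
        lo.append(0.0); hi.append(np.inf); r += 1
    for j in range(nR):
        # y_{j-1} - y_j + y_{j+1} >= 0, out-of-range terms absent
        if j > 0:
            rows.append(r); cols.append(nP + j - 1); vals.append(1.0)
        rows.append(r); cols.append(nP + j); vals.append(-1.0)
        if j < nR - 1:
            rows.append(r); cols.append(nP + j + 1); vals.append(1.0)
        lo.append(0.0); hi.append(np.inf); r += 1
    if xcap is not None:
        for i in range(nP):
            for j in range(nR):
                rows.append(r); cols.append(zvar(i, j)); vals.append(1.0)
            lo.append(-np.inf); hi.append(xcap[i]); r += 1
    if ycap is not None:
        for j in range(nR):
            for i in range(nP):
                rows.append(r); cols.append(zvar(i, j)); vals.append(1.0)
            lo.append(-np.inf); hi.append(ycap[j]); r += 1

    A = sp.csr_matrix((vals, (rows, cols)), shape=(r, nvar))
    c = -np.concatenate([u, v, w.ravel()])
    res = milp(c,
               constraints=LinearConstraint(A, np.array(lo), np.array(hi)),
               integrality=np.ones(nvar),
               bounds=Bounds(0.0, 1.0),
               options={"mip_rel_gap": 0.0})
    if res.status != 0 or res.x is None:
        return {"status": int(res.status),
                "message": str(getattr(res, "message", "")),
                "objective": None, "contacts": []}
    z = np.round(res.x[nP + nR:]).astype(int).reshape(nP, nR)
    ii, jj = np.nonzero(z)
    contacts = [[int(i) + 1, int(j) + 1] for i, j in zip(ii, jj)]
    obj = float(u @ np.round(res.x[:nP])) + float(v @ np.round(res.x[nP:nP + nR]))
    obj += float(w[z == 1].sum())
    return {"status": 0, "objective": obj, "contacts": contacts}


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    results = [solve_one(p) for p in payload["problems"]]
    with open(sys.argv[2], "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main()
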