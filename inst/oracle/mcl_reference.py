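#!/usr/bin/env python
"""Independent dense-matrix MCL used as a test oracle.

Reads a JSON object {"nodes": [...], "edges": [[a, b, w], ...],
"inflation": r} on stdin and writes a JSON list of clusters (lists of node
ids, sorted) on stdout. Standard MCL: self-loops of weight 1, column
normalization, expansion = matrix square, inflation = entrywise power with
renormalization, iterated to a fixed point; clusters are the supports of
attractor rows.
"""
import json
import sys

import numpy as np


def mcl(nodes, edges, inflation, self_loop=1.0, tol=1e-8, max_iter=1000):
    n = len(nodes)
    index = {v: i for i, v in enumerate(nodes)}
    A = np.zeros((n, n))
    for a, b, w in edges:
        A[index[a], index[b]] = w
        A[index[b], index[a]] = w
    A += self_loop * np.eye(n)
    M = A / A.sum(axis=0)
    for _ in range(max_iter):
        Mn = np.linalg.matrix_power(M, 2)
        Mn = Mn ** inflation
        Mn = Mn / Mn.sum(axis=0)
        Mn[Mn < 1e-12] = 0.0
        s = Mn.sum(axis=0)
        s[s == 0] = 1.0
        Mn = Mn / s
        if np.max(np.abs(Mn - M)) < tol:
            M = Mn
            break
        M = Mn
    M[M < 1e-6] = 0.0
    attractors = np.where(np.diag(M) > 0)[0]
    clusters = set()
    for a in attractors:
        support = tuple(sorted(np.where(M[a] > 0)[0]))
        clusters.add(support)
    # resolve overlaps: assign each node to the cluster with the largest
    # attractor value, ties to the smallest representative
    out = {}
    for support in sorted(clusters, key=lambda s: nodes[s[0]]):
        rows = [a for a in attractors
                if tuple(sorted(np.where(M[a] > 0)[0])) == support]
        for j in support:
            val = max(M[a, j] for a in rows)
            if j not in out or val > out[j][0] + 1e-12:
                out[j] = (val, support)
    groups = {}
    for j, (_, support) in out.items():
        groups.setdefault(support, []).append(j)
    covered = set(out)
    result = [sorted(nodes[j] for j in members) for members in groups.values()]
    result += [[nodes[j]] for j in range(n) if j not in covered]
    result.sort(key=lambda c: c[0])
    return result


def main():
    payload = json.load(sys.stdin)
    clusters = mcl(payload["nodes"], payload.get("edges", []),
                   payload.get("inflation", 2.0))
    json.dump(clusters, sys.stdout)


if __name__ == "__main__":
    main()
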