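"""Reference Markov Cluster implementation (dense NumPy).

Reads a JSON task list on stdin: [{"n": int, "edges": [[i, j, w], ...],
"inflation": float}, ...] with 0-based node indices, and writes a JSON list
of partitions (each a sorted list of sorted 0-based index lists) on stdout.
Conventions: self-loop per node equal to its maximum incident weight
(1.0 for isolated nodes), column-stochastic normalisation, expansion by
squaring, entrywise inflation, pruning below 1e-8, convergence when the
largest entry change drops below 1e-6, 100-iteration cap.  Clusters are
read from attractor rows (positive diagonal); overlapping attractor rows
are merged into systems and every column joins the system receiving its
largest flow (ties to the smallest attractor index).
"""
import json
import sys

import numpy as np


def mcl_partition(n, edges, inflation, max_iter=100, tol=1e-6, prune=1e-8):
    A = np.zeros((n, n))
    for i, j, w in edges:
        i, j = int(i), int(j)
        A[i, j] = max(A[i, j], w)
        A[j, i] = A[i, j]
    loops = A.max(axis=0)
    loops[loops == 0] = 1.0
    np.fill_diagonal(A, loops)
    M = A / A.sum(axis=0, keepdims=True)
    for _ in range(max_iter):
        M2 = np.linalg.matrix_power(M, 2) ** inflation
        M2[M2 < prune] = 0.0
        colsum = M2.sum(axis=0, keepdims=True)
        colsum[colsum == 0] = 1.0
        M2 = M2 / colsum
        delta = np.abs(M2 - M).max()
        M = M2
        if delta < tol:
            break
    attractors = [i for i in range(n) if M[i, i] > 0]
    parent = list(range(n))

    def find(x):
        while parent[x] != x:
            parent[x] = parent[parent[x]]
            x = parent[x]
        return x

    for i in attractors:
        for j in attractors:
            if M[i, j] > 0:
                a, b = find(i), find(j)
                if a != b:
                    parent[max(a, b)] = min(a, b)
    clusters = {}
    for col in range(n):
        flows = {}
        for i in attractors:
            if M[i, col] > 0:
                s = find(i)
                flows[s] = flows.get(s, 0.0) + M[i, col]
        if flows:
            best = min(flows, key=lambda s: (-flows[s], s))
        else:
            best = -col - 1
        clusters.setdefault(best, []).append(col)
    return sorted(sorted(v) for v in clusters.values())


def main():
    tasks = json.load(sys.stdin)
    out = [mcl_partition(t["n"], t["edges"], t["inflation"]) for t in tasks]
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
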