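"""UMAP embedding and HDBSCAN clustering worker.

Reads a scaled feature matrix (TSV, no header) and a JSON job description,
writes TSV results. Three modes:

  embed   jobs = {"n": int, "min_dist": float, "seed": int}
          -> TSV with columns x, y (one row per input row)
  cluster jobs = {"min_cluster_size": int}; input is an embedding TSV
          -> one integer label per row (-1 = noise)
  sweep   jobs = [{"n": ..., "min_dist": ..., "seed": ..., "c": [ints]}, ...]
          -> long TSV: n, c, row, x, y, label

Embeddings are deterministic for a fixed seed (random_state pins UMAP to
single-threaded exact mode); HDBSCAN is deterministic.
"""

import argparse
import json
import sys
import warnings

import numpy as np


def load_matrix(path):
    m = np.loadtxt(path, delimiter="\t", ndmin=2)
    if m.size == 0:
        sys.exit("empty input matrix")
    return m


def make_embedding(X, n, min_dist, seed):
    warnings.filterwarnings("ignore")
    import umap

    reducer = umap.UMAP(
        n_neighbors=int(n),
        min_dist=float(min_dist),
        n_components=2,
        metric="euclidean",
        random_state=int(seed),
    )
    return reducer.fit_transform(X)


def hdbscan_labels(emb, c):
    from sklearn.cluster import HDBSCAN

    return HDBSCAN(min_cluster_size=int(c)).fit_predict(emb)


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--mode", choices=["embed", "cluster", "sweep"],
                    required=True)
    ap.add_argument("--input", required=True)
    ap.add_argument("--jobs", required=True)
    ap.add_argument("--out", required=True)
    a = ap.parse_args()

    X = load_matrix(a.input)
    with open(a.jobs) as fh:
        jobs = json.load(fh)

    if a.mode == "embed":
        emb = make_embedding(X, jobs["n"], jobs["min_dist"], jobs["seed"])
        np.savetxt(a.out, emb, delimiter="\t", fmt="%.17g")
        return

    if a.mode == "cluster":
        lab = hdbscan_labels(X, jobs["min_cluster_size"])
        np.savetxt(a.out, lab, fmt="%d")
        return

    with open(a.out, "w") as fh:
        fh.write("n\tc\trow\tx\ty\tlabel\n")
        for job in jobs:
            emb = make_embedding(X, job["n"], job["min_dist"], job["seed"])
            for c in job["c"]:
                lab = hdbscan_labels(emb, c)
                for i in range(X.shape[0]):
                    fh.write("%d\t%d\t%d\t%.17g\t%.17g\t%d\n"
                             % (job["n"], c, i + 1, emb[i, 0], emb[i, 1],
                                lab[i]))


if __name__ == "__main__":
    main()
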