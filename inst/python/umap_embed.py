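"""Embed a precomputed distance matrix with UMAP, one embedding per seed.

Usage: python umap_embed.py DIST_CSV OUT_CSV N_NEIGHBORS MIN_DIST SEED[,SEED...]

DIST_CSV: square symmetric distance matrix with a header row and a leading
label column.  OUT_CSV gets columns seed,label,x,y.  n_neighbors is clipped
to n_items - 1 when the matrix is smaller than requested.
"""
import sys
import warnings

import numpy as np
import pandas as pd


def main():
    dist_csv, out_csv, n_neighbors, min_dist, seeds = sys.argv[1:6]
    n_neighbors = int(n_neighbors)
    min_dist = float(min_dist)
    seeds = [int(s) for s in seeds.split(",")]

    df = pd.read_csv(dist_csv, index_col=0)
    labels = [str(x) for x in df.index]
    D = np.ascontiguousarray(df.to_numpy(dtype=np.float64))
    n = D.shape[0]
    if D.shape[1] != n:
        sys.exit("distance matrix must be square")
    n_neighbors = min(n_neighbors, n - 1)

    with warnings.catch_warnings():
        warnings.simplefilter("ignore")
        import umap  # deferred: numba compilation is slow

        rows = []
        for seed in seeds:
            reducer = umap.UMAP(
                n_neighbors=n_neighbors,
                min_dist=min_dist,
                metric="precomputed",
                random_state=seed,
                n_components=2,
            )
            emb = reducer.fit_transform(D)
            for lab, (x, y) in zip(labels, emb):
                rows.append((seed, lab, float(x), float(y)))

    pd.DataFrame(rows, columns=["seed", "label", "x", "y"]).to_csv(
        out_csv, index=False
    )


if __name__ == "__main__":
    main()
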