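"""Fit a seeded 2-D UMAP on a TSV matrix (no header) and write the
embedding as TSV. Usage:

    python umap_embed.py in.tsv out.tsv seed n_neighbors min_dist
"""
import sys

import numpy as np
import umap


def main():
    infile, outfile = sys.argv[1], sys.argv[2]
    seed = int(sys.argv[3])
    n_neighbors = int(sys.argv[4])
    min_dist = float(sys.argv[5])
    x = np.loadtxt(infile, delimiter="\t", ndmin=2)
    reducer = umap.UMAP(n_components=2, n_neighbors=n_neighbors,
                        min_dist=min_dist, random_state=seed)
    emb = reducer.fit_transform(x)
    np.savetxt(outfile, emb, delimiter="\t")


if __name__ == "__main__":
    main()
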