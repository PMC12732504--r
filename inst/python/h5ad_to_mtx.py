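"""Convert an AnnData .h5ad container to the matrix.mtx/genes.tsv/
barcodes.tsv directory layout (genes x cells). Usage:

    python h5ad_to_mtx.py in.h5ad outdir [layer]
"""
import sys

import anndata
import numpy as np
import scipy.io
import scipy.sparse


def main():
    path, outdir = sys.argv[1], sys.argv[2]
    layer = sys.argv[3] if len(sys.argv) > 3 else None
    ad = anndata.read_h5ad(path)
    x = ad.layers[layer] if layer else ad.X
    if not scipy.sparse.issparse(x):
        x = scipy.sparse.csr_matrix(np.asarray(x))
    scipy.io.mmwrite(f"{outdir}/matrix.mtx", x.T)
    with open(f"{outdir}/genes.tsv", "w") as fh:
        fh.write("\n".join(map(str, ad.var_names)) + "\n")
    with open(f"{outdir}/barcodes.tsv", "w") as fh:
        fh.write("\n".join(map(str, ad.obs_names)) + "\n")


if __name__ == "__main__":
    main()
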