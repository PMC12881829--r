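"""Exchange bridge between AnnData h5ad files and a plain-text MTX layout.

Usage:
  python h5ad_bridge.py export <in.h5ad> <out_dir> <name_column>
  python h5ad_bridge.py import <in_dir> <out.h5ad> <name_column>

The exchange directory holds matrix.mtx (genes x cells, full %.17g
precision so float64 values round-trip bit-exactly), genes.tsv,
barcodes.tsv (barcode[<TAB>cell name]) and state.txt.
"""
import sys


def _fmt(x):
    if x == int(x) and abs(x) < 1e15:
        return str(int(x))
    return "%.17g" % x


def export(h5ad_path, out_dir, name_col):
    import os
    import anndata
    import numpy as np
    import scipy.sparse as sp

    ad = anndata.read_h5ad(h5ad_path)
    X = ad.X
    if sp.issparse(X):
        X = X.toarray()
    X = np.asarray(X, dtype=np.float64)  # cells x genes
    os.makedirs(out_dir, exist_ok=True)
    rows, cols = np.nonzero(X.T)  # genes x cells
    with open(os.path.join(out_dir, "matrix.mtx"), "w") as fh:
        fh.write("%%MatrixMarket matrix coordinate real general\n")
        fh.write("%d %d %d\n" % (X.shape[1], X.shape[0], len(rows)))
        vals = X.T[rows, cols]
        for r, c, v in zip(rows, cols, vals):
            fh.write("%d %d %s\n" % (r + 1, c + 1, _fmt(v)))
    with open(os.path.join(out_dir, "genes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, ad.var_names)) + "\n")
    names = None
    if name_col in ad.obs.columns:
        names = [str(v) for v in ad.obs[name_col]]
    with open(os.path.join(out_dir, "barcodes.tsv"), "w") as fh:
        for i, b in enumerate(ad.obs_names):
            if names is not None:
                fh.write("%s\t%s\n" % (b, names[i]))
            else:
                fh.write("%s\n" % b)
    state = ad.uns.get("state")
    if state is not None:
        with open(os.path.join(out_dir, "state.txt"), "w") as fh:
            fh.write(str(state) + "\n")


def import_(in_dir, h5ad_path, name_col):
    import os
    import anndata
    import numpy as np
    import pandas as pd
    from scipy.io import mmread

    X = np.asarray(mmread(os.path.join(in_dir, "matrix.mtx")).todense(),
                   dtype=np.float64).T  # cells x genes
    genes = [l.rstrip("\n") for l in open(os.path.join(in_dir, "genes.tsv"))]
    barcodes, names = [], []
    for line in open(os.path.join(in_dir, "barcodes.tsv")):
        parts = line.rstrip("\n").split("\t")
        barcodes.append(parts[0])
        if len(parts) > 1:
            names.append(parts[1])
    obs = pd.DataFrame(index=pd.Index(barcodes, name=None))
    if len(names) == len(barcodes) and names:
        obs[name_col] = names
    ad = anndata.AnnData(
        X=X, obs=obs, var=pd.DataFrame(index=pd.Index(genes, name=None)))
    state_file = os.path.join(in_dir, "state.txt")
    if os.path.exists(state_file):
        ad.uns["state"] = open(state_file).read().strip()
    ad.write_h5ad(h5ad_path)


def main():
    if len(sys.argv) != 5:
        sys.stderr.write(__doc__)
        return 2
    mode = sys.argv[1]
    if mode == "export":
        export(sys.argv[2], sys.argv[3], sys.argv[4])
    elif mode == "import":
        import_(sys.argv[2], sys.argv[3], sys.argv[4])
    else:
        sys.stderr.write("unknown mode: %s\n" % mode)
        return 2
    return 0


if __name__ == "__main__":
    sys.exit(main())
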