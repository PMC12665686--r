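"""Minimal H5AD <-> text bridge.

Only the expression matrix and the obs/var name vectors are touched; full
AnnData container semantics are out of scope. Invoked by the R package as
`python h5ad_bridge.py read <in.h5ad> <prefix>` or
`python h5ad_bridge.py write <out.h5ad> <prefix>` where the prefix names
`<prefix>_X.csv` (cells x genes, no header), `<prefix>_obs.txt` and
`<prefix>_var.txt`.
"""
import sys

import numpy as np


def main():
    mode, h5ad, prefix = sys.argv[1], sys.argv[2], sys.argv[3]
    import anndata
    if mode == "read":
        ad = anndata.read_h5ad(h5ad)
        X = ad.X
        if not isinstance(X, np.ndarray):
            X = X.toarray()
        np.savetxt(prefix + "_X.csv", np.asarray(X, dtype=float), delimiter=",")
        with open(prefix + "_obs.txt", "w") as fh:
            fh.write("\n".join(map(str, ad.obs_names)) + "\n")
        with open(prefix + "_var.txt", "w") as fh:
            fh.write("\n".join(map(str, ad.var_names)) + "\n")
    elif mode == "write":
        X = np.loadtxt(prefix + "_X.csv", delimiter=",", ndmin=2)
        obs = [l.rstrip("\n") for l in open(prefix + "_obs.txt")]
        var = [l.rstrip("\n") for l in open(prefix + "_var.txt")]
        ad = anndata.AnnData(X=X)
        ad.obs_names = obs
        ad.var_names = var
        ad.write_h5ad(h5ad)
    else:
        raise SystemExit(f"unknown mode {mode}")


if __name__ == "__main__":
    main()
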