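"""Bridge between the R package and HDF5 paired-image datasets.

Called as a subprocess; exchanges pixel data with R as raw little-endian
float32 streams plus a JSON header, so no R-side HDF5 binding is needed.

  write <h5path> <inbin> <tgtbin> <metajson>   build /pairs/{input,target}
  read  <h5path> <inbin> <tgtbin> <metajson>   dump datasets + attributes
  probe <h5path> <metajson>                    shapes/attributes only
"""
import json
import sys

import h5py
import numpy as np


def write(h5path, inbin, tgtbin, metajson):
    with open(metajson) as fh:
        meta = json.load(fh)
    shape = tuple(meta["shape"])            # (N, H, W)
    inp = np.fromfile(inbin, dtype="<f4").reshape(shape)
    tgt = np.fromfile(tgtbin, dtype="<f4").reshape(shape)
    with h5py.File(h5path, "w") as f:
        g = f.create_group("pairs")
        g.create_dataset("input", data=inp, dtype="<f4")
        g.create_dataset("target", data=tgt, dtype="<f4")
        for k in ("fraction", "dynamic_range_db", "seed"):
            if k in meta and meta[k] is not None:
                f.attrs[k] = meta[k]


def _meta(f):
    need = ["/pairs/input", "/pairs/target"]
    for key in need:
        if key not in f:
            raise SystemExit("schema error: missing dataset " + key)
    m = {"shape": list(f["/pairs/input"].shape)}
    for k in ("fraction", "dynamic_range_db", "seed"):
        if k in f.attrs:
            v = f.attrs[k]
            m[k] = v.item() if hasattr(v, "item") else v
    return m


def read(h5path, inbin, tgtbin, metajson):
    with h5py.File(h5path, "r") as f:
        m = _meta(f)
        np.asarray(f["/pairs/input"], dtype="<f4").tofile(inbin)
        np.asarray(f["/pairs/target"], dtype="<f4").tofile(tgtbin)
    with open(metajson, "w") as fh:
        json.dump(m, fh)


def probe(h5path, metajson):
    with h5py.File(h5path, "r") as f:
        m = _meta(f)
    with open(metajson, "w") as fh:
        json.dump(m, fh)


if __name__ == "__main__":
    cmd = sys.argv[1]
    {"write": write, "read": read, "probe": probe}[cmd](*sys.argv[2:])
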