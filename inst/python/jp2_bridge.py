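"""Batch JPEG 2000 encode/decode helper for 16-bit frames.

Protocol (all integers little-endian int32, rates float64):
  encode in : n, rows, cols, rate, then n*rows*cols uint16 samples
              (column-major within each frame, frames consecutive)
  encode out: n, then per frame: length, payload bytes
  decode in : n, rows, cols, then per frame: length, payload bytes
  decode out: n*rows*cols uint16 samples (column-major per frame)
"""
import io
import struct
import sys

import numpy as np
from PIL import Image


def main():
    mode = sys.argv[1]
    if mode == "probe":
        arr = np.arange(64, dtype=np.uint16).reshape(8, 8)
        buf = io.BytesIO()
        Image.fromarray(arr).save(buf, format="JPEG2000", irreversible=False)
        back = np.asarray(Image.open(io.BytesIO(buf.getvalue())))
        assert back.dtype == np.uint16 and (back == arr).all()
        return 0
    inpath, outpath = sys.argv[2], sys.argv[3]
    with open(inpath, "rb") as f:
        n, rows, cols = struct.unpack("<iii", f.read(12))
        if mode == "encode":
            (rate,) = struct.unpack("<d", f.read(8))
            data = np.frombuffer(f.read(n * rows * cols * 2), dtype="<u2")
            frames = data.reshape((n, rows * cols))
            with open(outpath, "wb") as out:
                out.write(struct.pack("<i", n))
                for i in range(n):
                    arr = np.ascontiguousarray(
                        frames[i].reshape((rows, cols), order="F"))
                    buf = io.BytesIO()
                    img = Image.fromarray(arr)
                    if rate <= 1.0:
                        img.save(buf, format="JPEG2000", irreversible=False)
                    else:
                        img.save(buf, format="JPEG2000", irreversible=True,
                                 quality_mode="rates",
                                 quality_layers=[float(rate)])
                    payload = buf.getvalue()
                    out.write(struct.pack("<i", len(payload)))
                    out.write(payload)
        elif mode == "decode":
            with open(outpath, "wb") as out:
                for _ in range(n):
                    (length,) = struct.unpack("<i", f.read(4))
                    img = Image.open(io.BytesIO(f.read(length)))
                    arr = np.asarray(img).astype(np.uint16)
                    out.write(arr.tobytes(order="F"))
        else:
            raise SystemExit("unknown mode: " + mode)
    return 0


if __name__ == "__main__":
    sys.exit(main())
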