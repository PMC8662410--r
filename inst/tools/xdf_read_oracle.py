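#!/usr/bin/env python
"""Independent XDF 1.0 decoder used as a cross-language read oracle.

Implements the public XDF binary layout directly with the standard library
(struct + xml.etree), sharing no code with the R reader it checks. For each
file given on the command line it emits one JSON object:

    {"<path>": {"<stream_id>": {"info": {...}, "timestamps": [...],
                                "values": [[...]], "clock_offsets": [...],
                                "footer_sample_count": int|null}}}

Deduced (omitted) per-sample timestamps are reconstructed as
previous + 1/nominal_srate, as the format prescribes. A truncated trailing
chunk is discarded silently; unknown tags are skipped.
"""
import json
import struct
import sys
import xml.etree.ElementTree as ET

FMT = {"float32": ("<f", 4), "double64": ("<d", 8), "int32": ("<i", 4)}


def read_varlen(buf, pos):
    nbytes = buf[pos]
    pos += 1
    val = int.from_bytes(buf[pos:pos + nbytes], "little")
    return val, pos + nbytes


def parse_samples(content, stream):
    pos = 4  # stream id already consumed by caller
    n, pos = read_varlen(content, pos)
    ch = stream["channel_count"]
    fmt = stream["channel_format"]
    dt = 1.0 / stream["nominal_srate"] if stream["nominal_srate"] > 0 else 0.0
    last_ts = stream["last_ts"]
    for _ in range(n):
        flag = content[pos]
        pos += 1
        if flag == 8:
            ts = struct.unpack_from("<d", content, pos)[0]
            pos += 8
        elif flag == 0:
            ts = last_ts + dt
        else:
            raise ValueError("bad timestamp flag %d" % flag)
        if fmt == "string":
            row = []
            for _ in range(ch):
                slen, pos = read_varlen(content, pos)
                row.append(content[pos:pos + slen].decode("utf-8"))
                pos += slen
        else:
            code, size = FMT[fmt]
            row = list(struct.unpack_from("<%d%s" % (ch, code[1]), content, pos))
            pos += ch * size
        stream["timestamps"].append(ts)
        stream["values"].append(row)
        last_ts = ts
    stream["last_ts"] = last_ts


def read_xdf(path):
    with open(path, "rb") as fh:
        buf = fh.read()
    if buf[:4] != b"XDF:":
        raise ValueError("bad magic in %s" % path)
    streams = {}
    pos = 4
    total = len(buf)
    while pos < total:
        nbytes = buf[pos]
        if nbytes not in (1, 4, 8) or pos + 1 + nbytes > total:
            break  # truncated / corrupt tail
        length = int.from_bytes(buf[pos + 1:pos + 1 + nbytes], "little")
        pos += 1 + nbytes
        if length < 2 or pos + length > total:
            break  # truncated trailing chunk
        tag = int.from_bytes(buf[pos:pos + 2], "little")
        content = buf[pos + 2:pos + length]
        pos += length
        if tag in (2, 3, 4, 6):
            sid = int.from_bytes(content[:4], "little")
        if tag == 2:  # StreamHeader
            root = ET.fromstring(content[4:].decode("utf-8"))
            streams[sid] = {
                "name": root.findtext("name"),
                "type": root.findtext("type"),
                "channel_count": int(root.findtext("channel_count")),
                "nominal_srate": float(root.findtext("nominal_srate")),
                "channel_format": root.findtext("channel_format"),
                "source_id": root.findtext("source_id"),
                "uid": root.findtext("uid"),
                "timestamps": [], "values": [], "clock_offsets": [],
                "footer_sample_count": None, "last_ts": 0.0,
            }
        elif tag == 3:  # Samples
            parse_samples(content, streams[sid])
        elif tag == 4:  # ClockOffset
            t, v = struct.unpack_from("<dd", content, 4)
            streams[sid]["clock_offsets"].append([t, v])
        elif tag == 6:  # StreamFooter
            root = ET.fromstring(content[4:].decode("utf-8"))
            streams[sid]["footer_sample_count"] = int(root.findtext("sample_count"))
        # tags 1 (FileHeader) and 5 (Boundary) carry no sample data; others skipped
    for s in streams.values():
        del s["last_ts"]
    return streams


def main(argv):
    out = {}
    for path in argv:
        out[path] = {str(k): v for k, v in read_xdf(path).items()}
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main(sys.argv[1:])
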