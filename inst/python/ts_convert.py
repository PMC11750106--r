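"""Convert between the binary tskit .trees container and the plain-text
tree-sequence table format used by the R package.

Usage:
  python ts_convert.py to_text   in.trees  out.txt
  python ts_convert.py from_text in.txt    out.trees
"""
import sys

import numpy as np
import tskit


def read_text(path):
    sec = None
    meta = {}
    nodes, edges, muts = [], [], []
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            if line.startswith("#"):
                tag = line[1:].strip()
                if tag in ("nodes", "edges", "mutations"):
                    sec = tag
                    next(fh)  # header row
                continue
            if sec is None:
                k, v = line.split()
                meta[k] = v
            elif sec == "nodes":
                i, t = line.split("\t")
                nodes.append((int(i), float("nan") if t == "NA" else float(t)))
            elif sec == "edges":
                c, p, l, r = map(int, line.split("\t"))
                edges.append((c, p, l, r))
            else:
                n, s = map(int, line.split("\t"))
                muts.append((n, s))
    return int(meta["m"]), int(meta["seq_len"]), nodes, edges, muts


def from_text(src, dst):
    m, seq_len, nodes, edges, muts = read_text(src)
    tab = tskit.TableCollection(sequence_length=seq_len)
    n = max([i for i, _ in nodes] + [m])
    times = {i: t for i, t in nodes}
    # text ids are 1-based and time-ordered; tskit ids = text id - 1
    for i in range(1, n + 1):
        t = times.get(i, float("nan"))
        if np.isnan(t):
            t = 0.0 if i <= m else float(i - m)  # rank stand-in
        tab.nodes.add_row(flags=tskit.NODE_IS_SAMPLE if i <= m else 0, time=t)
    for c, p, l, r in edges:
        tab.edges.add_row(left=l - 1, right=r, parent=p - 1, child=c - 1)
    site_id = {}
    for node, site in sorted(muts, key=lambda t: (t[1], t[0])):
        if site not in site_id:
            site_id[site] = tab.sites.add_row(
                position=site - 1, ancestral_state="0")
        tab.mutations.add_row(site=site_id[site], node=node - 1,
                              derived_state="1")
    tab.sort()
    tab.build_index()
    tab.compute_mutation_parents()
    tab.tree_sequence().dump(dst)


def to_text(src, dst):
    ts = tskit.load(src)
    m = ts.num_samples
    # relabel: leaves 1..m first, internal nodes in time order, so that
    # parent id > child id holds in the text tables
    times = ts.tables.nodes.time
    n = len(times)
    internal = np.setdiff1d(np.arange(n), ts.samples())
    order = internal[np.argsort(times[internal], kind="stable")]
    new_id = np.empty(n, dtype=int)
    new_id[ts.samples()] = np.arange(1, m + 1)
    new_id[order] = np.arange(m + 1, n + 1)
    inv = np.argsort(new_id)
    with open(dst, "w") as fh:
        fh.write("#treeseq-text 1\n")
        fh.write("m %d\nseq_len %d\n" % (m, int(ts.sequence_length)))
        fh.write("#nodes\nid\ttime\n")
        for u in inv:
            fh.write("%d\t%.10g\n" % (new_id[u], ts.node(int(u)).time))
        fh.write("#edges\nchild\tparent\tleft\tright\n")
        for e in ts.edges():
            fh.write("%d\t%d\t%d\t%d\n"
                     % (new_id[e.child], new_id[e.parent], int(e.left) + 1,
                        int(e.right)))
        fh.write("#mutations\nnode\tsite\n")
        rows = sorted(
            (int(ts.site(mu.site).position) + 1, int(new_id[mu.node]))
            for mu in ts.mutations())
        for pos, node in rows:
            fh.write("%d\t%d\n" % (node, pos))


if __name__ == "__main__":
    mode, src, dst = sys.argv[1:4]
    if mode == "to_text":
        to_text(src, dst)
    elif mode == "from_text":
        from_text(src, dst)
    else:
        raise SystemExit("unknown mode: " + mode)
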