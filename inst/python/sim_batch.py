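"""Batched coalescent simulation bridge.

Reads a JSON job file describing a batch of coalescent-with-recombination
simulations, runs msprime once per dataset, and writes three TSV tables
(nodes, edges, mutations) covering the whole batch, keyed by a `dataset`
column.  Coordinates are converted to the 1-based closed convention used by
the R package; node ids are 1-based with leaves 1..m first and internal
nodes relabelled in time order so that parent id > child id always holds.

Usage: python sim_batch.py job.json
"""
import json
import sys

import numpy as np
import msprime


def build_demography(model):
    kind = model["kind"]
    dem = msprime.Demography()
    if kind == "constant":
        dem.add_population(initial_size=model["N"])
    elif kind == "exponential":
        n0, tau = model["N0"], model["tau"]
        dem.add_population(initial_size=n0, growth_rate=tau)
        if tau < 0:
            # N(g) = N0*exp(-tau*g) grows into the past; cap at 2*N0
            g_cap = np.log(2.0) / (-tau)
            dem.add_population_parameters_change(
                time=g_cap, initial_size=2.0 * n0, growth_rate=0.0)
    elif kind == "step":
        dem.add_population(initial_size=model["N0"])
        dem.add_population_parameters_change(
            time=model["g_star"], initial_size=model["N_star"])
    elif kind == "piecewise":
        g = model["g"]
        n = model["N"]
        dem.add_population(initial_size=n[0])
        for gi, ni in zip(g[1:], n[1:]):
            dem.add_population_parameters_change(time=gi, initial_size=ni)
    else:
        raise ValueError("unknown demographic model kind: %s" % kind)
    return dem


def rate_map(sim, seq_len):
    if "map_pos" in sim:
        pos = list(sim["map_pos"])
        rates = list(sim["map_rate"])
        if pos[0] != 0:
            pos = [0] + pos
            rates = [rates[0]] + rates
        if pos[-1] < seq_len:
            pos = pos + [seq_len]
        else:
            rates = rates[: len(pos) - 1]
        return msprime.RateMap(position=pos, rate=rates)
    return sim["recomb_rate"]


def simulate_one(sim):
    seq_len = int(sim["seq_len"])
    kwargs = dict(
        samples=int(sim["m"]),
        ploidy=1,
        sequence_length=seq_len,
        recombination_rate=rate_map(sim, seq_len),
        demography=build_demography(sim["model"]),
        discrete_genome=True,
        random_seed=int(sim["seed"]),
    )
    gc = sim.get("gene_conversion")
    if gc:
        kwargs["gene_conversion_rate"] = gc["rate"]
        kwargs["gene_conversion_tract_length"] = gc["tract_length"]
    ts = msprime.sim_ancestry(**kwargs)
    if sim["mu"] > 0:
        ts = msprime.sim_mutations(
            ts, rate=sim["mu"], model=msprime.BinaryMutationModel(),
            discrete_genome=True, random_seed=int(sim["seed"]) + 7)
    return ts


def relabel(ts):
    """1-based node ids, leaves first, internal nodes in time order."""
    m = ts.num_samples
    times = ts.tables.nodes.time
    n = len(times)
    internal = np.setdiff1d(np.arange(n), ts.samples())
    order = internal[np.argsort(times[internal], kind="stable")]
    new_id = np.empty(n, dtype=int)
    new_id[ts.samples()] = np.arange(1, m + 1)
    new_id[order] = np.arange(m + 1, n + 1)
    return new_id


def tables_for(ts, dataset):
    new_id = relabel(ts)
    tab = ts.tables
    nodes = []
    inv = np.argsort(new_id)
    for old in inv:
        nodes.append((dataset, int(new_id[old]), float(tab.nodes.time[old])))
    edges = [
        (dataset, int(new_id[e.child]), int(new_id[e.parent]),
         int(e.left) + 1, int(e.right))
        for e in ts.edges()
    ]
    muts = []
    for mut in ts.mutations():
        pos = int(ts.site(mut.site).position) + 1
        muts.append((dataset, int(new_id[mut.node]), pos))
    muts.sort(key=lambda t: (t[2], t[1]))
    return nodes, edges, muts


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    out = job["out_prefix"]
    with open(out + ".nodes.tsv", "w") as fn, \
         open(out + ".edges.tsv", "w") as fe, \
         open(out + ".muts.tsv", "w") as fm:
        fn.write("dataset\tid\ttime\n")
        fe.write("dataset\tchild\tparent\tleft\tright\n")
        fm.write("dataset\tnode\tsite\n")
        for i, sim in enumerate(job["sims"], start=1):
            ts = simulate_one(sim)
            nodes, edges, muts = tables_for(ts, i)
            fn.writelines("%d\t%d\t%.10g\n" % t for t in nodes)
            fe.writelines("%d\t%d\t%d\t%d\t%d\n" % t for t in edges)
            fm.writelines("%d\t%d\t%d\n" % t for t in muts)
    with open(out + ".done", "w") as fh:
        fh.write("%d\n" % len(job["sims"]))


if __name__ == "__main__":
    main(sys.argv[1])
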