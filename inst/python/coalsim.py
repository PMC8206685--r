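"""Coalescent engine behind archstats::simulate_fragments().

Reads a JSON description of a demographic model (populations, migration
matrix, backward-time events in generations), simulates independent fragments
with msprime under the infinite-sites mutation model, and writes one row per
segregating site to a Feather file: fragment index, integer position, derived
allele counts per population, and the derived dosage of one diploid
"reference individual" per population (the first two sample haplotypes).

Usage: python coalsim.py <config.json>
"""

import json
import sys

try:
    import msprime
    import numpy as np
    import pyarrow as pa
    import pyarrow.feather as feather
except ImportError as exc:  # pragma: no cover
    sys.stderr.write(
        "coalsim.py requires msprime, numpy and pyarrow in the python on "
        "PATH: %s\n" % exc)
    sys.exit(3)


def build_demography(cfg):
    dem = msprime.Demography()
    for p in cfg["populations"]:
        dem.add_population(name=p["name"], initial_size=p["size"])
    for m in cfg.get("migration", []):
        dem.set_symmetric_migration_rate([m["pop_a"], m["pop_b"]], m["rate"])
    for ev in cfg["events"]:
        t = ev["time_gen"]
        typ = ev["type"]
        if typ == "pulse":
            dem.add_mass_migration(time=t, source=ev["pop"], dest=ev["dest"],
                                   proportion=ev["value"])
        elif typ == "join":
            dem.add_mass_migration(time=t, source=ev["pop"], dest=ev["dest"],
                                   proportion=1.0)
        elif typ == "migration_off":
            # shut down all migration involving the deme that just joined
            for m in cfg.get("migration", []):
                if ev["pop"] in (m["pop_a"], m["pop_b"]):
                    dem.add_migration_rate_change(
                        time=t, rate=0.0, source=m["pop_a"], dest=m["pop_b"])
                    dem.add_migration_rate_change(
                        time=t, rate=0.0, source=m["pop_b"], dest=m["pop_a"])
        elif typ == "size_change":
            dem.add_population_parameters_change(
                time=t, population=ev["pop"], initial_size=ev["value"])
        else:
            raise ValueError("unknown event type: %r" % typ)
    dem.sort_events()
    return dem


def african_branch_extra_mutations(ts, afr_ids, extra_rate, rng):
    """Sites created by extra mutations on branches private to the African
    sample (heterozygosity-linked mutation-rate extension). Returns a list of
    (position, carrier sample id array)."""
    out = []
    afr_set = set(afr_ids)
    for tree in ts.trees(tracked_samples=afr_ids):
        span = tree.interval.right - tree.interval.left
        if span <= 0:
            continue
        for u in tree.nodes():
            nt = tree.num_tracked_samples(u)
            if nt == 0 or nt != tree.num_samples(u):
                continue
            parent = tree.parent(u)
            if parent == -1:
                continue
            blen = tree.time(parent) - tree.time(u)
            k = rng.poisson(extra_rate * blen * span)
            for _ in range(int(k)):
                pos = tree.interval.left + rng.uniform(0, span)
                carriers = np.fromiter(tree.samples(u), dtype=np.int64)
                # private to Africans by construction
                assert set(carriers) <= afr_set
                out.append((pos, carriers))
    return out


def main(path):
    with open(path) as fh:
        cfg = json.load(fh)
    dem = build_demography(cfg)
    pops = cfg["populations"]
    names = [p["name"] for p in pops]
    sizes = [int(p["samples"]) for p in pops]
    samples = [msprime.SampleSet(n, population=nm, ploidy=1)
               for nm, n in zip(names, sizes)]
    idx = {}
    start = 0
    for nm, n in zip(names, sizes):
        idx[nm] = (start, start + n)
        start += n

    seed = int(cfg["seed"])
    nfrag = int(cfg["num_fragments"])
    scale = float(cfg.get("african_mutation_scale", 1.0))
    rng = np.random.default_rng(seed)

    reps = msprime.sim_ancestry(
        samples=samples, demography=dem, ploidy=2,
        sequence_length=float(cfg["fragment_length"]),
        recombination_rate=float(cfg["recombination_rate"]),
        num_replicates=nfrag, random_seed=seed)

    taxa = [nm for nm in names if nm not in cfg["human_pops"]]
    frag_col, pos_col = [], []
    cols = {}
    for nm in names:
        cols[nm + "_ac"] = []
        if sizes[names.index(nm)] >= 2:
            cols[nm + "_gt"] = []

    for j, ts in enumerate(reps):
        mts = msprime.sim_mutations(
            ts, rate=float(cfg["mutation_rate"]),
            random_seed=seed + 1000003 * (j + 1), discrete_genome=False)
        G = mts.genotype_matrix()
        positions = np.floor(
            np.array([s.position for s in mts.sites()])).astype(np.int64) + 1
        if scale != 1.0:
            a, b = idx[cfg["african_pop"]]
            extra = african_branch_extra_mutations(
                ts, np.arange(a, b), (scale - 1.0) * float(cfg["mutation_rate"]),
                rng)
            if extra:
                rows = np.zeros((len(extra), G.shape[1]), dtype=G.dtype)
                epos = np.zeros(len(extra), dtype=np.int64)
                for i, (p, carriers) in enumerate(extra):
                    rows[i, carriers] = 1
                    epos[i] = int(p) + 1
                G = np.vstack([G, rows])
                positions = np.concatenate([positions, epos])
                o = np.argsort(positions, kind="stable")
                G = G[o]
                positions = positions[o]
        nsite = G.shape[0]
        frag_col.append(np.full(nsite, j + 1, dtype=np.int32))
        pos_col.append(positions.astype(np.int32))
        for nm in names:
            a, b = idx[nm]
            cols[nm + "_ac"].append(
                G[:, a:b].sum(axis=1).astype(np.int32))
            if nm + "_gt" in cols:
                cols[nm + "_gt"].append(
                    G[:, a:a + 2].sum(axis=1).astype(np.int32))

    arrays = {"frag": np.concatenate(frag_col),
              "pos": np.concatenate(pos_col)}
    for k, v in cols.items():
        arrays[k] = np.concatenate(v)
    table = pa.table({k: pa.array(v) for k, v in arrays.items()})
    feather.write_feather(table, cfg["out"], compression="uncompressed")
    meta = {"n_fragments": nfrag,
            "sample_sizes": {nm: int(n) for nm, n in zip(names, sizes)},
            "taxa": taxa}
    with open(cfg["out"] + ".json", "w") as fh:
        json.dump(meta, fh)


if __name__ == "__main__":
    if len(sys.argv) != 2:
        sys.stderr.write(__doc__ + "\n")
        sys.exit(2)
    main(sys.argv[1])
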