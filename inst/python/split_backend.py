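"""msprime backend for the clean two-population split null.

Reads a JSON config on stdin:
  {"n1": .., "n2": .., "tau": .., "theta": .., "rhos": [..], "L": .., "seed": ..}
and writes one ms-format replicate per entry of "rhos" to stdout.

Scaling matches the ms convention used by the R package: time in units of
4N generations (pairwise coalescence rate 2 within a deme), theta = 4*N*mu
per locus, rho = 4*N*c per locus. With ploidy=1 populations of size 0.5,
msprime's generation equals one 4N unit; per-site rates are theta/L and
rho/(L-1).
"""
import json
import sys

import msprime


def build_demography(tau):
    dem = msprime.Demography()
    dem.add_population(name="p1", initial_size=0.5)
    dem.add_population(name="p2", initial_size=0.5)
    dem.add_population(name="anc", initial_size=0.5)
    dem.add_population_split(time=tau, derived=["p1", "p2"], ancestral="anc")
    return dem


def main():
    cfg = json.load(sys.stdin)
    n1, n2 = int(cfg["n1"]), int(cfg["n2"])
    tau, theta = float(cfg["tau"]), float(cfg["theta"])
    L = int(cfg["L"])
    rhos = [float(r) for r in cfg["rhos"]]
    seed = int(cfg["seed"])

    dem = build_demography(tau)
    out = sys.stdout
    out.write("msprime split backend\n\n")
    for i, rho in enumerate(rhos):
        s = (seed + 2654435761 * i) % (2**31 - 1) + 1
        ts = msprime.sim_ancestry(
            samples={"p1": n1, "p2": n2},
            demography=dem,
            ploidy=1,
            sequence_length=L,
            recombination_rate=rho / (L - 1) if L > 1 else 0.0,
            discrete_genome=False,
            random_seed=s,
        )
        mts = msprime.sim_mutations(
            ts,
            rate=theta / L,
            model=msprime.BinaryMutationModel(),
            discrete_genome=False,
            random_seed=s + 1,
        )
        positions = [site.position / L for site in mts.sites()]
        haps = list(mts.haplotypes())
        out.write("//\n")
        out.write("segsites: %d\n" % len(positions))
        if positions:
            out.write("positions: " +
                      " ".join("%.6f" % p for p in positions) + "\n")
            for h in haps:
                out.write(h + "\n")
        out.write("\n")


if __name__ == "__main__":
    main()
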