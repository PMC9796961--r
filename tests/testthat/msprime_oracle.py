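"""Independent coalescent oracle: expected branch-length joint SFS for a
two-deme split model, computed with msprime. Prints batch means of the
unfolded joint branch AFS (one batch per line, entries flattened in C
order) so the caller can form Monte-Carlo standard errors.

Usage: python msprime_oracle.py N_BIN N_SAU N_ANC T_SPLIT N1 N2 REPS BATCHES SEED
Sizes are diploid; T_SPLIT in generations; N1/N2 haploid sample sizes.
"""
import sys

import msprime
import numpy as np

n_bin, n_sau, n_anc = (float(x) for x in sys.argv[1:4])
t_split = float(sys.argv[4])
n1, n2 = int(sys.argv[5]), int(sys.argv[6])
reps, batches, seed = int(sys.argv[7]), int(sys.argv[8]), int(sys.argv[9])

dem = msprime.Demography()
dem.add_population(name="bin", initial_size=n_bin)
dem.add_population(name="sau", initial_size=n_sau)
dem.add_population(name="anc", initial_size=n_anc)
dem.add_population_split(time=t_split, derived=["bin", "sau"],
                         ancestral="anc")

assert n1 % 2 == 0 and n2 % 2 == 0, "haploid sample sizes must be even"
per_batch = reps // batches
out = []
for b in range(batches):
    acc = np.zeros((n1 + 1, n2 + 1))
    # diploid ploidy so that initial_size is a diploid N_e (pairwise
    # coalescence rate 1/(2N)); n1, n2 are haploid counts
    sims = msprime.sim_ancestry(
        samples={"bin": n1 // 2, "sau": n2 // 2}, demography=dem, ploidy=2,
        num_replicates=per_batch, random_seed=seed + b)
    for ts in sims:
        acc += ts.allele_frequency_spectrum(
            sample_sets=[ts.samples(population=0),
                         ts.samples(population=1)],
            mode="branch", polarised=True, span_normalise=True)
    out.append(acc.ravel() / per_batch)

for row in out:
    print(" ".join("%.17g" % v for v in row))
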