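"""Independent oracle for the speciation-by-fusion demography: expected
branch-length joint SFS from msprime for three demes where `alg` originates
at time T_HYB as an admixture of `bin` (proportion GAMMA) and `sau`, which
merge at T_DIV1. No migration. Prints batch means of the unfolded joint
branch AFS (C order), one batch per line.

Usage: python msprime_fusion_oracle.py N_BIN N_SAU N_ALG N_ANC_BIN \
    N_ANC_SAU N_ANC T_HYB T_DIV1 GAMMA N1 N2 N3 REPS BATCHES SEED
Sizes diploid; times in generations; N1..N3 haploid (even) sample sizes.
"""
import sys

import msprime
import numpy as np

(n_bin, n_sau, n_alg, n_anc_bin, n_anc_sau, n_anc, t_hyb, t_div1,
 gamma) = (float(x) for x in sys.argv[1:10])
n1, n2, n3 = (int(x) for x in sys.argv[10:13])
reps, batches, seed = (int(x) for x in sys.argv[13:16])
assert n1 % 2 == 0 and n2 % 2 == 0 and n3 % 2 == 0

dem = msprime.Demography()
dem.add_population(name="bin", initial_size=n_bin)
dem.add_population(name="sau", initial_size=n_sau)
dem.add_population(name="alg", initial_size=n_alg)
dem.add_population(name="anc", initial_size=n_anc)
dem.add_admixture(time=t_hyb, derived="alg", ancestral=["bin", "sau"],
                  proportions=[gamma, 1 - gamma])
# parental sizes above the pulse
dem.add_population_parameters_change(time=t_hyb, population="bin",
                                     initial_size=n_anc_bin)
dem.add_population_parameters_change(time=t_hyb, population="sau",
                                     initial_size=n_anc_sau)
dem.add_population_split(time=t_div1, derived=["bin", "sau"],
                         ancestral="anc")
dem.sort_events()

per_batch = reps // batches
for b in range(batches):
    acc = np.zeros((n1 + 1, n2 + 1, n3 + 1))
    sims = msprime.sim_ancestry(
        samples={"bin": n1 // 2, "sau": n2 // 2, "alg": n3 // 2},
        demography=dem, ploidy=2, num_replicates=per_batch,
        random_seed=seed + b)
    for ts in sims:
        acc += ts.allele_frequency_spectrum(
            sample_sets=[ts.samples(population=0),
                         ts.samples(population=1),
                         ts.samples(population=2)],
            mode="branch", polarised=True, span_normalise=True)
    print(" ".join("%.17g" % v for v in acc.ravel()))
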