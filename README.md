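# fusioncoal

Coalescent tests of speciation by fusion from the folded joint site
frequency spectrum (SFS).

`fusioncoal` is for population geneticists who suspect that a taxon of
uncertain phylogenetic placement is not a poorly resolved branch but a
lineage of hybrid origin. Given unlinked biallelic SNPs from three demes —
two candidate parental lineages (`bin`, `sau`) and the putative hybrid
(`alg`) — the package:

* simulates genealogies and SNP data under twelve competing demographic
  scenarios: three topologies (strictly bifurcating; bifurcating plus an
  introgression pulse; speciation by fusion, where `alg` originates from an
  admixture event between the two parental lineages) crossed with four
  gene-flow configurations (none, ancestral, contemporary, full);
* estimates each scenario's parameters by maximum composite likelihood,
  `lnL = sum_i m_i log p_i`, where `m_i` is the observed mass of folded
  joint-SFS cell `i` and `p_i` its probability under the model, estimated
  by Monte-Carlo coalescent simulation (expected branch lengths subtending
  each joint allele-count configuration, conditioned on polymorphism);
* compares scenarios with `AIC = 2k - 2 lnL`, `delta AIC`, and Akaike
  weights, and attaches percentile parametric-bootstrap confidence
  intervals to the winning model's parameters;
* computes four-taxon ABBA/BABA D-statistics
  (`D = (ABBA - BABA)/(ABBA + BABA)` with frequency weights
  `abba = (1-p1) p2 p3 (1-p4)`, `baba = p1 (1-p2) p3 (1-p4)`) with
  locus-bootstrap standard errors as an independent test for gene flow.

One deme's effective size is fixed from nucleotide diversity,
`N_e = pi / (4 mu)`, which makes the remaining sizes, event times (in
generations), admixture proportion `gamma`, and migration rates
identifiable from a polymorphism-only spectrum. The coalescent engine is
written in C++ and handles piecewise-constant sizes, continuous migration,
instantaneous admixture pulses, and deme mergers.

A synthetic-data module generates study-like datasets (three demes plus an
outgroup, ~60% missing genotype calls, ~2,000 variable SNPs retained after
50% hypergeometric downsampling) with a serialized ground-truth record, so
the whole pipeline is testable without any external data.

## Worked example

Simulate a 2,000-SNP folded joint SFS under the speciation-by-fusion model
at its published point estimates, then refit that model and compare
against the strictly bifurcating null:

```r
library(fusioncoal)

model   <- study_model(anchor = 1e6)        # fusion + contemporary gene flow
samples <- sample_config(18, 14, 6)         # haploid sizes per deme
obs     <- simulate_sfs(model, samples, n_snps = 2000, seed = 1)

set <- fit_settings(n_sims = 5e4, n_sims_final = 1e5, n_replicates = 20,
                    cycles = 9, iters_per_cycle = 25, triage_cycles = 1,
                    deepen_top = 3, polish_iters = 60)
fit <- fit_model(obs, model_spec("fusion", "contemporary"),
                 anchor = 1e6, settings = set, seed = 1)
fit
#> <fit_result> fusion+contemporary: lnL = -5970.67 (k = 11, 20 replicates)
#>     N_anc N_anc_sau N_anc_bin     N_sau     N_alg    T_div1     T_hyb gamma_hyb
#> 1.960e+05 6.117e+05 5.493e+04 2.800e+06 7.961e+05 1.826e+06 1.396e+06 1.941e-01
#> m_sau_alg m_bin_alg m_bin_sau
#> 5.173e-08 3.039e-08 4.736e-08
```

The refit recovers the generating values — `gamma_hyb = 0.24`,
`T_hyb = 1,365,495` generations, `T_div1 = 2,052,400` generations,
migration rates of a few 1e-8 — within their sampling spread: here
`gamma_hyb = 0.19`, `T_hyb = 1.40e6`, `T_div1 = 1.83e6`. With a 1-year
generation time (`time_in_years()`), `T_hyb` reads directly as ~1.4 Ma.

Model comparison on published likelihood/parameter-count pairs:

```r
tab <- data.frame(model = c("fusion+contemporary", "introgression+contemporary",
                            "bifurcating+none"),
                  lnL = c(-3092.83, -3097.91, -3158.59), k = c(11, 11, 6))
compare_models(tab)
#>                        model      lnL  k     AIC delta_AIC       weight
#> 1        fusion+contemporary -3092.83 11 6207.66      0.00 9.938185e-01
#> 2 introgression+contemporary -3097.91 11 6217.82     10.16 6.181461e-03
#> 3           bifurcating+none -3158.59  6 6329.18    121.52 4.069812e-27
```

The fusion scenario carries essentially all of the Akaike weight; the
strictly bifurcating history is ruled out (`delta AIC > 121`).

D-statistic on a synthetic study-like dataset (P1 = `sau`, P2 = `alg`,
P3 = `bin`, outgroup = `out`; `D > 0` means excess `alg`-`bin` sharing, the
fusion signal):

```r
gen <- generate_study_like(scale = 0.5, seed = 7)
d_statistic(gen$dataset, quartet_assignment("sau", "alg", "bin", "out"),
            n_boot = 1000, seed = 7)
#> <dstat_result> D = 0.4623 +/- 0.0343 SD; Z = 13.49; p = 1.8e-41
#>   ABBA = 144.78, BABA = 53.23 over 33615 loci (1014 informative)
```

A positive, strongly significant `D` is the expected signature of the
`bin`-into-`alg` admixture that the fusion model encodes.

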