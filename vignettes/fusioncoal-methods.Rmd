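---
title: "Coalescent tests of speciation by fusion: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent tests of speciation by fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

A narrowly distributed taxon (`alg`) sits uncertainly between two
well-separated clades (`bin` and `sau`). Three demographic histories can
produce that pattern: a strictly bifurcating tree with incomplete lineage
sorting, a bifurcating tree followed by an introgression pulse from `bin`
into `alg`, and speciation by fusion, in which `alg` itself originates from
an admixture event between the `bin` and `sau` ancestral lineages. Each
topology is crossed with four gene-flow configurations (none, ancestral,
contemporary, both), giving twelve scenarios (`enumerate_models()`).

The data are unlinked biallelic SNPs (one SNP per locus) summarized as a
folded joint three-deme site frequency spectrum (SFS), and scenarios are
compared by maximum composite likelihood with AIC model selection,
parametric-bootstrap confidence intervals, and four-taxon ABBA/BABA
D-statistics as an independent line of evidence for gene flow.

## Model parameterization

A `demographic_model` carries absolute diploid effective sizes with the
mutation rate held separately (mutation-scaled `theta = 4 N_e mu` appears
only at I/O boundaries via `theta_of()`); event times are in generations
(the taxa are univoltine, so generations read as years); migration rates
are symmetric per-generation backward rates; and the admixture coefficient
`gamma` is the fraction of `alg` lineages that trace to the `bin` side at
the pulse.

The free-parameter accounting is: bifurcating
`{N_anc, N_anc_sau, N_sau, N_alg, T_div1, T_div2}` (k = 6); introgression
adds `{T_int, gamma_int}` (k = 8); fusion replaces the `alg` branch with a
pulse, freeing `{N_anc, N_anc_sau, N_anc_bin, N_sau, N_alg, T_div1, T_hyb,
gamma_hyb}` (k = 8). Contemporary gene flow adds three pairwise rates;
ancestral gene flow adds one symmetric rate between the two parental
lineages, active from the `alg` merge (or pulse) up to `T_div1`. This is
the unique assignment that reproduces every published k (6..12) across the
twelve scenarios. The contemporary size of `bin` is never free: it is
anchored from nucleotide diversity as `N_e = pi / (4 mu)` (`ne_from_pi()`),
which is what makes the remaining parameters identifiable from a
polymorphism-conditioned SFS. The published analysis does not print its
anchor value; this package's study model (`study_model()`) uses
`N_e(bin) = 1e6` diploids, equivalent to `pi = 0.0112` at
`mu = 2.8e-9` — a typical orthopteran silent-site diversity. All
downstream recovery experiments simulate and refit with the same anchor,
so anchor choice does not propagate into the time or admixture estimates.

## The coalescent engine

`expected_sfs()` estimates SFS entry probabilities by simulating
genealogies backward in time under piecewise-constant deme sizes,
continuous migration within epochs, instantaneous pulses (each `alg`
lineage jumps to `bin` with probability `gamma`), and deme mergers. Under
infinite sites with a single variant placed uniformly on the total branch
length, the probability that a SNP falls in joint-frequency cell `(i, j,
k)`, conditional on polymorphism, is proportional to the expected branch
length subtending exactly that leaf configuration; the engine therefore
accumulates branch lengths per configuration over all simulated
genealogies rather than dropping one mutation per tree, which uses every
branch of every genealogy and cuts Monte-Carlo variance substantially at
no extra simulation cost. The accumulation is exact per genealogy: a
lineage's subtended configuration never changes during its lifetime, so
each node contributes its full branch length to one cell.

`simulate_snp_dataset()` mirrors the same convention from the data side:
loci that carry a SNP are an ascertained sample, biased toward long
genealogies (a short locus yields a SNP with probability proportional to
its total branch length when the per-site mutation rate is small), so the
simulator draws genealogies length-biased by rejection before placing the
variant. Simulated SNP data and the expected SFS therefore share one
probability model, and the single-population site-frequency law
`E[count of i-copy sites] proportional to 1/i` holds exactly in
expectation.

Entries with zero simulated mass are floored at `1 / (10 n_sims)` and the
spectrum renormalized, so observed data never meet a zero probability (the
analysis otherwise rejects parameter regions that merely failed to
simulate a rare cell). Pulses scheduled at the same instant as a merger
are processed in declared order (pulse first); any other exact tie in
event times is an error rather than a silent ordering choice.

Folding is on the global minor allele: cells whose total derived count
exceeds half the total sample size fold onto their complement, and cells
at exactly half frequency take the average of the complementary pair, so
mass is preserved and folding is idempotent.

## Composite likelihood and optimization

With unlinked SNPs, `lnL = sum_i m_i log p_i` over folded polymorphic
cells (natural log; `composite_loglik()`), treating the SNPs as a
multinomial sample conditioned on polymorphism. Monomorphic mass never
contributes, matching the "exclude invariant sites" convention of the
original analysis, and published AIC values are consistent with natural-log
likelihoods under `AIC = 2k - 2 lnL`.

The likelihood surface is simulation-based, so optimization is
derivative-free and noise-aware (`fit_settings()`, `fit_model()`):

* **Search space.** Sizes, times, and migration rates are searched in log
  space; proportions in logit space. Event ordering is built into the
  parameterization (`T_hyb = r T_div1`, `T_int = r1 T_div2 = r1 r2 T_div1`,
  each ratio in logit space), so every internal point is a valid
  demography and Nelder-Mead runs unconstrained.
* **Bounds.** Sizes and times span `1e3`–`1e7`; `gamma` spans
  `0.001`–`0.999`; migration rates span `1e-10`–`1e-6` per generation.
  The migration cap deserves a note: with divergence times of order `1e6`
  generations, rates above `~1e-6` imply many migration events per lineage
  per epoch — effective panmixia between demes that are, by hypothesis,
  distinct taxa — while multiplying the cost of exact coalescent
  simulation by orders of magnitude. The cap still sits an order of
  magnitude above the largest published upper CI bound (`1.06e-7`).
  Soft quadratic penalties (log scale) handle excursions outside the box.
* **Multi-start schedule.** Each replicate draws a log-uniform start,
  screens `prescan` further random candidates, and runs short Nelder-Mead
  cycles with a relative-improvement stopping rule (`stop_tol`, default
  `0.001`). With `triage_cycles` set, every replicate gets only the short
  triage budget and the `deepen_top` most promising replicates spend the
  remaining budget as one uninterrupted Nelder-Mead run — restarting the
  simplex discards its adaptation, so one long run dominates several short
  ones from the same point.
* **Noise control.** Within a replicate all evaluations reuse one
  simulation seed (common random numbers), making the search surface
  deterministic. This has a side effect worth knowing: a long search can
  end in a region where the stream's own fluctuations flatter it, so the
  reported maximum can exceed the true likelihood by many units in
  high-variance corners of parameter space. Two mechanisms correct for
  it: an optional `polish_iters` phase re-optimizes the leaders against a
  fresh stream at `n_sims_final` simulations, and every replicate's final
  likelihood is re-evaluated under one common high-precision stream before
  the best replicate is selected.

The default full-fidelity schedule (100 replicates, 1e5 simulations per
evaluation, up to 40 cycles, stopping criterion 0.001) mirrors the
original analysis; the recovery experiments in the tests and the
acceptance script use a reduced but structurally identical schedule
(20 replicates, 5e4 simulations per evaluation, triage plus deepen plus
polish) so a full three-parameter recovery across five seeds completes in
minutes on one CPU. Those problem sizes — 2,000-SNP spectra, 20 starts,
5 seeds — are stated here as the package's chosen desk-scale experiment
design.

## Model selection and uncertainty

`compare_models()` computes `AIC = 2k - 2 lnL`, `delta_AIC`, and Akaike
weights `exp(-delta/2) / sum exp(-delta/2)` from full-precision deltas
(recomputing weights from 2-decimal printed deltas reproduces published
weights only to about ±0.01, which is a rounding artifact, not a
discrepancy to chase). `parametric_bootstrap()` simulates replicate SFS of
the observed size from the fitted model, refits each, and reports
percentile intervals with linear order-statistic interpolation
(`quantile` type 7); the point estimate is reported as fitted and never
clamped into the interval. Bootstrap refits default to a reduced
optimization schedule, flagged in the result, because refitting 100
bootstrap spectra at search fidelity is rarely worth the cost — the
full schedule remains available by passing explicit `refit_settings`.

One identifiability caveat belongs here rather than in any test: a fusion
history is the boundary case of an introgression history (let the
`alg`/`sau` split time approach the pulse time), and with contemporary
gene flow both have k = 11. On data simulated under fusion, the
introgression model can therefore fit essentially as well, and AIC cannot
be expected to separate them reliably; the separation reported for the
real data (delta AIC ~ 10) reflects features of that dataset, not a
structural property. The package's end-to-end selection test accordingly
contrasts fusion against the strictly bifurcating null, which is the
structurally distinguishable alternative.

## D-statistics

`d_statistic()` uses the frequency-weighted four-taxon form:
`abba = (1 - p1) p2 p3 (1 - p4)`, `baba = p1 (1 - p2) p3 (1 - p4)` per
site, `D = (sum abba - sum baba) / (sum abba + sum baba)`, with the
standard error from resampling loci with replacement (default 1000
replicates), `Z = D / SD`, and a two-sided normal p-value; `|Z| > 3` is
reported alongside the raw p-value as the conventional significance flag.
Sites are polarized on the outgroup: the derived allele is the minority
allele among outgroup calls (an exact 50/50 outgroup keeps the coding as
read — such sites are rare and symmetric in expectation), and loci with
any role group entirely missing are excluded. `D > 0` indicates excess
sharing between P2 and P3; assigning `sau` to P1, `alg` to P2, and `bin`
to P3 makes the fusion signal positive.

## The synthetic-data generator

`generate_study_like()` emulates the study's data structure: three demes
of 18/14/6 diploids plus a 4-diploid outgroup, unlinked SNPs simulated
under `study_model()` (fusion with contemporary gene flow at the published
point estimates), independent genotype missingness at 60%, and a dataset
sized so the default 50%-of-individuals projection retains about
`scale x 1998` variable SNPs. The outgroup is modeled as a fourth deme
splitting from the root at `2 T_div1` with the root's size — the original
analysis provides no outgroup demography, and the outgroup exists only to
polarize D-statistic sites, for which any comfortably external split
works. The per-deme diploid counts are likewise a design choice: the
study pooled 77 individuals from many populations into three demes with
the hybrid taxon a narrow endemic, and 18/14/6 reproduces that shape; the
supplement with exact per-deme counts is not part of the package's
inputs, so the counts are configurable everywhere.

What the generator deliberately does not emulate: linked sites (loci are
exactly unlinked by construction), genotyping error, allele dropout and
depth-dependent missingness (masking is independent per call), selection,
and recombination within loci. Tests passing on these data therefore
validate the estimation machinery under the model's own assumptions; they
do not validate robustness to the ways real reduced-representation data
violate them.

## Numerical conventions collected

* Projection: expected hypergeometric mass (deterministic), not a single
  random subsample; loci under-covered in any deme are dropped; projected
  mass falling on monomorphic cells is discarded (`removeZeroSFS`
  convention). Default projection: 50% of individuals per deme, rounded
  down, at least one diploid.
* Folding ties at half frequency: averaged between the complementary pair.
* Zero-probability floor: `1 / (10 n_sims)`, then renormalize.
* Percentile CIs: linear interpolation between order statistics (type 7).
* All randomness flows from one integer seed through fixed derivation
  offsets; the coalescent engine has its own explicitly seeded generator,
  so results are independent of R's global RNG state, and identical seeds
  give bit-identical results.
* Likelihoods are natural-log throughout.

## Known limitations

* The composite likelihood treats SNPs as independent; with real
  ddRAD-style data the one-SNP-per-locus filter approximates this, but
  residual linkage would make the implied confidence statements
  anti-conservative.
* Monte-Carlo likelihood noise sets a resolution floor of a few log units
  at 5e4 simulations per evaluation; model pairs closer than that in
  expected lnL (notably fusion vs introgression on fusion-generated data)
  are not reliably separable at desk scale.
* The simulator is exact, so its cost grows linearly with the expected
  number of migration events; the migration search bound reflects that.
* Parameter recovery experiments fix the anchor at its generating value;
  with real data, error in the diversity estimate propagates into all
  size and time estimates proportionally.
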