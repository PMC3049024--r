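# dogphy

Discrete orthologue groups and phylogenomic intersection tests.

`dogphy` is an R package for a question that comes up whenever one
domain of life is suspected to have emerged from inside another: given
a well-supported *host* phylogeny (say, a set of archaeal genomes) and
a monophyletic *outgroup* (eukaryotes, or bacteria), on which branch of
the host tree does the outgroup attach? The package implements the full
workflow:

1. **Orthologue discovery** — every protein seeds an iterative
   profile search (calibrated log-odds profiles, E ≤ 10⁻⁵, gap-column
   and redundancy parsing between iterations, convergence on a hit-set
   fixpoint). A *discrete orthologue group* (DOG) is a hit set with at
   most one member per taxon that is recovered identically by the
   search seeded from **every** one of its members; anything else is
   discarded.
2. **Character matrices** — DOG detection/non-detection as binary
   characters, and trimmed, concatenated amino-acid supermatrices with
   an occupancy rule (≥ 10 non-gap characters per column) applied over
   the full taxon set.
3. **Phylogenetics** — a likelihood engine for the binary restriction
   model (with ascertainment conditioning, since all-absent families
   are unobservable) and empirical amino-acid models (WAG, Dayhoff,
   BLOSUM62), each with discrete-gamma rates (Γ8 for binary, Γ4 for
   amino acids) and an optional covarion switch process; exact
   coordinate-ascent branch optimization; fixed- and free-topology
   Metropolis samplers; ML search with bootstrap.
4. **Intersection tests** — for every internal edge of the fixed host
   topology (plus chosen terminal edges), the outgroup is grafted on,
   branch lengths are sampled by MCMC, and the log marginal likelihood
   is estimated by a stabilized harmonic mean. Support for edge *h* is
   the log₁₀ Bayes factor

   BF(h) = [ln ML(best) − ln ML(h)] / ln 10,

   averaged over substitution models; the cross-model r² of the BF
   vectors is the model-independence diagnostic.
5. **Maximum-likelihood corroboration** — per-site log-likelihoods per
   hypothesis feed the Shimodaira–Hasegawa test (RELL resampling,
   simultaneous one-sided construction) and the approximately unbiased
   (AU) test (multiscale bootstrap), plus the correlation between BF
   and ΔlnL profiles.
6. **Controls** — quartet support of the reference topology from
   per-gene trees, lateral-transfer filtering of clade-confined shared
   families, compositional-similarity diagnostics, and a stringent
   missing-data re-filter.

A synthetic-data module (species trees, gene gain/loss as a two-state
Markov chain, sequence families with optional paralogues and lateral
transfers, grafted intersection datasets) provides ground truth for
every stage, so the entire pipeline is testable offline.

## Worked example

The demo pipeline simulates 8 host taxa, 100 gene families, a 3-taxon
outgroup attached at a known internal edge and 2,000 intersection
sites, then runs every stage:

```r
library(dogphy)
mf <- run_pipeline(run_config(seed = 42, out_dir = "demo"))
mf$results$inter$map$report
```

```
  hypothesis       split     avg_bf rank flagged
1        H01       t4+t6 292.039540    5   FALSE
2        H02       t3+t7  36.018313    4   FALSE
3        H03    t1+t3+t7   0.000000    1   FALSE
4        H04       t2+t5  12.193068    3   FALSE
5        H05    t4+t6+t8  11.217816    2   FALSE
```

`H03` — the edge whose child side holds `{t1, t3, t7}` — has average
log₁₀ Bayes factor 0: it is the winning attachment point, and it is the
edge the outgroup was actually grafted onto. The ML tests agree
(`demo/topology_tests.tsv`):

```
hypothesis      lnl     delta    p_sh   p_au    avg_bf
H01   -23433.88  673.49  0.022  0.001   292.04
H02   -22841.76   81.37  0.423  0.001    36.02
H03   -22760.38    0.00  1.000  0.968     0.00
H04   -22789.30   28.91  0.494  0.044    12.19
H05   -22789.42   29.04  0.494  0.345    11.22
```

The true edge has SH p = 1 (it is the ML hypothesis) while the worst
placement is rejected at SH p = 0.022 and AU p = 0.001; the per-hypothesis ΔlnL values
track the Bayes factors. Of the 672 seeded searches, 666 were
category 2 (one sequence per taxon) and reconciled into 97 DOGs —
exactly the simulated families present in at least two taxa — and the
quartet support of the host tree from 25 per-gene ML trees is 83–98%
per edge (`demo/quartet_support.tsv`).

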