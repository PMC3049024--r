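---
title: "Orthologue-group discovery and phylogenomic intersection tests with dogphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthologue-group discovery and phylogenomic intersection tests with dogphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dogphy)
```

## What the package does

`dogphy` implements a complete phylogenomic workflow of the kind used to
ask where one domain of life attaches to the tree of another: identify
*discrete orthologue groups* (DOGs) across a set of proteomes by
iterative profile searches; treat detection/non-detection of each group
as a binary phylogenetic character and infer a tree under the
restriction model; concatenate the per-group amino-acid alignments into
a supermatrix; then, holding the host topology fixed, evaluate every
possible attachment point of a constrained monophyletic outgroup by
Bayesian marginal likelihoods (log10 Bayes factors) and by
maximum-likelihood topology tests (SH, AU). Quartet decomposition of
per-gene trees and amino-acid composition diagnostics guard against
missing-data and compositional artefacts.

Because real proteome sets are large and external, the package carries a
first-class synthetic-data module: species trees, gene gain/loss,
sequence families, paralogues and intersection datasets are simulated
with known ground truth, so every stage of the pipeline can be exercised
and validated end to end on a desk machine.

## The orthologue-search protocol

Each sequence in the proteome set seeds one iterative search
(`iterate_search()`):

1. build a profile from the current parsed alignment (initially the
   seed sequence alone);
2. score every database sequence by local profile-sequence dynamic
   programming and keep hits with E-value at most `1e-5`;
3. re-align the hit set, remove columns with *more than* 50% gaps and
   sequences *more than* 95% identical to an earlier one (both strict
   inequalities), and build the next profile;
4. stop when the hit set is identical to the previous iteration's, or
   at the safety cap (30 iterations; the result is flagged rather than
   raising an error).

Results fall into three categories: (1) nothing beyond the seed,
(2) at most one sequence per taxon, (3) paralogues in at least one
taxon. Only category-2 results can become DOGs, and a candidate group
is accepted only when the search seeded from *every* member returns
exactly the same set (`reconcile_dogs()`); set equality is the
acceptance relation. Accepted groups are disjoint by construction.
Outgroup proteomes are scanned with the accepted profiles and at most
one homologue — the best-scoring hit passing the threshold — is kept
per group and genome.

### Profile model and calibration

The profile is a calibrated log-odds position-specific scoring matrix
with per-column affine gap penalties scaled by column occupancy, not a
full profile HMM: the protocol's observable behaviour (iteration,
thresholds, categories) only needs a scoring model with well-calibrated
E-values, and the search interface is pluggable. Column frequencies are
blended with *substitution-mixture pseudocounts* (the observed column
propagated through the WAG transition matrix at one expected
substitution per site, mass 4): with naive background pseudocounts a
single-sequence profile penalizes every unobserved residue so harshly
that genuinely homologous but diverged family members score at decoy
level, and recall collapses. E-values come from a maximum-likelihood
Gumbel fit to the scores of at least 500 shuffled database sequences
(`E = D * P(S >= s)` over database size `D`); the decoy set is drawn
once per database and scored under every profile.

### Aligner

Hit sets are re-aligned by a built-in progressive aligner: a shared
k-mer distance matrix, an average-linkage guide tree, and global affine
profile-profile alignment under sum-of-pairs BLOSUM62 scores. Any
reasonable aligner satisfies the protocol's contract; the built-in one
keeps the pipeline self-contained and deterministic.

## Character matrices

`build_binary_matrix()` records detection/non-detection of each DOG per
taxon. `trim_blocks()` removes poorly aligned regions with a
conserved-block filter (a column is conserved when its majority residue
reaches half the sequences plus one and gaps are below half; blocks are
split at runs of more than 8 nonconserved columns, flanks trimmed, and
blocks shorter than 5 columns dropped). `concatenate()` pads taxa
missing from a family with gap rows *before* applying the occupancy
rule — only columns with at least 10 non-gap characters are kept — so
the rule operates over the full taxon universe exactly as it would on a
large sparse supermatrix. `stringent_filter()` re-applies the rule at a
fractional occupancy for missing-data robustness checks. The default
occupancy threshold of 10 is exposed as a parameter because its origin
is practical (matrix size), not statistical.

## Likelihood models

Two substitution model families are provided, both normalized to one
expected substitution per unit branch length at stationarity:

* empirical amino-acid models (WAG, Dayhoff, BLOSUM62 exchangeabilities
  with their equilibrium frequencies), and
* the binary *restriction* model for detection data, with likelihoods
  conditioned on characters being observable: a family absent from
  every genome can never be detected, so each site likelihood is
  divided by `1 - P(all absent)`.

Among-site rate variation uses the discrete-gamma approximation with
equal-probability categories (8 for binary data, 4 for amino acids, as
is conventional for these data types); category means are exact
incomplete-gamma expressions and average exactly 1. The covarion
process is the two-hidden-class switch model: a site is either "on"
(evolving at the model rate) or "off" (frozen), with switch rates
`s_on`/`s_off` composed into a doubled-state-space generator. This is
the simplest model in which a character invariant in one clade can be
variable elsewhere. The doubled generator is reversible, so the same
engine handles it via its eigendecomposition.

The engine computes Felsenstein-pruning likelihoods with per-node
rescaling, caches per-edge messages, and factorizes the likelihood as a
function of a single branch length through the model's
eigendecomposition, which makes branch-length-only updates (coordinate
ascent and MCMC proposals) cheap. Branch-length optimization is exact
sequential coordinate ascent — bounded Brent search per branch on
`[1e-8, 20]`, all cached partials refreshed before the next branch — so
the log-likelihood trace is monotone by construction; sweeps repeat
until the improvement falls below `1e-6` (a looser tolerance is used
where only large likelihood differences matter, e.g. per-hypothesis
optimization for topology tests).

## MCMC

Fixed-topology runs (the workhorse of the intersection analysis) use a
deterministic-scan Metropolis sampler: branch-length multiplier
proposals are made in depth-first sweep order with a handful of
consecutive proposals per edge visit, and a reflected sliding-window
proposal on the gamma shape is interleaved about once per sweep. Each
kernel leaves the posterior invariant, so the composition is a valid
MCMC scheme; the scan order simply lets the expensive per-edge
coefficients be reused across proposals. Priors are iid exponential
(rate 10) branch lengths — matching the random-start branch-length
distribution — and a uniform shape on `(0.05, 50)`. One "generation" is
one proposal, and samples are recorded at fixed intervals after a
configured burn-in; burn-in is configuration, not auto-detected, and
`plot()` on a chain trace shows the lnL series for choosing it.

Free-topology runs add NNI moves and optional Metropolis-coupled chains
(heat `1/(1 + 0.2 * rank)` with periodic swap proposals); they are used
for the binary-data tree and are implemented at R level since those
matrices are small. Metropolis coupling is only available on the
free-topology path — fixed-topology runs sample branch lengths and the
shape, which mix well without heating.

Proposal tuning constants (multiplier scale 1.0, shape window 0.35)
were chosen so acceptance rates sit comfortably inside [0.1, 0.7] on
reference runs of a few thousand amino-acid sites.

## Marginal likelihoods and Bayes factors

Per attachment hypothesis and substitution model, the log marginal
likelihood is estimated by the *stabilized harmonic mean* of the
post-burn-in sampled log-likelihoods, computed entirely in log space
(the naive harmonic mean overflows immediately at this scale), with a
standard error from a moving-block bootstrap (1,000 pseudo-replicates,
block length `sqrt(n)`) to respect autocorrelation. The harmonic-mean
family is known to be optimistic in absolute terms; every downstream
conclusion here depends only on *differences and ranks* across
hypotheses evaluated on the same data, which the estimator resolves
well. A stepping-stone estimator (8 power-posterior rungs on a
`Beta(0.3, 1)` schedule) is provided as an independent cross-check and
agrees with 1-D quadrature on analytically tractable cases in the test
suite.

Log10 Bayes factors are `(logML_best - logML_h) / ln 10`, zero for each
model's best hypothesis and positive otherwise; per-hypothesis averages
across models drive the edge ranking (`average_and_map()`, which also
flags factors above 1000), and `model_independence()` reports the
cross-model OLS r-squared of the Bayes-factor vectors — the diagnostic
that the placement signal does not depend on the chosen substitution
matrix. p-values throughout are floored at `1e-5`.

## Topology tests

`per_site_lnl()` optimizes each hypothesis and records per-site
log-likelihoods; resampling is done at the site-pattern level with
weights (equivalent to resampling raw columns, asserted by test). The
SH test uses the simultaneous one-sided construction: centre each
hypothesis's RELL-resampled totals by its own bootstrap mean, take the
across-hypothesis maximum as the replicate's null deviate, and compare
it with each observed lnL difference. p-values are exactly 1 for the
best hypothesis, non-increasing in the lnL difference, floored at
`1/n_replicates`, and conservative by construction. The AU test follows
the standard multiscale-bootstrap recipe (scales 0.5-1.4 in steps of
0.1, 1,000 replicates per scale, weighted least-squares fit of
`z(BP) = d*sqrt(r) + c/sqrt(r)`, `p = 1 - pnorm(d - c)`), with
degenerate fits clamped and flagged. Only the standard joint test over
the full hypothesis set is implemented; pairwise sub-tests between
selected hypotheses are out of scope.

## Quartet support and composition

Every four-taxon subset of each gene tree induces one quartet topology
(resolved via the four-point condition on topological distances; ties
are star quartets and uninformative). A quartet votes on every
reference edge that splits its four taxa two-against-two — the standard
quartet-mapping attribution — and per-edge support is the percentage of
agreeing informative quartets. Composition diagnostics pool residue
frequencies (gaps excluded) and relate the Euclidean (optionally
chi-square) distance between candidate-clade and outgroup profiles to
the average Bayes factors; no correlation is the desired outcome,
meaning placement is not driven by compositional attraction.

## The synthetic-data module

The generator defines the study conditions for every test:

* **Species trees** are fixed-size birth-death trees (`ape::rphylo`),
  rescaled to a target mean root-to-tip depth.
* **Gene content** evolves as a per-family two-state Markov chain with
  gain and loss rates from a Bernoulli root state. Gain is modelled as
  a reversible two-state process (not innovation-only) deliberately:
  the downstream inference treats detection as a reversible binary
  character, so parameter-recovery experiments are coherent. Families
  absent everywhere are unobservable and are re-drawn until the
  requested count of observable families is met, mirroring how
  detection data arise. An optional lateral-transfer rate copies
  presence to random recipients as a confounder.
* **Sequences** evolve site-iid under WAG/Dayhoff/BLOSUM62 with
  discrete-gamma categories; the covarion variant simulates on the
  doubled hidden space. Indels are off by default; the optional crude
  per-site subtree-deletion model exists only to exercise gap handling.
* **Proteomes**: "moderate divergence" for family recovery means the
  species tree rescaled to a mean root-to-tip depth of 0.35
  substitutions/site (mean pairwise identity roughly 55-65%), sequence
  length 80 — deep enough that single-seed searches must iterate
  through intermediates, shallow enough that homology is detectable at
  all. Paralogous copies are extra branches of configurable length
  within a taxon.
* **Intersection datasets**: a 12-taxon host at depth 1.0, a 4-taxon
  monophyletic outgroup at depth 0.5 grafted by a 0.3 stem onto a known
  internal edge, WAG+G4 sequences; the truth records the edge.

One global seed drives everything; child streams are derived by fixed
per-stage offsets, and identical seeds give byte-identical outputs
(tested via output-file hashes).

What the generator does *not* emulate: realistic indel processes,
genome rearrangement, rate heterogeneity across genes beyond the shared
gamma, compositional heterogeneity across lineages (available only as a
deliberate contrast in one diagnostic test), or any nucleotide-level
process. Passing tests therefore demonstrate algorithmic correctness
and internal consistency under the stated generative model — not that
the biological conclusions of any particular empirical dataset are
right.

## Problem sizes in the shipped tests

The validation suite runs everything at desk scale, chosen as the
package's own testing conditions: exhaustive likelihood oracles on all
4- and 5-taxon topologies; parameter recovery on 8 taxa x 10,000 sites;
orthologue discovery on 200 families x 12 taxa (sequence length 80);
intersection recovery on ten seeded 12+4-taxon datasets of 800 sites
with 5,000-generation samplers; the cross-model Bayes-factor comparison
on 1,000 sites in the suite and 10,000 sites in the standalone
reproduction script; SH calibration with 1,000 RELL replicates over 200
null experiments; and a full demo pipeline of 8 host taxa, 3 outgroup
taxa, 100 families and 2,000 intersection sites.

## Numerical choices

* Per-node rescaling of partial likelihoods at every internal node;
  scalers are tracked per pattern so per-site log-likelihoods are exact.
* Branch-length bounds `[1e-8, 20]`; Brent tolerance `1e-7`.
* Eigendecompositions via symmetrization with the stationary
  frequencies, valid for all reversible generators used here
  (including the covarion expansion).
* Ties in hit sorting and best-hit selection broken lexicographically
  by sequence ID; redundancy removal keeps the first (input-order)
  sequence of an offending pair. Both make reruns bit-reproducible.
* The LogDet starting distance for ML searches falls back to a
  corrected p-distance when the divergence matrix is singular.

## Known limitations

* The harmonic-mean marginal likelihood is used for ranking; absolute
  logML values inherit its optimism. Use the stepping-stone option when
  absolute values matter.
* The fixed-topology sampler does not sample covarion switch rates;
  covarion models run there with fixed switch rates (the free-topology
  R sampler has no such restriction, but is slower).
* The AU fit can be unstable when a hypothesis wins (or loses) every
  replicate at every scale; such cases are clamped and flagged rather
  than extrapolated.
* `iterate_search()` convergence is a fixpoint on hit sets with a hard
  cap; oscillating configurations terminate at the cap and are flagged
  `converged = FALSE` rather than resolved.
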