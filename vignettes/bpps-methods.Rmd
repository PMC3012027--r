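---
title: "Partitioning protein alignments with pattern selection: model and methods"
author: "bpps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning protein alignments with pattern selection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpps)
```

# The problem

A deep multiple sequence alignment of a protein class mixes many
functionally divergent subgroups. Two questions are coupled: *which
subgroup does each sequence belong to?* and *which alignment positions,
with which residues, define each subgroup?* `bpps` answers both at once.
The contract between them is the **hyperpartition**: an N × M table whose
rows are sequence subgroups and whose columns are contrast *categories*.
In a category, each subgroup is foreground (`+`), background (`-`) or
non-participating (`o`); the category's *pattern* is the set of alignment
columns (with residue sets such as `[ST]`) conserved in the foreground and
divergent in the background.

A rooted phylogenetic tree induces one canonical hyperpartition
(`hyperpartitionFromTree()`): one row and one column per node; row *i* is
`+` in column *j* when node *i* lies in the subtree rooted at *j*, `-` when
it lies in a sibling subtree, `o` otherwise. Internal-node rows are
*miscellaneous* subgroups — sequences that belong to a clade but to none of
its leaf subfamilies. Because the root has no sibling, no tree row can be
background in the root's column; we therefore make the appended `Rejected`
row (the sink for aberrant sequences) the background of the root category.
That mirrors how a top-level category is, in practice, a contrast of the
whole class against random sequences, and it keeps tree-derived schemes
valid under the validation rules (`validateHyperpartition()`): every real
row has a foreground cell, no two rows share a foreground signature,
M ≥ N, every category has both a foreground and a background, and the
`Rejected` row is never foreground.

# The column contrast model

Let a candidate pattern column carry residue set $R$, and let
$(m_F, u_F)$ and $(m_B, u_B)$ be the redundancy-weighted match/non-match
masses of the foreground and background sequences ('match' means the
residue is in $R$; gaps and `X` are always non-matches). With
$q = \Pr(R)$ under the weighted whole-alignment amino-acid composition,
the position's evidence in nats is the marginal-likelihood contrast

$$\mathrm{LLR} = \ell(m_F, u_F;\, a_F, b_F)
 + \ell(m_B, u_B;\, Aq, A(1{-}q))
 - \ell(m_F{+}m_B, u_F{+}u_B;\, Aq, A(1{-}q)),$$

$$\ell(m, u;\, a, b) = \ln \mathrm{B}(a{+}m,\, b{+}u) - \ln \mathrm{B}(a, b).$$

The first term scores the foreground under a high-conservation
$\mathrm{Beta}(a_F, b_F)$ prior on the match probability, the second scores
the background under a composition-matched null, and the third is the
shared-null alternative for the pooled counts; algebraically the whole
expression is the Bayes factor for "the foreground is a conserved draw, the
background is at the null" against "foreground and background share one
null-distributed match rate". No point estimates are involved, weighted
(non-integer) counts are handled exactly, and the per-position nats are
what the pattern-information report and the contrast-alignment histograms
display.

## Parameters that matter

* `fgPrior = c(9, 1)` — prior pseudocounts for the foreground match
  probability; mean 0.9 encodes that a pattern residue is expected in
  roughly 90% of foreground sequences. Units: pseudo-observations.
* `nullConcentration A = 20` — strength of the composition-matched null;
  small enough that a few hundred observations dominate it.
* `rho = 0.02` — prior inclusion probability per column. Each accepted
  position pays $\ln(\rho/(1-\rho)) \approx -3.89$ nats, so a position
  needs about 4 nats of evidence to enter the pattern; on a 200–300-column
  domain this yields patterns of order ten positions.
* `maxSetSize = 4` — residue sets are grown greedily from the
  frequency-ranked foreground residues (`{top1}`, `{top1, top2}`, ...);
  published patterns rarely exceed three residues.
* `minConservation = 0.5` — a position is accepted only while its residue
  set is carried by a weighted **majority** of the foreground. This is the
  package's operational reading of "conserved in the foreground": without
  it, the Bayes factor above also fires on positions where foreground and
  background genuinely differ but the foreground is *not* conserved (e.g. a
  residue at 8% in the foreground and 2% in the background), which in
  multi-category runs lets one category adopt columns that really belong to
  another. The gate is applied during candidate-set construction in the
  sampler's pattern sweep; `bestResidueSet()` exposes it as an argument and
  defaults to pure evidence maximisation.

## Preprocessing

Fragments (fewer than `minResidues = 100` non-gap residues, or under
`minCoverage = 50%` of columns — the coverage rule is this package's
concrete definition of a fragment and is configurable) are removed first;
then a greedy first-seen-kept pass removes any sequence sharing more than
98% identity (matches over jointly non-gap columns) with an already kept
sequence. Retention is deterministic in input order. The survivors get
position-based Henikoff weights — per column each sequence receives
$1/(rs)$, where $r$ is the number of distinct symbols in the column (gap
counts as a symbol type) and $s$ the multiplicity of its own symbol —
averaged over columns and rescaled to mean 1.

# The sampler

`runSampler()` alternates two sweeps until `patience = 3` consecutive
sweeps change nothing (or `maxSweeps = 500`):

1. **Assignment sweep.** Every non-seed sequence is scored against every
   subgroup row. The score is the exact conditional change in the total
   log posterior: leave-one-out beta-binomial predictive ratios of the
   sequence's residues at the current pattern positions — foreground model
   where the row's cell is `+`, background model where `-`, nothing where
   `o` (hence the all-`o` `Rejected` row scores 0, and a sequence enters it
   exactly when every competing row loses evidence on it). `greedy` mode
   takes the argmax (ties keep the current row); `sample` mode draws with
   probability ∝ exp(score/T).
2. **Pattern sweep.** For each category, every column is re-evaluated from
   the current assignment: best residue set (the incumbent set always stays
   in the candidate list, so a retained column cannot lose evidence),
   conservation gate, then inclusion iff LLR + ln(ρ/(1−ρ)) > 0 (greedy) or
   with the corresponding sigmoid probability at temperature T (sample
   mode). Position-level decisions are conditionally independent given the
   assignment, so this is a full conditional update.

Because assignment scores are exact conditional differences and pattern
decisions are per-column argmaxes, the greedy trace of the log posterior is
non-decreasing — an invariant the tests assert. The reported
`log_posterior` is recomputed from scratch each sweep and must agree with
the incremental bookkeeping to 1e-6.

Other choices worth recording:

* **Initialization.** Each non-seed sequence starts in the subgroup whose
  seed alignment gives it the highest fractional identity; exact ties go to
  `Rejected`. Patterns are then initialized by one greedy pattern sweep.
  This is the deterministic "meaningful starting point" heuristic.
* **Annealing.** `sample` mode starts at T = 2 and cools by 0.98 per sweep
  toward the greedy limit; the joint partition/pattern posterior is
  multimodal and early high-temperature sweeps let sequences cross between
  plausible rows. At T ≤ 1e-8 the code short-circuits to argmax, so a cold
  start reproduces `greedy` exactly.
* **Tie-breaks** are "keep current" (assignments) and "smaller/earlier"
  (residue sets, columns) everywhere, for determinism; with a fixed
  `rngSeed` whole trajectories are byte-reproducible.
* **Seeds** present in the main alignment are pinned to their subgroup in
  every sweep. Consensus seeds (not present as sequences) still steer
  initialization and rendering but pin nothing.
* **Category rejection.** A category whose pattern ends empty is reported
  as rejected (its contrast alignment says so); it is not an error.
* Categories are updated sequentially within a sweep against the current
  state of all others; joint inference does not require concurrency.

# Outputs

`renderContrast()` prints, per category: a constraint histogram (per-column
nats rescaled linearly to bar heights 1–10 over the displayed positions — a
relative, qualitative display; the TSV report holds the quantitative nats),
the seed rows, the foreground pattern line and its `wt_res_freqs` digits
(weighted set frequency in integer tenths, `floor(10f)` clamped to 9 so a
fully conserved position still occupies one character), and the background
counterparts prefixed `bg|` (plain text stands in for the gray of printed
figures). The *contrast setting* (default 10) chooses how many of the
strongest positions are highlighted. `writePatternInfo()` emits one row per
(category, position) with a reference label in the numbering of the
category's first seeded foreground sequence. `membershipProbabilities()`
returns the softmax of per-row scores; `writeAssignmentTable()` attaches
the assigned row's probability to every sequence.

# The synthetic benchmark

`syntheticSpec()` describes alignments with known truth; its defaults *are*
the study conditions used throughout the tests: 3 subgroups × 100 sequences,
200 columns, an identity hyperpartition (subgroup *i* foreground of
category *i*, background elsewhere), 10 planted positions per category with
foreground conservation `pF = 0.9` and background set-frequency
`pB = 0.1`, uniform background composition, 30 random-composition decoys,
and the first 3 members of each subgroup as its seed alignment. Planted
residue sets alternate sizes 1 and 2 and cycle deterministically through
the alphabet; planted columns interleave across categories. Misses at a
planted column draw from the non-set composition, so the set frequency is
exactly the intended rate in expectation (and the `pF = 1, pB = 0` limits
are exact). Optional duplicates and fragments exercise the purge.

What the generator does *not* emulate: phylogenetic correlation within
subgroups, indel processes, rate variation, biased amino-acid composition,
alignment errors. Passing recovery tests therefore demonstrates correctness
of the inference machinery under the model's own assumptions, not
performance on real alignments, where redundancy weighting and the purge
carry more of the load.

Problem sizes in the test suite are deliberately modest — unit fixtures of
3 × 12 to 3 × 50 sequences over 60 columns, the standard 3 × 100 benchmark
for recovery, 9-node random trees for the conversion oracle, n ≤ 50 for
the quadratic purge oracle — chosen as the smallest sizes at which each
property is informative.

# Numerical notes and limitations

* All marginals are computed through `lbeta`; evidence values are finite
  for any nonnegative (weighted) counts. The null set-probability q is
  clamped to (0, 1 − 1e-9]; the alignment composition carries a 0.5
  pseudocount per residue so q is never 0.
* Degenerate inputs: an all-gap foreground column yields no candidate set;
  a category whose foreground or background empties mid-run gets an empty
  (rejected) pattern rather than an error; an alignment that purges to
  nothing is an error.
* Globally conserved columns (same high frequency in foreground *and*
  background) can still score positive against the composition null; in
  tree-derived schemes the deeper categories are the intended home for
  such columns. The conservation gate does not remove them.
* The quadratic purge is O(n²) in sequences and is the scaling bottleneck
  for very deep alignments; the sampler itself is linear per sweep in
  sequences × pattern positions.
* The exact closed-form model of the original program is unpublished; the
  beta-binomial contrast here is this package's own concrete instantiation,
  isolated behind `columnLLR()` so alternatives (e.g. contrasting against
  the background partition's own composition) can be swapped in.

```{r session}
sessionInfo()
```
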