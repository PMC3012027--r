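# bpps

Multiple-category **B**ayesian **P**artitioning with **P**attern
**S**election for protein sequence alignments.

Large protein classes (P-loop GTPases, kinases, transporters, ...) split
into functionally divergent subgroups, and the residues that *define* a
subgroup are the ones conserved within it but divergent outside it. Given a
multiple sequence alignment of a protein class, `bpps` jointly

* classifies every sequence into one of *N* subgroups (plus a *Rejected*
  sink that absorbs pseudogene products and other aberrant sequences), and
* selects, for each of *M* contrast categories, the residue pattern — a set
  of alignment columns with residue sets such as `[ST]` or `[VI]` — that
  best separates that category's **foreground** subgroups from its
  **background** subgroups.

Which subgroups form the foreground and background of each category is
declared in a *hyperpartition*: an *N* × *M* table over `{+, -, o}` that
generalizes a rooted phylogenetic tree (every rooted tree converts into a
valid hyperpartition, one row and one column per node). A small curated
*seed alignment* anchors each subgroup; seed sequences stay fixed while a
Gibbs sampler reassigns everything else. The intended users are molecular
evolution and structural biology groups mapping functional divergence onto
residues — the same audience that runs specificity-determining-position
scans.

## The model

For category *j* with foreground set *F* and background set *B*, each
candidate pattern column contributes a beta-binomial contrast. With
weighted match/non-match masses (m_F, u_F) and (m_B, u_B) for a residue set
*R*, and q = pooled probability of *R* under the alignment-wide
composition:

    LLR = lbb(m_F, u_F; a_F, b_F)
        + lbb(m_B, u_B; Aq, A(1-q))
        - lbb(m_F+m_B, u_F+u_B; Aq, A(1-q))

    lbb(m, u; a, b) = ln B(a+m, b+u) - ln B(a, b)

i.e. a Bayes factor for "foreground conserved under a Beta(a_F, b_F) =
Beta(9, 1) prior, background at the composition-matched null" against "all
participating sequences at the null". The LLR is reported in nats. A
Bernoulli(ρ = 0.02) inclusion prior penalizes each pattern column by
ln(ρ/(1−ρ)) ≈ −3.89 nats, and a position is only accepted while its residue
set is carried by a weighted majority of the foreground (conservation, not
mere divergence). Gaps and unknown residues (`X`) always count as
non-matches. Sequences are down-weighted for redundancy with position-based
(Henikoff) weights after fragments and >98%-identity duplicates are purged.

The sampler alternates sweeps that (1) reassign each non-seed sequence to a
subgroup row — by exact conditional argmax in `greedy` mode, or with
probability ∝ exp(score/T) under a geometrically annealed temperature in
`sample` mode — and (2) resample every category's pattern columns and
residue sets. It returns the best state visited, per-sweep trace, and
predictive membership probabilities (softmax of per-row scores).

## Worked example

Everything below is reproducible: the synthetic module generates a
benchmark alignment with known truth (3 subgroups × 100 sequences over 200
columns, 10 planted pattern columns per category at foreground conservation
0.9 versus background 0.1, plus 30 random-composition decoys).

```r
library(bpps)

gen <- generateSynthetic(syntheticSpec(rngSeed = 1))   # standard benchmark
msa <- computeWeights(gen$msa)
fit <- runSampler(msa, gen$hyperpartition, gen$seeds,
                  config = SamplerConfig(rngSeed = 1))
fitState(fit)
#> SamplerState at sweep 16: log posterior 2551.614
#>   Rejected         32 sequences
#>   SG1              99 sequences
#>   SG2              99 sequences
#>   SG3              100 sequences
#>   pattern positions: C1=10, C2=10, C3=10
```

All 30 decoys land in `Rejected` (two borderline real sequences join them),
every planted pattern column is recovered, and no spurious column is added
(assignment accuracy 98.4% on non-seed sequences). A contrast alignment for one category (here from a
smaller 3 × 40 fixture) prints the seed sequences, the foreground pattern
with its weighted residue frequencies in integer tenths (`9` = 90–100%),
the background counterparts (`bg|` lines), and a constraint histogram:

```
category C1: 6 pattern positions (5 displayed)
histogram:        ....*..6..8..8..9...........................................
SG1_seq001        DQRKAACCLQDIVFWAFFPCYCWWCEDEPHKPPSRLDRIQQMEWGSCLVVIYGCRCDHNF
SG1_seq002        GCCFAQMCMEDYIIFPFVIYCNQKVTTGNMVWMITASKRYLRGAWVQQGSSEQLYTRLQW
SG1_seq003        EAVVAHKCTLDIWFWCFIMLDMDDYAPVLDDYCWRFCDNQHLERHDEAVGKHTEHYNISI
pattern:          ....A..C..D..F..F...........................................
wt_res_freqs:     ....9..7..9..9..8...........................................
bg|pattern:       ....M..M..D..C..D...........................................
bg|wt_res_freqs:  ....0..0..1..0..0...........................................
```

So at column 5 the foreground conserves `A` in 90–100% of (weighted)
sequences while the background's most common residue `M` sits at 0–10%. The
pattern-information report carries the quantitative per-position strengths
(nats of posterior log-likelihood ratio), e.g.

```
category  column  ref             residue_set  nats     fg_freq  bg_freq
C1        11      D11^SG1_seq001  D            117.22   0.888    0.050
C1        14      F14^SG1_seq001  EF           116.06   0.919    0.071
```

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/bpps.R simulate --out-dir fix --seed 5
Rscript inst/scripts/bpps.R run --alignment fix/alignment.fasta \
    --hyperpartition fix/hyperpartition.tsv --seeds-dir fix/seeds \
    --out-dir out --seed 2
Rscript inst/scripts/bpps.R tree2hp --newick tree.nwk --out hp.tsv
```

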