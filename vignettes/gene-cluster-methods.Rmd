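---
title: "Consolidating allopolyploid transcriptome contigs into gene clusters"
author: "homeoclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating allopolyploid transcriptome contigs into gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoclust)
```

## The problem

An allohexaploid plant carries three diploid subgenomes, so a typical gene
is present as three *homeologs* — copies that are nearly identical to each
other and clearly distinct from paralogous gene families. A de novo
transcriptome assembly of such a species therefore over-counts genes
roughly threefold, and fragments each transcript further into full-length,
5'-biased and 3'-biased contigs depending on library construction. Before
any downstream census (transcription-factor families, pathway enzymes,
ortholog selection for phylogenetics) the contig set has to be consolidated
back to something gene-like.

homeoclust implements that consolidation as a two-condition rule. A **gene
cluster** is a set of contigs that

1. share the same reference-proteome **top-hit** (best translated-search
   hit at E-value strictly below $10^{-5}$), and
2. are mutually connected by **homology edges**: a pairwise translated
   comparison (longest ORF of one contig against the six-frame translation
   of the other, better orientation kept) at E-value strictly below
   $10^{-100}$.

"Connected to at least one other member" is a self-referential phrasing;
we formalize it as connected components of the edge graph within each
top-hit bin (single linkage). Contigs with a top-hit but no qualifying
edge are singleton clusters; contigs without a top-hit stay unclustered
and are reported separately. One contig per cluster — the member with the
lowest top-hit E-value — acts as the cluster representative for
phylogenetics and ortholog tables.

## Alignment model and statistics

All pairwise comparisons are Smith–Waterman local alignments with affine
gap penalties (gap of length $k$ costs $q + rk$; default BLOSUM62 with
$q = 11$, $r = 1$). Raw scores $S$ are converted to bit scores and
E-values with the Karlin–Altschul formulas

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'},$$

with the published gapped parameters for this scheme,
$\lambda = 0.267$, $K = 0.041$. The search space $m \times n$ is the
query length times the total database residue count (translated-query
search) or the query ORF length times the subject length in codons
(contig-pair mode); no finite-size edge correction is applied, which is
second-order at the E-value ranges that matter here. `X` scores zero
against everything; subjects are split at stop codons so `*` never enters
an alignment. All cutoffs stated with "<" are strict; the
ortholog-candidate rule keeps assignments with $E < 10^{-5}$, bit score
$> 150$ and query coverage $\ge 20\%$, each boundary honored exactly.

Two implementation details matter for reproducibility:

* **Determinism.** The DP reports the optimal alignment with the smallest
  end coordinates, traceback preferring substitutions over gaps; top-hit
  ties are broken by bit score, then subject id.
* **Seeded prescreen.** By default a subject is aligned only if it shares
  at least one exact 5-mer with the query. Every reported hit carries its
  exact full-DP score — the prescreen can only omit alignments whose
  score would have been discarded anyway at the cutoffs used (a chance
  5-mer is ~200× more likely than a chance hit at $E < 10^{-5}$). Set
  `seed_filter = FALSE` to force full DP everywhere; the test suite
  cross-checks both paths against an independent reference DP.

## ORF extraction

ESTs are frequently truncated at either end, so an ORF is defined
stop-to-stop: the longest stretch without a stop codon across all six
frames, sequence ends counting as stops and no start codon required.
Requiring ATG would discard valid homeolog fragments. The default minimum
of 30 aa only prunes noise — far shorter than anything that could reach
the edge threshold. Ties on length are broken by peptide string first,
then frame order $+1,+2,+3,-1,-2,-3$, then 5'-most position; putting the
peptide key first makes the result exactly invariant under reverse
complementation of the contig, which frame order alone is not. Codons
containing `N` translate to the encoded residue when all IUPAC expansions
agree, otherwise to `X`.

## Read cleanup

The trimming stage mirrors the upstream EST protocol: adapter removal
(the two library PCR primers ship as the default set), 5' poly-T and 3'
poly-A removal, then a length filter in which a read of exactly 40 bases
passes ("less than 40" is read literally). An adapter occurrence is
terminal — and trimmed together with everything outward of it — when it
lies within one adapter length of its *nearer* end; classifying by the
nearer end prevents a 3'-terminal occurrence on a short read from being
consumed by the 5' rule. Poly-tails are maximal terminal runs allowing
isolated interruptions (default: one non-matching base, never two in a
row, minimum run 10); interrupted tails are our generalization, kept
conservative and configurable, since the upstream protocol does not state
one.

## The synthetic allohexaploid generator

Because the original raw data and assembler are out of scope, validation
runs on a simulator whose defaults encode the study regime:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 200 | genes in the transcriptome |
| `n_subgenomes` | 3 | homeologous copies per gene |
| `homeolog_divergence` | 0.03 | substitutions/site per homeolog branch |
| `family_divergence` | 0.5 | substitutions/site per gene branch from a paralog-family root |
| `reference_divergence` | 0.15 | divergence to the reference proteome |
| `fragment_profile` | 0.5 / 0.25 / 0.25 | full-length, 5', 3' contigs |
| `missing_homeolog_prob` | 0.1 | homeolog dropout |
| `indel_rate` | 0.001 | whole-codon indels per site |
| `cds_length_range` | 150–500 aa | CDS length, uniform |

Substitutions follow Jukes–Cantor, giving the closed-form calibration
$\mathbb{E}[\text{identity}] = 1 - 0.75\,(1 - e^{-8d/3})$ for two
sequences each $d$ from their ancestor; the suite checks the simulator
against this formula. Substitutions that would create an in-frame stop are
repaired by re-assigning one mutated site to a different non-ancestral,
non-stop base, which preserves the number of differing sites and hence the
calibration. Genes are generated in paralog pairs (about 45% mutual
nucleotide identity at the default family divergence), each with exactly
one reference protein derived from the gene's ancestral CDS, so every
contig has a single correct top-hit target. Fragments cover a uniform
40–90% of the CDS from their end; short (20–60 nt) undiverged UTRs pad the
transcripts. Indels are whole codons, keeping frame so the longest-ORF
stage behaves as in real coding sequence.

What the simulator deliberately does **not** model: sequencing-error
profiles (homopolymer miscalls), chimeric contigs, expression levels,
alternative splicing, and real codon usage. Passing the recovery tests
therefore demonstrates that the clustering logic is correct under the
stated divergence regime — not that any particular biological dataset
will reach the same accuracy.

## What the thresholds imply for recovery

The edge threshold is deliberately stringent, and its consequences follow
directly from the Karlin–Altschul statistics rather than from any
implementation choice: with $\lambda = 0.267$, $K = 0.041$ and search
space $m \cdot n \approx L^2$, even a *perfect* match of length $L$ has

$$E \approx L^2\, 2^{-(0.267 \cdot 5.3 L + 3.19)/\ln 2},$$

which crosses $10^{-100}$ only near $L \approx 180$ aa. Contigs whose
alignable overlap is shorter — genes below ~180 aa, and fragment pairs
with modest overlap — cannot form edges even at 100% identity and remain
singleton clusters. Under the default generator regime this makes the
procedure conservative: cross-gene merges essentially never happen
(pairwise precision 1.0 in our runs), while a substantial minority of
short genes and fragments stay split, inflating the cluster count above
the true gene number. The idealized limit in which every gene collapses
to exactly one cluster holds only when all CDS lengths clear the ~180 aa
bound. `scripts/acceptance.R` reports both regimes so the behavior is
visible rather than hidden.

## Neighbor-joining stage

Protein alignments are consumed, not produced (any multiple aligner can
supply them). Distances default to p-distance with pairwise deletion of
gap columns — the simplest defensible choice when no model is stated —
and the agglomeration is standard Saitou–Nei: join the pair minimizing
the Q-criterion, ties to the lowest index pair, the usual branch-length
and reduction formulas. A negative branch length is clamped to zero with
the deficit moved to its sibling so the joined path length is preserved.
The implementation is exact on additive matrices (recovering generating
topology and branch lengths to $10^{-9}$) and is cross-checked against an
independent NJ implementation in the test suite. Bootstrap support
resamples alignment columns with replacement, rebuilds each replicate
tree, and reports for each internal bipartition of the full-data tree the
integer percentage of replicates containing it; 1000 replicates is the
conventional default.

## Validation problem sizes

The shipped tests validate the aligner against an independent reference
DP on 1000+ random peptide pairs, consolidation against brute-force
transitive closure on 500+ random instances, ORF extraction against
window enumeration on 1000 random sequences, and NJ on 100 random
additive 8-taxon matrices. End-to-end recovery runs use 200-gene
transcriptomes (~550 contigs) across five seeds, and the idealized
hexaploid limit uses 100 genes — sizes at which every property above is
exercised while a full run stays around a minute on one CPU.

## Command line

`inst/scripts/homeoclust.R` exposes the stages as subcommands (`trim`,
`orfs`, `search`, `cluster`, `census`, `simulate`, `evaluate`, `nj`,
`run`) for shell pipelines; each is a thin wrapper over the exported
functions documented here.
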