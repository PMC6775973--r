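---
title: "Methods and design of the cobascan pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the cobascan pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cobascan reconstructs, as tested and reusable code, the computational chain
used to characterize short-DTR marine podoviruses ("cobavirus-like" phages):
genome terminus detection and reorientation, identity-filtered metagenomic
read recruitment with presence and abundance statistics, protein-family
clustering, rho-independent terminator scanning, and genome-similarity
clustering. This vignette explains each model, its parameters and defaults,
the numerical choices, and what the synthetic-data tests do and do not show
about real data.

## The synthetic community defines the study conditions

All testing runs on simulated phage communities with planted ground truth.
`simulate_genome()` emits a linear genome with the hallmark architecture of
this phage group, with defaults chosen to match it:

* **length 40,000 bp, G+C 0.47** — typical of the ~40 kb, ~47% G+C genomes
  the pipeline targets;
* **a direct terminal repeat (DTR) of 170 bp** (the group's DTRs span
  159–173 bp), whose first 30 bp are drawn at G+C + 0.15 (capped at 0.9) to
  emulate the conserved G+C-rich 5' region of these DTRs;
* **a bidirectional rho-independent terminator at `terminator_offset`
  (default 0.5)** separating the two divergently transcribed genome arms:
  a 12 bp all-G/C stem, 4 bp loop, and 6 bp A- and T-tracts flanking the
  hairpin. The tract geometry is the biological one: the plus strand reads
  hairpin-then-T-tract, and the reverse complement of the upstream A-tract
  supplies the T-tract of the minus strand, so *each strand* sees a
  terminator in its own reading direction.

The read simulator uses the simplest error model whose statistics are
analytically checkable: substitutions i.i.d. and uniform over the three
alternative bases, single-base indels with equiprobable insertion/deletion,
uniform start positions on the linear genome, about half the reads
reverse-complemented, constant Q37 qualities (with an optional linear 3'
quality decay for exercising the read cleaner). Expected read identity is
therefore `1 - subst_rate` up to binomial noise, which the tests exploit.
Communities allocate reads to members multinomially with the requested
weights; the truth table records planted aligned bases and the implied
per-Gb abundance. Every generator takes one seed and is bit-reproducible.

What this does **not** emulate: platform-specific error profiles, GC bias in
coverage, chimeras, real intergenomic mosaicism, or gene content. Passing
tests therefore demonstrate the correctness of the statistics and algorithms
under controlled conditions, not end-to-end performance on real libraries.

## Genome termini

`find_terminal_repeat()` compares the length-L prefix with the length-L
suffix for every candidate L (default search up to a quarter of the genome:
terminal repeats of linear phages are short relative to the genome) and
reports the longest candidate whose mismatch fraction is at most 2%.
The comparison is end-anchored and substitutions-only: DTR copies arise by
replication of identical ends, and permitting indels would inflate false
repeats on repetitive sequence. Among candidates the *longest* wins
(determinism); an `"inverted"` mode compares the prefix with the
reverse-complemented suffix as a mis-assembly diagnostic — it is reported but
never used for reorientation, because inverted repeats away from the exact
ends are assembly artifacts rather than replication signals. One behaviour
worth knowing: for *inverted* repeats the comparison is cumulative in L, so
under a nonzero mismatch tolerance a detected inverted repeat can
over-extend by a few bases into flanking sequence; the direct-repeat scan
does not share this property because extension shifts the alignment frame.

`locate_dtr_by_reference()` finds a known DTR inside another genome by
k-mer seeding (k = 12, permissive because related phages carry DTRs at
70–100% nucleotide identity) followed by semi-global alignment of the whole
reference against a windowed target region. `reorient_to_dtr()` then treats
the genome as a circular permutation: a detected 3' terminal-repeat copy is
collapsed, the circle is rotated so the DTR hit starts at position zero, and
the leading repeat copy is re-appended at the 3' end. Rotation and
reorientation are exact bijections on the circular form; if a hit covers
only a clipped repeat copy (a rotation that split the repeat across the
junction), the circular sequence is still recovered exactly while the
re-appended linear copy is correspondingly clipped.

`termini_from_alignments()` implements the read-structure criterion as a
start-pileup test: on a linear molecule every read overhanging an end maps
starting exactly at it, so alignment starts accumulate there, whereas a
circularly permuted library has uniform starts. Positions are flagged at
z ≥ 6 against the uniform null (mean N/L), merged within 5 bp. The z-score
rule is this package's own operationalization of that idea; it is
deliberately conservative and requires ≥ 100 alignments.

## Read recruitment

Cleaning follows the standard rule set: trim bases below Q20 from both read
ends, then drop reads with mean quality < 20 or length < 30. The built-in
aligner is a seed-and-extend mapper sufficient for the package's scale:
exact 15-mer seeds on both strands, candidate diagonals ranked by seed
support, banded semi-global extension (window slack 16 bp, match +1,
mismatch −2, gap −3, linear gaps — adequate because the simulator plants
single-base indels), one primary alignment per read with deterministic
tie-breaking (best score, then lexicographic genome id, then leftmost
position, then plus strand). SAM input from an external mapper can be
substituted; identity is reconstructed from the NM tag
(`mismatches = NM − insertions − deletions`), and the test suite asserts
that both routes produce identical alignment records for the same
alignment.

The statistics are:

* **identity** = matches / (matches + mismatches + insertions + deletions),
  indel columns counted (conservative, like common mappers); the ≥ 90%
  filter is inclusive;
* **breadth** = fraction of genome positions covered by ≥ 1 passing read;
* **presence** ⇔ breadth ≥ 75% (inclusive) at ≥ 90% identity;
* **relative abundance per Gb** = aligned bases / genome length /
  (library size / 10⁹). "Aligned bases" counts *reference* bases covered
  with multiplicity (the coverage-style reading), and "library size" is the
  total bases *after* cleaning — the denominator consistent with what was
  actually mapped. A percent-of-library column is also emitted, since both
  normalizations are used in enrichment profiling and the choice between
  them is not recoverable from the figure legends they feed.

Raising the identity cutoff can only discard alignments, so breadth and
abundance are monotone non-increasing in the cutoff; the acceptance suite
asserts this over randomized samples, alongside exact recovery of planted
abundances (within 10%) at ≥ 20× depth and ≤ 2% error.

## Protein clustering

All-versus-all Smith–Waterman (BLOSUM62, gap open 11 / extend 1, via
Biostrings) feeds BLAST-like statistics computed with the standard gapped
Karlin–Altschul constants λ = 0.267, K = 0.041 over the raw m×n search
space; the effective-length adjustment is deliberately omitted for
transparency, since only threshold crossings immediately at the cutoffs are
affected and both cutoffs are configurable. Edges pass with
e-value ≤ 10⁻⁵ **and** bitscore ≥ 50; isolated proteins remain as
singletons.

Markov clustering is implemented in the package (it is part of the
contribution, not delegated): self-loops with weight equal to each node's
maximum incident weight, column-stochastic normalization, then alternating
expansion (matrix squaring) and inflation (elementwise power 2.0 — the
canonical "-I 2" granularity) with renormalization, pruning entries below
10⁻¹², until the maximum elementwise change falls below 10⁻⁶ (cap 100
iterations; non-convergence returns the current state with a warning flag).
Clusters are read off attractor-wise: rows with positive diagonal attract
their positive-mass columns, and overlapping attractor systems merge.
Self-hits are handled entirely inside this step, so the edge list needs no
self-edges. Expansion and inflation cannot create probability flow between
disconnected components, so clusters never span components — asserted as a
property over random graphs against an independent connected-components
oracle.

## Terminator scanning

The hairpin scanner enumerates stems of 4–20 bp (G:T wobble pairs allowed,
at most one mismatch) around loops of 4–12 bp on both strands and scores
them with a transparent stability model: −3.3 kcal/mol per G:C pair, −2.0
per A:T or G:T pair, +4.0 loop initiation, +1.0 per loop base beyond 4,
+3.0 per stem mismatch. A call requires |ΔG| ≥ 10.5 kcal/mol and a run of
≥ 3 T's starting within 8 bp downstream of the stem on the call's strand;
overlapping same-strand calls reduce to the most stable one. The T-tract is
checked per candidate stem length rather than only for the most stable stem
at an anchor, because flanking A/T tracts base-pair with each other and a
maximally extended stem can bury its own poly-U signal.
`pair_bidirectional()` merges opposite-strand calls whose hairpins overlap
or lie within 60 bp into one bidirectional call at the midpoint — the
configuration expected between divergently transcribed genome arms.

Two honest caveats. First, the ΔG model is this package's own surrogate
with the conventional 10.5 kcal/mol magnitude threshold applied to *its*
scores; it is not a reconstruction of thermodynamic folding tools, whose
internals are not reproducible here, and all stacking parameters are
exposed as arguments. Second, under this surrogate the threshold is
permissive on random DNA: dinucleotide-shuffled 10 kb controls average
roughly 20 chance calls per genome (and several chance bidirectional
pairs). The scanner is therefore reliable for *locating and scoring* a
known terminator architecture (planted cassettes are recovered within
±5 bp in ≥ 95 of 100 genomes) but is not, at these defaults, a selective
de-novo screen; the test suite records this openly rather than tuning the
planted conditions around it.

## Genome distance and clustering

Contigs shorter than 34 kb (~85% of a complete genome of this group) are
discarded as incomplete; the boundary is inclusive by the strict reading of
"smaller than". `fragment_identity()` is a fragment-ANI: each genome is
tiled into non-overlapping 1,020 bp fragments, each fragment is aligned to
the other genome (both strands, same seed-and-extend machinery), fragments
are counted as aligned at ≥ 30% identity, and the mean identity of aligned
fragments is symmetrized by averaging both directions. This is a declared
surrogate for genome-BLAST distance formulas, which are not reproduced
here; it recovers planted substitution divergence r as identity 1 − r to
within ±0.1 percentage points for r ≤ 5%.

`f_link_cluster()` performs OPTSIL-style threshold clustering: starting
from singletons, the pair of clusters with the highest *link fraction* —
the fraction of inter-cluster distances at or below the threshold — is
merged while that fraction is at least F (default 0.5). Ties are broken
first by the smallest maximum inter-cluster distance, then by
lexicographically smallest member ids. The distance-based tie-break is a
deliberate design choice: with it, F = 1 coincides *exactly* with a
complete-linkage cut at the threshold (complete linkage is monotone, so all
sub-threshold merges precede the rest in height order), and F → 0
approaches single linkage (connected components of the threshold graph).
A purely lexicographic tie-break would not guarantee the complete-linkage
equivalence. Both equivalences are asserted against `hclust` oracles on
random matrices. The species-level distance threshold (default 0.05) is a
configuration value, not a calibrated constant: the canonical thresholds
for the original distance formulas do not transfer to the fragment-ANI
surrogate.

## Problem sizes and numerical notes

The test and acceptance workloads are sized for quick, deterministic runs
while keeping every statistic in its asymptotic regime: communities of two
40 kb-scale genomes at 30× depth (~8,000 reads of 150 bp), 100-seed
repeat-recovery and terminator panels on 10 kb genomes, 20-sample
monotonicity sweeps on 3 kb genomes, and 100 random 8-genome matrices for
the clustering oracles. Internal coordinates are 0-based half-open
throughout, converted at the SAM (1-based) and GFF3 (1-based inclusive)
boundaries only. All randomness flows through per-call seeds; re-running
any generator or the command-line interface with the same configuration
reproduces outputs byte-identically.
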