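---
title: "Screening S-RNase candidates: models, parameters and design choices"
author: "SRNaseScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening S-RNase candidates: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science behind each stage of the package, the
tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical conventions. It is
the package's record of design decisions that were genuinely open.

# The screen

S-RNases — the pistil determinant of gametophytic self-incompatibility
(GSI) in several eudicot families — sit inside the large T2 ribonuclease
family and are recognized by a conjunction of weak signals rather than
any single one. The pipeline evaluates seven criteria per candidate:
class III membership, non-membership in a low-polymorphic subcluster
(LPSC), basic isoelectric point, two intact CAS histidines, a single
intron in the hypervariable (HV) region, pistil-specific expression, and
an S-haplotype-like inheritance pattern in reciprocal semi-compatible
crosses. A gene is designated only when all seven hold.

## Sequence stage

`longestOrf()` scans all six frames for the longest stop-free run of
codons. `requireStart` defaults to `FALSE` because assembled transcripts
are frequently 5'-truncated; `minAa` defaults to 200 residues, the
cutoff separating plausible T2 RNases (~230 aa, ~25 kDa) from fragments.
`greedyCluster()` collapses redundancy CD-HIT-style: length-sorted
greedy assignment to the first representative at global-alignment
identity ≥ 0.95. Identity is defined explicitly as matches over
alignment columns excluding terminal-gap runs, which makes the
clustering deterministic and testable; similarity is computed at the
protein level (the nucleotide/protein choice is configurable since
either convention exists in practice).

Pairwise and progressive alignment use one Needleman–Wunsch engine
(compiled) with linear gap penalty (match 1, mismatch 0, gap −1) and a
fixed traceback preference (diagonal, then gap in the second sequence).
The progressive stage merges profiles in the order of a neighbor-joining
guide tree built on pairwise p-distances. No installed package provides
profile–profile progressive alignment, and a single engine keeps the
pairwise and multiple stages mutually consistent; for real data a
user-supplied alignment (e.g. from MAFFT) can be read with `readFasta()`
and used directly — every downstream function accepts any equal-width
alignment.

## Classification and LPSC detection

Classes are assigned by nearest labelled reference under p-distance
(`pairwise_deletion` gap policy, the common default for p-distances;
`complete_deletion` is available). The maximum-likelihood/bootstrap tree
of a full phylogenetic analysis is deliberately replaced by
neighbor-joining plus nearest-reference labelling: the screen needs
class membership and subcluster structure, not branch support. Every
report header records this substitution. The `unclassified` floor
defaults to nearest-reference identity 0.30 — far below within-class
identities (~0.7+ at the generator defaults) and above random-protein
identity (~0.05–0.1).

LPSCs are found by single-linkage grouping at pairwise identity ≥ 0.85
(groups of ≥ 3 whose mean pairwise identity also reaches the floor).
The 0.85 floor is calibrated to sit below observed subcluster
identities (~0.89–0.97) and above typical S-allele identities
(~0.60–0.80); it is exposed in `runConfig()`. LPSC members are
near-identical paralogs — too invariant to encode S specificity — and
are excluded from candidacy regardless of their other features.

## Protein features

`netCharge()` is the Henderson–Hasselbalch sum over ionizable groups;
`isoelectricPoint()` finds its unique zero by bisection on pH ∈ [0, 14]
(200-iteration cap, tolerance 1e-4 pH). The default pKa set is the
EMBOSS convention (N-terminus 8.6, C-terminus 3.6, C 8.5, D 3.9, E 4.1,
H 6.5, K 10.8, R 12.5, Y 10.1), with cysteine ionizable. Published
class-wise pI averages depend on the (unpublished) constants of the
calculator that produced them, so the table is pluggable and its name is
recorded in every feature table; the package's claims about pI are
*ordinal* (class III basic, classes I/II acidic), which is robust to the
constant set. Molecular weight is the sum of average residue masses plus
one water. The `basicPiCutoff` for designation defaults to pH 7.0
(neutrality) — planted class III proteins sit near pI 11, classes I/II
near 4, so the call is insensitive to the exact cutoff over a wide
range.

## Gene structure

`inferGeneStructure()` performs exact spliced mapping: it finds the exon
chain whose concatenation reproduces the CDS byte-for-byte, minimizing
intron count, then preferring GT..AG introns, then leftmost donors; any
tie that survives all three rules is an error, never a silent choice.
Exactness (no mismatches) is appropriate because inputs are
Sanger-verified clones or synthetic sequences; a mismatch-tolerant mode
is out of scope. The dynamic program costs one large unit per intron
plus a small penalty per non-canonical splice pair, so canonical
solutions dominate at equal intron count. Intron position is assigned to
the codon containing the donor-site CDS coordinate, and phase (0/1/2) is
reported. Intron lengths are annotated against a plausible range
(default 50–2000 bp) and against the 87–374 bp band observed for citrus
class III T2 RNase introns — an annotation, not a filter. HV windows are
configuration data on alignment columns (`hvWindows()`): their real
boundaries are figure-level annotations in the literature, not printed
numbers, so they are inputs; the synthetic pipeline places its window at
30–45% of the reference protein, between the two CAS segments.

Exon coordinates live in `IRanges` (1-based inclusive), the interval
container of this ecosystem, and GFF3 output follows the same
convention, which avoids maintaining a second internal coordinate
system.

## Inheritance

`gsiCross()` draws one maternal allele uniformly and one paternal allele
uniformly from the father's alleles compatible with the mother's pistil
(an allele matching either maternal allele is rejected; the dominant
self-fertility allele `Sf` is always compatible — its pistil-side
behaviour is modelled as a normal rejecting allele, since only the
pollen-side dominance is established). A fully incompatible cross is an
error. The class validity of every progeny table re-asserts the
rejection rule, so no simulated table can violate it.

`segregationTest()` is the Pearson chi-square against 1:1 or 3:1 with
df = 1 and *no* continuity correction — the uncorrected statistic is the
one that reproduces published segregation P values exactly (verified in
the acceptance tests); Yates correction is available behind a flag.
`classifyMarker()` maps reciprocal segregation records to roles with
"fits ratio" meaning P ≥ α, α = 0.05: all-present in both crosses →
`homozygous_non_S`; all-present only when the carrying parent is the
pollen donor, 1:1 otherwise, unique to that parent → `unique_S(parent)`;
1:1 in both, carried by both, and complementary (`sameLocusTest()`) with
a `unique_S` marker → `shared_S`; 3:1 in both → `unlinked_het_both`;
1:1 in both, one parent → `unlinked_het_one`; otherwise `inconclusive`.
With recombination fraction r = 0 the classifier cannot distinguish
S-locus identity from tight linkage — a genuine limit of segregation
data.

### The sampling-noise ceiling on recovery rates

Because "fits" is a significance test at α = 0.05 applied to counts
drawn at the *true* ratio, each stochastic gate passes with probability
≈ 0.95, not 1. At the default scenario sizes (n = 81 and 95) the exact
pass probabilities are 0.9552 and 0.9604 for 1:1 and 0.9462 and 0.9568
for 3:1 (binomial mass where the Pearson P ≥ 0.05). The five-role
recovery per simulated dataset is their product over the four
independent draws, 0.830, and the three-S-gene designation gate is
0.917. These ceilings are properties of the decision rules and sample
sizes, not of the implementation; the acceptance script reports the
empirical rates (≈ 0.83–0.92), and no parameter was adjusted to raise
them. Larger populations or a lower α would raise the ceiling; both are
exposed (`nForward`/`nReciprocal`, `alpha`) and both defaults follow the
emulated study design.

## Expression

`tissueSpecificity()` classifies detection profiles over a fixed
ten-tissue vocabulary; any non-pistil detection (notably anther/pollen)
disqualifies pistil specificity. Detection in every tissue is
`ubiquitous`; detection only outside the pistil is also reported as
`ubiquitous` (generic expression), keeping the four-label vocabulary
closed. `ddct()` is the Livak 2^−ΔΔCt formula with replicate standard
errors propagated in quadrature. `simpleDeTest()` is a
permutation test on the difference of group means of log2
median-of-ratios-normalized counts — deliberately labelled
NON-equivalent to a negative-binomial model (that stage of a real
analysis is out of scope here). With 3 vs 3 samples the exact
enumeration has 20 label assignments, so the smallest achievable
two-sided permutation P is 2/20 = 0.1 and BH q values cannot fall below
0.1 at that design; the planted down-regulated gene is therefore
identified by rank (smallest q, direction down), which the tests verify
in ≥ 95% of simulations. FDR control defaults to 0.05, the one threshold
the emulated analysis fixes.

# The synthetic-data generators

`genFamily()` emulates the structure the screen relies on: one root,
three class ancestors at per-site substitution rate 0.5 from the root,
members at rate 0.15 from their ancestor (substitution always changes
the residue, no indels — keeping p-distances analytically predictable:
expected member–member p ≈ 2d(1−d)), class III substitutions biased 60%
toward K/R/H (classes I/II toward D/E) so the class-wise pI ordering
holds, two preserved CAS histidine positions (knockouts available), and
an LPSC regenerated from a founder at per-branch rate (1−0.95)/2.
Protein length defaults to 230 aa (~25 kDa). What it does *not* emulate:
indels and alignment ambiguity, rate heterogeneity across sites,
recombination between paralogs, and assembly artifacts. Passing tests
therefore show the pipeline's logic is correct under clean conditions,
not that it is robust to real assembly noise.

`plantGene()` builds genomic sequences as flank + exons interleaved with
introns carrying requested splice dinucleotides. Intron interiors and
flanks are drawn from A/C/T only: with no G outside the planted
junctions, no spurious GT donor or AG acceptor can arise, making the
planted chain the unique optimal spliced mapping — the generator is
exactly invertible by `inferGeneStructure()`, which the tests exploit
(1,000 random plant-then-recover cases). Real introns are AT-rich, but
the G-free convention is a determinism guarantee, not a biological
claim. One interior base per side is additionally forced to mismatch the
CDS continuation, and the rare boundary offsets where the splice
dinucleotides themselves spell the adjacent CDS bases (so the sequence
would admit a fewer-intron reading than the planted truth) are rejected
with an error rather than emitted with a wrong truth record.

`genCrossDataset()` simulates both directions of the default scenario —
mother `S1Sx` × father `S1Sy`, five markers (three S-linked at r = 0,
one unlinked hemizygous in both parents, one unlinked homozygous in the
mother), n = 81/95 progeny — with optional symmetric miscall noise.
`genCounts()` produces negative-binomial counts (dispersion 0.1,
log-normal baselines and library sizes, 3 vs 3) with planted fold
changes; `genTissuePanel()` emits detection matrices that classify back
to their truth labels by construction.

# Numerical conventions and degenerate inputs

* Alignment tie-breaks: diagonal over gap-in-second over gap-in-first;
  empty-vs-empty alignments are empty; identity over zero comparable
  columns is `NA`.
* p-distance over zero compared sites is an error ("no overlap"), not 0.
* Neighbor joining clamps negative branch-length estimates to zero and
  counts them in the `clamped` attribute; additive inputs are recovered
  to 1e-9.
* Bisection for pI always brackets [0, 14]; with termini included a root
  always exists, and `includeTermini = FALSE` on a non-ionizable peptide
  is an error ("pI undefined").
* Spliced mapping caps optimal-chain enumeration (64) and errors on any
  ambiguity surviving the tie-breaks, listing the candidate chains.
* Every generator is seeded explicitly, never touches the caller's RNG
  state, and is a deterministic function of (arguments, seed).
* Report files begin with `# seed=` and `# config_md5=` headers plus the
  NJ-for-ML substitution notice.

# Problem sizes used by the test suite

The suite runs the oracle-equivalence checks at deliberately small sizes
where exhaustive enumeration is feasible (alignments ≤ 8 residues,
trees ≤ 10 taxa, 120 random transcripts for the ORF scan, 50 peptides
for the pI grid scan), 1,000 plant-then-recover gene models, 100
simulated reciprocal-cross datasets for role recovery, and 100 full
synthetic screens end-to-end. These sizes were chosen to exercise every
code path with tight determinism while keeping the default test run
fast on a single CPU.

# Known limitations

* Published sequence-dependent numbers (subcluster identities
  91.4/96.7/89.4%, class pI averages, the 46.2% overall identity) need
  the underlying sequences and the original calculator's constants, and
  are not reproducible desk-side; the package substitutes property-based
  checks (planted-truth recovery, analytic identity targets).
* The DE stage is a permutation test, not a dispersion-modelling count
  model; at 3 vs 3 its P values are floor-limited (see above).
* The classifier's recovery rate is ceiling-limited by its α-level gates
  (see above); this is a property of the decision rules, reported, not
  hidden.
* Real HV window boundaries must be supplied by the user; the shipped
  window is synthetic.
* No mismatch-tolerant spliced mapping; no isoform handling (a CDS that
  cannot be reproduced exactly is reported as unmappable, the behaviour
  expected for assembly artifacts).
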