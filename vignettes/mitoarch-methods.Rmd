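---
title: "Methods: mitochondrial genome architecture, breakpoints, ancestral arrangements and truncated tRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial genome architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

`mitoarch` analyses the architecture of animal mitochondrial (mt) genomes:
the arithmetic of annotation tables, rearrangement of the circular 37-gene
order, parsimony reconstruction of ancestral arrangements, and the
secondary structure of truncated mt tRNAs.  It was developed around the
mite (Acari) system, where one superorder (Parasitiformes) largely retains
the ancestral arthropod gene arrangement and cloverleaf tRNAs while the
other (Acariformes) shows pervasive rearrangement and tRNA truncation; the
packaged fixtures are the annotation tables of two eriophyoid mites, the
least rearranged acariform mt genomes known.  This vignette records the
models, conventions and numerical choices, and what the shipped validation
does and does not establish.

## Annotation arithmetic

An annotation table is a set of records `(gene, class, strand, start, end,
anticodon)` over the 37-gene metazoan mt vocabulary plus one optional
control region (CR).  Coordinates are 1-based inclusive and no feature
spans the origin; genome circularity enters only through the
origin-wrapping intergenic pair.  Records are sorted by `(start, end,
name)` — an arbitrary but fixed tie-break for exactly overlapping starts —
regardless of source row order, because published tables sometimes print a
relocated gene (e.g. a tRNA moved into another neighbourhood) out of
coordinate order, and intergenic counts only reproduce when each count is
attributed to the pair *(coordinate predecessor, feature)*.

The gap between adjacent features is `downstream.start − upstream.end − 1`
(negative values are overlapping nucleotides); for the wrap pair the
downstream start is lifted by the genome length.  Because the sum
telescopes, `Σ feature lengths + Σ gaps = genome length` holds identically
for every valid table, and is asserted on all fixtures and simulated
genomes.  When the genome length is not declared it is inferred from the
wrap-around intergenic count of the first feature:
`max(end) + wrap_gap − (first.start − 1)`.  A supplied FASTA length takes
precedence; a conflict between declared lengths is an error, never silently
resolved.  Printed intergenic counts, when present, are all recomputed and
any disagreement is surfaced in the reports (`printed_gap_mismatches`),
not patched.  One known prose-vs-table discrepancy in the source material —
the count of protein-coding genes ending in TAA — is handled this way: the
pipeline reports its own tally from the stop-codon column (8 of 13 in each
fixture genome) and leaves the audit to the reader.

Start/stop codons are read from the genome sequence when one is given:
minority-strand genes are reverse-complemented first; a gene whose length
is not a multiple of 3 ends in a partial `T`/`TA` stop (completed to TAA by
polyadenylation after transcript cleavage), and in-frame internal stops
under the invertebrate mt code warn rather than fail, since annotation
boundary uncertainty of a few nucleotides is common.

## Gene orders and breakpoint distance

A gene order is a circular signed permutation read along the majority (J)
strand.  Equality is rotation-invariant and reflection-invariant (reading
the circle from the other strand is the same molecule).  The CR is carried
as an inert marker and excluded from every comparison: it is non-coding,
its boundaries are the least certain, and 37-gene comparisons are the
field's convention.

The rearrangement measure is the breakpoint count: the number of gene
adjacencies of a target order absent from a reference order.  Published
counting conventions differ, and the tool that produced the published
counts does not document its convention, so the package makes its own
explicit:

* **`unsigned-linear-cox1`** (default): linearize the circle at *cox1*,
  read in *cox1*'s transcriptional direction, drop the pair spanning the
  cut, and compare unordered gene-name pairs (orientations ignored) —
  *n − 1* adjacencies for an *n*-gene genome.  This convention exactly
  reproduces the published counts for the two eriophyoid fixtures (13 and
  16) and the zero of the ancestral-type soft-tick arrangement, which is
  the only published anchor available; it is validated against a
  brute-force adjacency enumerator on random small orders.
* **`signed-circular`**: all *n* circular adjacencies with relative
  orientation, identifying `(x, y)` with `(−y, −x)`.  Strand-reading
  invariant; yields different (usually larger) counts and is the
  representation used for ancestral-state characters, where orientation
  matters.

Reading the linearization in *cox1*'s own direction (reverse-complementing
first when *cox1* is annotated on the minority strand) makes the unsigned
distance invariant to reflection; without it the dropped cut pair would
depend on the strand the order was written from.

## Shared derived clusters (synapomorphy candidates)

Derived adjacencies — present in every target genome, absent from the
reference — are chained into maximal contiguous runs.  Chaining uses
*strict ordered-orientation* adjacencies with no reverse-complement
folding, so that a block that relocated *and* inverted chains as a single
run: under the folded convention an inverted block's internal adjacencies
are indistinguishable from the original and the run would dissolve.

Screening is run-level: a run is refuted as a synapomorphy candidate of
the targets if the run (or its reverse complement) occurs contiguously in
any screened genome.  Adjacency-level screening would be stricter but
wrong here: unrelated lineages genuinely share *internal* adjacencies of,
for example, an inverted rRNA block, while lacking the diagnostic flanks.
A consequence of maximal chaining is that two diagnostic clusters joined
by further shared derived adjacencies are reported as one long run; the
individual clusters remain recoverable as contiguous sub-runs
(`order_contains_run()`), and the cluster inventory beyond the anchored
ones is reported, not asserted.

## Ancestral arrangements by parsimony

Every observed signed-circular adjacency becomes an independent binary
presence/absence character over the taxa; ancestral states on a
user-supplied rooted tree (polytomies allowed) are computed by
minimum-change parsimony — implemented as unit-cost dynamic programming
over the two states, which is exact, equals two-pass Fitch on binary
trees, and is verified against exhaustive enumeration of all internal
assignments on small trees.  Per node the minimal-cost state set is
reported; a tie is *ambiguous* and stays ambiguous unless an outgroup is
flagged, in which case root ties (only) are broken towards the outgroup's
observed state.  Treating adjacencies as independent characters ignores
their correlation (a single inversion changes two adjacencies at once);
this is a documented simplification that biases change counts upwards but
leaves presence/absence reconstruction serviceable.

The adjacencies inferred present at a node are reassembled by treating
each signed adjacency as joining two gene extremities (head/tail) and
walking maximal unambiguous paths: an extremity touched by more than one
adjacency is a conflict (the gene is split out and flagged), an untouched
gene is unplaced, and a conflict-free set of *n* adjacencies closes the
unique circle.  On the packaged mite data this reproduces the expected
qualitative picture: a long conserved protein-coding backbone, an
`rrnS–trnV–rrnL` unit whose orientation the folded characters cannot
decide (both readings are surfaced, not adjudicated), and `trnQ`/`trnY`
unplaced because their positions vary across acariform lineages.

The packaged tree and the non-eriophyoid screen arrangements are
best-effort schematic transcriptions (marked as such in the fixture
headers): they honour the verbal descriptions of those lineages but are
not gene-by-gene records, so conclusions about taxa other than the two
fixture genomes and the ancestral-type arrangements are illustrative.

## tRNA folding and truncation classes

Acariform mt tRNAs are heavily truncated: the D-arm or T-arm (or both) is
replaced by a short loop.  The folder is template-constrained search, not
free-energy minimization: thermodynamic folding is unreliable at these
lengths and the published structures were curated by hand, so the package
formalizes the curation rules instead.  Defaults (all configurable via
`params`):

| parameter | default | meaning |
|---|---|---|
| acceptor stem | 7 pairs, ≤ 2 mismatches, 0–1 nt discriminator | terminal complementarity |
| anticodon loop | 7 nt, anticodon at loop positions 3–5 | fixed geometry |
| anticodon stem | 2–5 contiguous WC/GU pairs | ≥ 2 required, else fold failure |
| D-arm stem | 2–4 pairs | searched between acceptor 5′ side and AC stem |
| T-arm stem | 2–5 pairs | searched between AC stem and acceptor 3′ side |
| arm loop | 3–9 nt | closing loop of a candidate arm |
| scoring | +2 per pair, −1 per mismatch | reported, not used for presence |

An arm is *present* iff a strict contiguous stem-loop of at least 2 pairs
fits in its region; otherwise the region is a replacement loop.  Arm
mismatches are therefore recorded (acceptor stem) but never flip presence
— the binary stem test is the classification boundary, a deliberate,
explicit stand-in for the unstated criterion behind hand-curated figures,
calibrated on the generator rather than on those figures.  All
tie-breaking is deterministic: longest stem, then 5′-most, then shortest
loop; anticodon candidates rank by expected-anticodon match, closing-stem
length, centrality, then 5′ position.  Classification is then a pure
function of arm presence: cloverleaf, D-armless, T-armless, armless.
Inputs outside 40–100 nt are rejected (the fixture annotations span 47–67
nt).  Invariants asserted in tests: no base is ever paired twice, every
reported pair is Watson–Crick or GU, identical input gives identical
structure.

## Synthetic data: what it emulates and what it does not

The generators provide ground truth for every stage under a mandatory
seed (identical seed, identical output):

* `evolve_order()`/`simulate_scenario()` apply inversions, transpositions
  and inverse transpositions (default mix 0.4/0.4/0.2) with span lengths
  uniform on `[1, n−1]` to uniformly chosen circular positions, per edge
  of a tree.  Event counts per edge are the study dial; replaying the
  logged events reproduces every node order exactly.  Duplication–loss
  events and rate heterogeneity are deliberately out of scope.
* `generate_genome()` realizes an order as an annotated sequence: ATN
  starts, complete TAA (or requested partial T) stops, sense-codon
  bodies, tRNAs built to architecture, small non-negative spacers.  It
  does not emulate overlapping genes, nucleotide composition bias or
  sequencing error — so round-trip tests validate the arithmetic, not
  robustness to messy annotation.
* `generate_trna()` builds clean-margin structures (perfect designed
  stems, unpairable A/C replacement loops, 0–2 acceptor mismatches).
  Recovery of designed architectures is effectively perfect under these
  margins (the ≥ 95% acceptance bar is conservative); real tRNAs with
  marginal stems will classify less cleanly, and the graceful degradation
  as mismatch rates rise is reported by the simulation driver rather than
  asserted.

Validation problem sizes, chosen to exercise each property at small cost:
1,000 random order pairs (≤ 10 genes) against the brute-force breakpoint
oracle; exhaustive parsimony checks on trees of ≤ 6 leaves; root-recovery
sweeps on an 8-leaf tree at 0–10 events per edge with a handful of
replicates per rate; 1,000 generated tRNAs for classification recovery;
100 replicates per event count for the distance-monotonicity property.

## Known limitations

* The breakpoint convention is validated against three published anchor
  values only; other published rows depend on arrangements this package
  ships only as schematic transcriptions.
* Adjacency characters are treated as independent in the parsimony step.
* The folder reports one structure per sequence; it does not enumerate
  co-optimal folds (ties are broken deterministically instead).
* Genome-level tRNA claims for the two fixture species (e.g. how many of
  the 22 are truncated) require the deposited nucleotide sequences, which
  are not shipped; the folder is exercised on generated sequences, and
  `fold_trna_set()` accepts user-downloaded FASTA for the real thing.
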