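# mitoarch

Comparative architecture of animal mitochondrial genomes: annotation-table
arithmetic, gene-order rearrangement (breakpoint distances), shared derived
cluster (synapomorphy) detection, parsimony reconstruction of ancestral
gene arrangements, and secondary-structure classification of truncated mt
tRNAs — with seed-deterministic synthetic-data generators so every stage is
testable without downloads.

The package was built around the mite (Acari) system.  Mites and ticks
split into two superorders: most Parasitiformes retain the ancestral
arthropod mt gene arrangement and cloverleaf tRNAs, whereas all known
Acariformes have rearranged genomes and truncated tRNAs (D-arm or T-arm
replaced by a loop).  The packaged fixtures are the complete mt genome
annotation tables of two eriophyoid (gall) mites — *Phyllocoptes
taishanensis* (13,475 bp) and *Epitrimerus sabinae* (13,531 bp) — the
least rearranged acariform mt genomes known, plus the Limulus-type
hypothetical arthropod ancestral arrangement and a schematic comparison
panel for other mite lineages.

## The core quantities

* **Intergenic arithmetic.** For coordinate-sorted features of a circular
  genome, `gap = downstream.start − upstream.end − 1` (negative =
  overlap), with the origin-wrapping pair closing the circle, so that
  Σ lengths + Σ gaps = genome length identically.
* **Breakpoint distance.** For gene orders π (target) and ρ (reference)
  over the same 37 genes, the count |A(π) \ A(ρ)| of adjacencies of π
  absent from ρ.  Default convention: unordered gene-name pairs on orders
  linearized at *cox1* (read in *cox1*'s direction, cut pair dropped,
  control region excluded); a signed-circular convention is available.
* **Synapomorphy candidates.** Maximal runs of ordered-orientation
  adjacencies derived (absent from the reference) in *every* target
  genome, screened run-by-run against other arrangements.
* **Ancestral arrangements.** Binary presence/absence of each signed
  adjacency, minimum-change (Fitch) parsimony on a rooted tree, then
  reassembly of the inferred adjacency set into ordered fragments with
  explicit conflicts and `?`-marked unplaced genes.
* **tRNA truncation classes.** Template-constrained folding (acceptor
  stem ≤ 7 bp, 7-nt anticodon loop, arms = strict stems of ≥ 2 WC/GU
  pairs with 3–9 nt loops) classifying each tRNA as cloverleaf,
  D-armless, T-armless or armless.

## Worked example

```r
library(mitoarch)

pt  <- fixture_genome_table("Pt")      # P. taishanensis annotation
es  <- fixture_genome_table("Es")      # E. sabinae annotation
anc <- fixture_ancestor_order()        # arthropod ancestral arrangement

pt$genome_length
#> [1] 13475
strand_counts(pt)
#>  J  N
#> 27 10

breakpoint_distance(gene_order_from_table(pt), anc)
#> [1] 13
breakpoint_distance(gene_order_from_table(es), anc)
#> [1] 16
```

13 and 16 are the breakpoint counts of the two eriophyoid genomes against
the hypothetical arthropod ancestor: of the 36 gene junctions in each
linearized order, 13 (respectively 16) do not occur in the ancestral
arrangement.  The shared derived junctions chain into candidate
synapomorphies:

```r
cl <- shared_derived_clusters(
  list(gene_order_from_table(pt), gene_order_from_table(es)), anc,
  screen = fixture_screen_orders())
sapply(cl, function(x) paste(paste0(ifelse(x$genes$orient == "-", "-", ""),
                                    x$genes$gene), collapse = " "))
#> [1] "trnS1 trnI trnE"
#> [2] "-nad4L -trnP"
#> [3] "nad6 trnT cob"
#> [4] "-nad1 -trnL2 -trnL1 trnY trnQ rrnS trnV rrnL trnW nad2 trnM -trnC cox1 cox2"
```

Clusters 1, 3 and 4 survive the screen (cluster 2, the `nad4L–trnP`
junction, also occurs in other mites and is refuted).  The
`trnY–trnQ–rrnS–trnV–rrnL` and `trnW–nad2–trnM–trnC` blocks sit inside
the long run as contiguous sub-runs.

The numbered scripts under `analysis/` drive the full study: per-genome
statistics (`01`), the breakpoint table (`02`), the synapomorphy screen
(`03`), the Acariformes ancestral arrangement with its `trnQ?`/`trnY?`
uncertainty (`04`), and simulation-based validation of the whole chain
(`05`).  Each writes its tables under `results/`.

## Scope

Gene identification, read assembly, tree estimation and free-energy tRNA
folding are out of scope: the package consumes annotation tables, a
user-supplied rooted tree, and tRNA sequences.  See
`vignettes/mitoarch-methods.Rmd` for conventions, thresholds and known
limitations.
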