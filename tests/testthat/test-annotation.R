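test_that("the packaged eriophyoid tables parse with the published composition", {
  pt <- fixture_genome_table("Pt")
  es <- fixture_genome_table("Es")
  for (tab in list(pt, es)) {
    r <- tab$records
    expect_equal(nrow(r), 38)            # 37 genes + control region
    expect_equal(sum(r$gene != "CR"), 37)
    expect_equal(as.integer(table(r$class)[c("PCG", "rRNA", "tRNA")]), c(13, 2, 22))
  }
  expect_equal(pt$genome_length, 13475)
  expect_equal(es$genome_length, 13531)
  expect_equal(unname(strand_counts(pt)), c(27, 10))
  expect_equal(unname(strand_counts(es)), c(27, 10))
})

test_that("genome length inference closes the circle from the wrap gap", {
  pt <- fixture_genome_table("Pt")
  es <- fixture_genome_table("Es")
  expect_equal(infer_genome_length(pt, 10), 13475)
  expect_equal(infer_genome_length(es, 14), 13531)
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstrand\tstart\tend", "cox1\tJ\t1\t100"), tmp)
  one <- parse_gene_table(tmp, genome_length = 100)
  expect_equal(infer_genome_length(one, 0), 100)
  expect_error(infer_genome_length(one, -200), "not positive")
})

test_that("single-record tables are valid but need an explicit genome length", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstrand\tstart\tend", "cox1\tJ\t1\t1554"), tmp)
  tab <- parse_gene_table(tmp)
  expect_true(is.na(tab$genome_length))
  expect_error(intergenic_gaps(tab), "genome_length")
  tab2 <- parse_gene_table(tmp, genome_length = 1600)
  expect_equal(intergenic_gaps(tab2)$gap, 46) # wrap pair only
})

test_that("malformed tables are rejected with informative errors", {
  write_tab <- function(lines) {
    tmp <- tempfile(fileext = ".tsv")
    writeLines(c("gene\tstrand\tstart\tend", lines), tmp)
    tmp
  }
  expect_error(parse_gene_table(write_tab("trnM\tJ\t500\t400")), "end < start")
  expect_error(parse_gene_table(write_tab(c("cox1\tJ\t1\t100", "cox1\tJ\t200\t300"))),
               "cox1")
  expect_error(parse_gene_table(write_tab("frobnitz\tJ\t1\t100")), "unknown gene")
  expect_error(parse_gene_table(write_tab("trnM\tJ\t1\t200")), "\\[40, 100\\]")
  tmp <- tempfile(fileext = ".tsv")
  writeLines("gene\tstrand\tstart\tend", tmp)
  expect_error(parse_gene_table(tmp), "empty")
})

test_that("every printed intergenic count is reproduced from coordinates", {
  for (which in c("Pt", "Es")) {
    chk <- check_printed_gaps(fixture_genome_table(which))
    expect_true(all(chk$match), info = which)
  }
})

test_that("published spot-check gaps: overlaps, spacers and the wrap pair", {
  gp <- intergenic_gaps(fixture_genome_table("Pt"))
  ge <- intergenic_gaps(fixture_genome_table("Es"))
  pick <- function(g, up, dn) g$gap[g$upstream == up & g$downstream == dn]
  expect_equal(pick(gp, "trnK", "trnD"), -2)
  expect_equal(pick(ge, "trnH", "nad4"), 16)
  expect_equal(pick(gp, "trnC", "cox1"), 10)   # origin-wrapping pair
  expect_equal(pick(ge, "atp8", "trnK"), -10)  # attributed to the coordinate predecessor
})

test_that("gap conservation holds and no non-CR spacer exceeds 16 bp", {
  for (which in c("Pt", "Es")) {
    tab <- fixture_genome_table(which)
    g <- intergenic_gaps(tab)
    len <- tab$records$end - tab$records$start + 1
    expect_equal(sum(len) + sum(g$gap), tab$genome_length)
    non_cr <- g[g$upstream != "CR" & g$downstream != "CR", ]
    expect_lte(max(non_cr$gap), 16)
  }
})

test_that("TSV round trip preserves the table", {
  pt <- fixture_genome_table("Pt")
  tmp <- tempfile(fileext = ".tsv")
  write_gene_table(pt, tmp)
  back <- parse_gene_table(tmp)
  expect_equal(back$records$gene, pt$records$gene)
  expect_equal(back$records$start, pt$records$start)
  expect_equal(back$records$end, pt$records$end)
  expect_equal(back$records$strand, pt$records$strand)
  expect_equal(back$genome_length, pt$genome_length)
  expect_equal(back$taxon, pt$taxon)
})

test_that("the GenBank-like feature dialect parses spans, strands and anticodons", {
  tmp <- tempfile(fileext = ".txt")
  writeLines(c(
    "     CDS             1..1554",
    '                     /gene="cox1"',
    "     tRNA            complement(1560..1615)",
    '                     /gene="trnF"',
    '                     /anticodon="(pos:1580..1582,aa:Phe,seq:gaa)"',
    "     rRNA            1620..2300",
    '                     /product="rrnS"',
    "     misc_feature    2301..2380",
    '                     /note="putative control region"'), tmp)
  tab <- parse_gene_table(tmp, dialect = "genbank-feature", taxon = "gb",
                          genome_length = 2400)
  expect_equal(tab$records$gene, c("cox1", "trnF", "rrnS", "CR"))
  expect_equal(tab$records$strand[1:3], c("J", "N", "J"))
  expect_equal(tab$records$anticodon[2], "GAA")
})

test_that("gene orders come out in coordinate order with CR placed as annotated", {
  es <- fixture_genome_table("Es")
  with_cr <- gene_order_from_table(es, include_cr = TRUE)
  i <- match(c("atp8", "trnK", "CR", "atp6"), with_cr$gene)
  expect_equal(i, sort(i)) # atp8 before trnK (despite overlap), then CR, then atp6
  expect_true(all(diff(i) == 1))
  pt <- gene_order_from_table(fixture_genome_table("Pt"), include_cr = TRUE)
  expect_true(order_contains_run(
    gene_order_from_table(fixture_genome_table("Pt")),
    c("-trnL1", "trnY", "trnQ", "rrnS", "trnV", "rrnL", "trnW")))
  expect_equal(pt$gene[match("rrnL", pt$gene) + 1], "CR")
})

test_that("codon extraction reads frames, partial stops and the N strand", {
  mk <- function(genes) {
    tmp <- tempfile(fileext = ".tsv")
    writeLines(c("gene\tclass\tstrand\tstart\tend", genes), tmp)
    tmp
  }
  # J-strand complete: ATG AAA TAA
  seq1 <- "ATGAAATAA"
  t1 <- parse_gene_table(mk("cox1\tPCG\tJ\t1\t9"), genome_length = 9)
  c1 <- extract_codons(seq1, t1)
  expect_equal(unlist(c1[1, c("start_codon", "stop_codon")], use.names = FALSE),
               c("ATG", "TAA"))
  expect_true(c1$complete)
  # 7-nt gene: partial T stop
  c2 <- extract_codons("ATGAAAT", parse_gene_table(mk("cox1\tPCG\tJ\t1\t7"),
                                                   genome_length = 7))
  expect_equal(c2$stop_codon, "T")
  expect_false(c2$complete)
  # N-strand gene whose reverse complement reads CTG ... TAG
  fwd <- "CTGAAACCCTAG"
  c3 <- extract_codons(mitoarch:::revcomp(fwd),
                       parse_gene_table(mk("cox1\tPCG\tN\t1\t12"), genome_length = 12))
  expect_equal(unlist(c3[1, c("start_codon", "stop_codon")], use.names = FALSE),
               c("CTG", "TAG"))
  # in-frame internal stop warns but does not error
  expect_warning(extract_codons("ATGTAAAAATAA",
                                parse_gene_table(mk("cox1\tPCG\tJ\t1\t12"),
                                                 genome_length = 12)),
                 "internal stop")
})
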