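# Independent reference implementations used as oracles.  These share no
# code with the package: plain vectors, explicit loops.

# unsigned breakpoint count, linearized at the cut gene read in its own
# transcriptional direction, wrap pair dropped.  Takes gene_order-like
# data frames but uses only plain vectors and loops.
bf_breakpoints <- function(target, reference, cut = "cox1") {
  pairs_of <- function(ord) {
    genes <- as.character(ord$gene)
    orient <- as.character(ord$orient)
    i <- which(genes == cut)
    if (orient[i] == "-") {
      genes <- rev(genes)
      i <- which(genes == cut)
    }
    g <- c(genes[i:length(genes)], if (i > 1) genes[1:(i - 1)])
    out <- character(0)
    for (k in 1:(length(g) - 1)) {
      p <- sort(c(g[k], g[k + 1]))
      out <- c(out, paste(p[1], p[2]))
    }
    out
  }
  tp <- pairs_of(target)
  rp <- pairs_of(reference)
  n <- 0
  for (p in tp) {
    found <- FALSE
    for (q in rp) if (identical(p, q)) { found <- TRUE; break }
    if (!found) n <- n + 1
  }
  n
}

# random circular signed order over k genes (always includes cox1 so the
# linearized convention applies)
random_order <- function(k, taxon = "rnd") {
  genes <- c("cox1", sample(setdiff(mitoarch:::MT_GENES, "cox1"), k - 1))
  genes <- sample(genes)
  orient <- sample(c("+", "-"), k, replace = TRUE)
  gene_order(genes, orient, taxon = taxon)
}

# random rooted binary tree with n tips labelled t1..tn (ape rtree is fine,
# but keep labels deterministic)
random_tree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

fixture_orders <- function() {
  list(pt = gene_order_from_table(fixture_genome_table("Pt")),
       es = gene_order_from_table(fixture_genome_table("Es")),
       anc = fixture_ancestor_order())
}
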