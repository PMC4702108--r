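## Gene-order algebra on circular signed permutations of the 37 mt genes.
##
## A gene order is the circular sequence of genes with transcriptional
## orientations read along the majority (J) strand.  The control region is
## carried as an inert marker: it may sit in the circle but is removed
## before any adjacency or distance computation.

#' Construct a circular signed gene order
#'
#' @param genes Character vector of gene names in reading order.  A leading
#'   \code{"-"} marks a gene transcribed on the minority (N) strand.
#'   Alternatively supply plain names plus \code{orient}.
#' @param orient Optional character vector of \code{"+"}/\code{"-"}
#'   orientations, recycled checks apply.
#' @param taxon Label for the genome.
#' @return An object of class \code{gene_order}: a data frame with columns
#'   \code{gene} and \code{orient} plus a \code{taxon} attribute.
#' @examples
#' gene_order(c("cox1", "-trnQ", "nad2"), taxon = "toy")
#' @export
gene_order <- function(genes, orient = NULL, taxon = "") {
  stopifnot(is.character(genes), length(genes) > 0)
  if (is.null(orient)) {
    neg <- grepl("^-", genes)
    genes <- sub("^-", "", genes)
    orient <- ifelse(neg, "-", "+")
  }
  if (length(orient) != length(genes)) stop("orient must match genes in length")
  if (!all(orient %in% c("+", "-"))) stop("orient must be '+' or '-'")
  genes <- canonical_gene_name(genes)
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) stop("duplicated gene(s) in order: ", paste(unique(dup), collapse = ", "))
  out <- data.frame(gene = genes, orient = orient, stringsAsFactors = FALSE)
  attr(out, "taxon") <- taxon
  class(out) <- c("gene_order", "data.frame")
  out
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order> ", attr(x, "taxon"), " (", nrow(x), " features)\n", sep = "")
  cat(paste0(ifelse(x$orient == "-", "-", ""), x$gene), fill = TRUE)
  invisible(x)
}

order_taxon <- function(order) attr(order, "taxon") %||% ""

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop the control region from a gene order
#' @param order A \code{gene_order}.
#' @return The order without any \code{CR} row.
#' @export
drop_cr <- function(order) {
  keep <- order$gene != "CR"
  out <- order[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxon") <- order_taxon(order)
  class(out) <- c("gene_order", "data.frame")
  out
}

#' Rotate a circular gene order
#' @param order A \code{gene_order}.
#' @param k Number of positions to rotate (the (k+1)-th feature becomes first).
#' @export
rotate_order <- function(order, k) {
  n <- nrow(order)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(order)
  idx <- c(seq_len(n)[-seq_len(k)], seq_len(k))
  out <- order[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxon") <- order_taxon(order)
  class(out) <- c("gene_order", "data.frame")
  out
}

#' Reverse-complement a circular gene order
#'
#' Reading the same circular molecule along the opposite strand: feature
#' order reverses and every orientation flips.
#' @param order A \code{gene_order}.
#' @export
revcomp_order <- function(order) {
  out <- order[rev(seq_len(nrow(order))), , drop = FALSE]
  out$orient <- ifelse(out$orient == "+", "-", "+")
  rownames(out) <- NULL
  attr(out, "taxon") <- order_taxon(order)
  class(out) <- c("gene_order", "data.frame")
  out
}

#' Rotation/reflection-invariant equality of circular orders
#'
#' Two circular signed orders are equal iff one is a rotation of the other
#' or a rotation of its reverse complement.
#' @param x,y \code{gene_order} objects.
#' @export
orders_equal <- function(x, y) {
  if (nrow(x) != nrow(y)) return(FALSE)
  key <- function(o) paste(paste0(o$orient, o$gene), collapse = " ")
  doubled <- function(o) paste(key(o), key(o))
  grepl(key(y), doubled(x), fixed = TRUE) ||
    grepl(key(revcomp_order(y)), doubled(x), fixed = TRUE)
}

## ordered-orientation circular adjacencies, CR excluded; strict keys with
## no reverse-complement folding ("a+>b-").  Used for cluster chaining.
ordered_adjacencies <- function(order) {
  o <- drop_cr(order)
  n <- nrow(o)
  if (n < 2) stop("order must contain at least two genes")
  nxt <- c(seq_len(n)[-1], 1L)
  paste0(o$gene, o$orient, ">", o$gene[nxt], o$orient[nxt])
}

## canonical signed adjacency key: (x,y) is identified with (-y,-x)
signed_key <- function(g1, o1, g2, o2) {
  a <- paste0(g1, o1, ">", g2, o2)
  b <- paste0(g2, ifelse(o2 == "+", "-", "+"), ">", g1, ifelse(o1 == "+", "-", "+"))
  ifelse(a <= b, a, b)
}

#' Adjacency set of a circular gene order
#'
#' The unordered gene-neighbour pairs of a gene order under a stated
#' convention.  The control region is always excluded.
#'
#' \describe{
#'   \item{\code{unsigned-linear-cox1}}{The circle is linearized to start at
#'     \emph{cox1}, the pair spanning the cut is dropped, and each remaining
#'     adjacency is an unordered pair of gene names (orientations ignored):
#'     \eqn{n-1} pairs for an \eqn{n}-gene order.  This is the unit counted
#'     as a "breakpoint" in rearrangement comparisons.}
#'   \item{\code{signed-circular}}{All \eqn{n} circular adjacencies with
#'     relative orientations, identifying \code{(x,y)} with \code{(-y,-x)}
#'     so the set is invariant to the strand the circle is read from.}
#' }
#'
#' @param order A \code{gene_order}.
#' @param convention \code{"unsigned-linear-cox1"} (default) or
#'   \code{"signed-circular"}.
#' @return Character vector of canonical adjacency keys with attributes
#'   \code{convention} and \code{taxon}.
#' @export
adjacency_set <- function(order, convention = c("unsigned-linear-cox1", "signed-circular")) {
  convention <- match.arg(convention)
  o <- drop_cr(order)
  n <- nrow(o)
  if (n < 2) stop("order must contain at least two genes")
  if (convention == "unsigned-linear-cox1") {
    i <- match("cox1", o$gene)
    if (is.na(i)) stop("cox1 absent: cannot linearize under unsigned-linear-cox1")
    ## read the circle in cox1's transcriptional direction so the cut (the
    ## junction at cox1's 5' end) is the same regardless of which strand
    ## the order was written from
    if (o$orient[i] == "-") {
      o <- revcomp_order(o)
      i <- match("cox1", o$gene)
    }
    o <- rotate_order(o, i - 1L)
    a <- o$gene[-n]
    b <- o$gene[-1]
    keys <- ifelse(a <= b, paste0(a, "|", b), paste0(b, "|", a))
  } else {
    nxt <- c(seq_len(n)[-1], 1L)
    keys <- signed_key(o$gene, o$orient, o$gene[nxt], o$orient[nxt])
  }
  keys <- unique(keys)
  attr(keys, "convention") <- convention
  attr(keys, "taxon") <- order_taxon(order)
  keys
}

check_same_gene_set <- function(target, reference) {
  gt <- sort(drop_cr(target)$gene)
  gr <- sort(drop_cr(reference)$gene)
  if (!identical(gt, gr)) {
    only_t <- setdiff(gt, gr)
    only_r <- setdiff(gr, gt)
    stop("gene sets differ between '", order_taxon(target), "' and '",
         order_taxon(reference), "': only in target: ",
         paste(only_t, collapse = ", "), "; only in reference: ",
         paste(only_r, collapse = ", "))
  }
  invisible(TRUE)
}

#' Breakpoint distance between two circular gene orders
#'
#' The number of gene adjacencies of \code{target} that are absent from
#' \code{reference} under the stated convention — a standard measure of the
#' extent of gene rearrangement.  Both genomes must carry the same gene set
#' (the control region never participates).
#'
#' @param target,reference \code{gene_order} objects over the same gene set.
#' @param convention Adjacency convention, see [adjacency_set()].
#' @return Integer count of breakpoints.
#' @examples
#' a <- gene_order(c("cox1", "cox2", "cox3", "cob"))
#' b <- gene_order(c("cox1", "cox3", "cox2", "cob"))
#' breakpoint_distance(b, a)
#' @export
breakpoint_distance <- function(target, reference,
                                convention = c("unsigned-linear-cox1", "signed-circular")) {
  convention <- match.arg(convention)
  length(derived_adjacencies(target, reference, convention))
}

#' Adjacencies of a target order absent from a reference order
#'
#' The set difference whose cardinality is [breakpoint_distance()]; these
#' derived adjacencies are the candidate apomorphies of the target.
#'
#' @inheritParams breakpoint_distance
#' @return Character vector of canonical adjacency keys (possibly empty).
#' @export
derived_adjacencies <- function(target, reference,
                                convention = c("unsigned-linear-cox1", "signed-circular")) {
  convention <- match.arg(convention)
  check_same_gene_set(target, reference)
  setdiff(adjacency_set(target, convention), adjacency_set(reference, convention))
}

#' Does a circular order contain a gene run contiguously?
#'
#' Checks whether \code{run} (genes with orientations, read 5'->3') occurs
#' as a contiguous block in the circular order on either strand (i.e. the
#' run itself or its reverse complement).  The control region is ignored.
#'
#' @param order A \code{gene_order}.
#' @param run Data frame with columns \code{gene} and \code{orient}, or a
#'   character vector with \code{-} prefixes for minority-strand genes.
#' @return Logical.
#' @export
order_contains_run <- function(order, run) {
  if (is.character(run)) {
    neg <- grepl("^-", run)
    run <- data.frame(gene = sub("^-", "", run),
                      orient = ifelse(neg, "-", "+"), stringsAsFactors = FALSE)
  }
  o <- drop_cr(order)
  circ <- function(x) {
    s <- paste(paste0(x$gene, x$orient), collapse = " ")
    paste(s, s)
  }
  pat <- paste(paste0(run$gene, run$orient), collapse = " ")
  rc <- data.frame(gene = rev(run$gene),
                   orient = ifelse(rev(run$orient) == "+", "-", "+"))
  pat_rc <- paste(paste0(rc$gene, rc$orient), collapse = " ")
  grepl(pat, circ(o), fixed = TRUE) || grepl(pat_rc, circ(o), fixed = TRUE)
}

#' Shared derived gene clusters (candidate synapomorphies)
#'
#' Finds maximal contiguous runs of genes whose internal adjacencies are
#' derived (absent from \code{reference}) in \emph{every} target genome.
#' Chaining uses strict ordered-orientation adjacencies, so a relocated and
#' inverted block chains as a single run.  When \code{screen} genomes are
#' supplied, a cluster is flagged synapomorphic for the targets only if the
#' run (or its reverse complement) occurs contiguously in none of them.
#'
#' @param targets List of \code{gene_order} objects (the focal clade).
#' @param reference A \code{gene_order}: the outgroup/ancestral arrangement.
#' @param screen Optional list of \code{gene_order} objects to screen
#'   against (arrangements the cluster must be absent from).
#' @return A list of clusters; each has elements \code{genes} (data frame
#'   \code{gene}/\code{orient}, 5'->3' on the reading strand of the first
#'   target), \code{support} (target taxa containing the run),
#'   \code{absent_from} (reference plus screened taxa lacking it),
#'   \code{present_in_screen} and logical \code{synapomorphic}.
#' @export
shared_derived_clusters <- function(targets, reference, screen = NULL) {
  if (length(targets) < 1) stop("need at least one target order")
  derived <- lapply(targets, function(t) {
    check_same_gene_set(t, reference)
    setdiff(ordered_adjacencies(t), ordered_adjacencies(reference))
  })
  shared <- Reduce(intersect, derived)
  if (length(shared) == 0) return(list())
  ## chain along the first target's circle
  o <- drop_cr(targets[[1]])
  n <- nrow(o)
  nxt <- c(seq_len(n)[-1], 1L)
  keys <- ordered_adjacencies(targets[[1]])
  in_shared <- keys %in% shared
  runs <- list()
  if (all(in_shared)) {
    runs[[1]] <- seq_len(n + 1) # whole circle; close it explicitly
  } else {
    ## starts: position i such that adjacency (i-1 -> i) is not shared but
    ## (i -> i+1) is
    prv <- c(n, seq_len(n - 1))
    starts <- which(in_shared & !in_shared[prv])
    for (s in starts) {
      idx <- s
      i <- s
      while (in_shared[i]) {
        i <- nxt[i]
        idx <- c(idx, i)
      }
      runs[[length(runs) + 1]] <- idx
    }
  }
  taxa <- vapply(targets, order_taxon, "")
  lapply(runs, function(idx) {
    idx_mod <- ((idx - 1) %% n) + 1
    genes <- data.frame(gene = o$gene[idx_mod], orient = o$orient[idx_mod],
                        stringsAsFactors = FALSE)
    in_screen <- if (length(screen) > 0) {
      vapply(screen, function(sg) order_contains_run(sg, genes), logical(1))
    } else logical(0)
    screen_taxa <- vapply(screen %||% list(), order_taxon, "")
    list(genes = genes,
         support = taxa,
         absent_from = c(order_taxon(reference), screen_taxa[!in_screen]),
         present_in_screen = screen_taxa[in_screen],
         synapomorphic = !any(in_screen))
  })
}

#' Read gene arrangements from the exchange format
#'
#' One genome per line: \code{taxon<TAB>gene gene ...} with genes in reading
#' order and a \code{-} prefix marking N-strand genes.  Lines starting with
#' \code{#} are comments.
#'
#' @param path Path to an arrangement file.
#' @return Named list of \code{gene_order} objects.
#' @export
read_arrangements <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed arrangement line: ", ln)
    genes <- strsplit(trimws(parts[2]), "[ ]+")[[1]]
    out[[parts[1]]] <- gene_order(genes, taxon = parts[1])
  }
  out
}

#' Write gene arrangements in the exchange format
#' @param orders Named list of \code{gene_order} objects.
#' @param path Output path.
#' @export
write_arrangements <- function(orders, path) {
  nms <- names(orders) %||% rep("", length(orders))
  lines <- vapply(seq_along(orders), function(i) {
    o <- orders[[i]]
    taxon <- if (nzchar(order_taxon(o))) order_taxon(o) else nms[i]
    paste0(taxon, "\t",
           paste(paste0(ifelse(o$orient == "-", "-", ""), o$gene), collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
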