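## Ancestral gene-arrangement inference: binary presence/absence of gene
## adjacencies as independent characters, minimum-change (Fitch) parsimony
## on a user-supplied rooted tree, and reassembly of candidate ancestral
## arrangements from the inferred adjacency set.

#' Build an adjacency presence/absence character matrix
#'
#' @param orders Named list of \code{gene_order} objects sharing one gene
#'   vocabulary (names, or taxon attributes, give the taxa).
#' @param convention Adjacency convention, see [adjacency_set()].  The
#'   signed-circular default is strand-reading invariant and yields
#'   \eqn{n} present characters per taxon.
#' @return Logical matrix, taxa x characters, over the union of observed
#'   adjacencies, with attribute \code{convention}.
#' @export
build_adjacency_matrix <- function(orders, convention = c("signed-circular", "unsigned-linear-cox1")) {
  convention <- match.arg(convention)
  if (length(orders) == 0) stop("no orders supplied")
  taxa <- names(orders) %||% vapply(orders, order_taxon, "")
  if (is.null(names(orders))) names(orders) <- taxa
  if (anyDuplicated(taxa)) stop("duplicate taxon labels: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  sets <- lapply(orders, adjacency_set, convention = convention)
  chars <- sort(unique(unlist(sets)))
  m <- t(vapply(sets, function(s) chars %in% s, logical(length(chars))))
  dimnames(m) <- list(taxa, chars)
  attr(m, "convention") <- convention
  m
}

## exact unit-cost parsimony DP for one binary character on a rooted tree
## (ape::phylo).  Returns per-node cost matrix (nodes x 2 states).
binary_parsimony_costs <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  cost <- matrix(Inf, n_node, 2)
  cost[cbind(seq_len(n_tip), states[tree$tip.label] + 1L)] <- 0
  ## postorder over internal nodes
  ord <- unique(tree$edge[rev(ape::postorder(tree)), 1])
  ord <- rev(ord)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  for (v in ord) {
    kids <- children[[as.character(v)]]
    for (s in 1:2) {
      tot <- 0
      for (k in kids) tot <- tot + min(cost[k, s], cost[k, 3 - s] + 1)
      cost[v, s] <- tot
    }
  }
  cost
}

#' Ancestral adjacency states by Fitch parsimony
#'
#' Runs minimum-change parsimony independently for every binary
#' presence/absence character on a rooted tree (polytomies allowed; exact
#' unit-cost dynamic programming, equivalent to two-pass Fitch on binary
#' trees).  Per internal node the minimal-cost state set is reported:
#' characters where both states tie are ambiguous.  When an outgroup taxon
#' is flagged, root-state ties are broken towards the outgroup's observed
#' state; otherwise ambiguity is reported, never silently resolved.
#'
#' @param matrix Logical taxa x characters matrix from
#'   [build_adjacency_matrix()].
#' @param tree A rooted \code{phylo} tree (or path to a Newick file) whose
#'   tip labels equal the matrix's taxa.
#' @param outgroup Optional tip label used for root tie-breaking.
#' @return List with \code{node_states} (per internal node: \code{present},
#'   \code{absent}, \code{ambiguous} character vectors), \code{changes}
#'   (named integer: most-parsimonious change count per character),
#'   \code{root} (the root's sets after outgroup tie-breaking) and
#'   \code{tree}.
#' @export
fitch_ancestral_states <- function(matrix, tree, outgroup = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick path")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tips <- tree$tip.label
  if (!setequal(tips, rownames(matrix))) {
    stop("tree leaves and matrix taxa differ; only in tree: ",
         paste(setdiff(tips, rownames(matrix)), collapse = ", "),
         "; only in matrix: ",
         paste(setdiff(rownames(matrix), tips), collapse = ", "))
  }
  if (!is.null(outgroup) && !outgroup %in% tips) stop("outgroup not a tip label")
  n_tip <- length(tips)
  root <- n_tip + 1L
  internal <- root:(n_tip + tree$Nnode)
  chars <- colnames(matrix)
  node_sets <- lapply(internal, function(.) list(present = character(), absent = character(),
                                                 ambiguous = character()))
  names(node_sets) <- as.character(internal)
  changes <- stats::setNames(integer(length(chars)), chars)
  root_sets <- list(present = character(), absent = character(), ambiguous = character())
  for (ch in chars) {
    states <- stats::setNames(as.integer(matrix[, ch]), rownames(matrix))
    cost <- binary_parsimony_costs(tree, states)
    changes[ch] <- as.integer(min(cost[root, ]))
    for (v in internal) {
      lab <- as.character(v)
      best <- which(cost[v, ] == min(cost[v, ])) - 1L
      slot <- if (length(best) == 2) "ambiguous" else if (best == 1L) "present" else "absent"
      node_sets[[lab]][[slot]] <- c(node_sets[[lab]][[slot]], ch)
    }
    best <- which(cost[root, ] == min(cost[root, ])) - 1L
    if (length(best) == 2 && !is.null(outgroup)) best <- states[outgroup]
    slot <- if (length(best) == 2) "ambiguous" else if (best[1] == 1L) "present" else "absent"
    root_sets[[slot]] <- c(root_sets[[slot]], ch)
  }
  list(node_states = node_sets, changes = changes, root = root_sets, tree = tree)
}

#' Minimal change count by exhaustive enumeration (reference oracle)
#'
#' Brute-force minimum over all assignments of internal-node states; only
#' feasible for small trees.  Provided as an independent check on
#' [fitch_ancestral_states()].
#'
#' @param tree Rooted \code{phylo}.
#' @param states Named 0/1 vector over tip labels.
#' @return Integer minimal number of state changes.
#' @export
brute_force_changes <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  if (n_int > 12) stop("tree too large for exhaustive enumeration")
  node_state <- integer(n_tip + n_int)
  node_state[seq_len(n_tip)] <- states[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    node_state[(n_tip + 1):(n_tip + n_int)] <- bitwAnd(bitwShiftR(mask, 0:(n_int - 1)), 1L)
    d <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
    if (d < best) best <- d
  }
  as.integer(best)
}

parse_signed_key <- function(key) {
  halves <- strsplit(key, ">", fixed = TRUE)[[1]]
  g <- sub("[+-]$", "", halves)
  o <- substr(halves, nchar(halves), nchar(halves))
  list(gene = g, orient = o)
}

#' Assemble candidate arrangements from an inferred adjacency set
#'
#' Treats each signed adjacency as joining two gene extremities and chains
#' maximal unambiguous paths.  A gene extremity touched by more than one
#' adjacency is a conflict: fragments are split there and the gene is
#' reported.  Genes with no incident adjacency are unplaced.  A
#' conflict-free set of \eqn{n} adjacencies over \eqn{n} genes closes into
#' the unique circular order.
#'
#' @param present Character vector of signed-circular adjacency keys (as
#'   produced by [adjacency_set()] or reported by
#'   [fitch_ancestral_states()]).
#' @param genes Optional gene vocabulary; defaults to the genes named in
#'   \code{present}.
#' @return List with \code{fragments} (list of \code{gene}/\code{orient}
#'   data frames), \code{circular} (logical: one fragment closing the
#'   circle), \code{unplaced} and \code{conflicts} (gene names).
#' @export
assemble_arrangement <- function(present, genes = NULL) {
  pairs <- lapply(present, parse_signed_key)
  all_genes <- genes %||% sort(unique(unlist(lapply(pairs, `[[`, "gene"))))
  ## extremities: gene.t (5' for + orientation) and gene.h (3').  The
  ## adjacency (a oa) -> (b ob) joins out-end(a,oa) = a.h if +, a.t if -
  ## with in-end(b,ob) = b.t if +, b.h if -.
  ends <- function(g, o, side) {
    if (side == "out") paste0(g, ifelse(o == "+", ".h", ".t"))
    else paste0(g, ifelse(o == "+", ".t", ".h"))
  }
  edge_list <- lapply(pairs, function(p) {
    c(ends(p$gene[1], p$orient[1], "out"), ends(p$gene[2], p$orient[2], "in"))
  })
  touch <- table(unlist(edge_list))
  conflict_ends <- names(touch)[touch > 1]
  conflicts <- sort(unique(sub("\\.[ht]$", "", conflict_ends)))
  keep <- vapply(seq_along(edge_list), function(i) {
    !any(edge_list[[i]] %in% conflict_ends) &&
      !any(pairs[[i]]$gene %in% conflicts)
  }, logical(1))
  edges <- edge_list[keep]
  ## undirected neighbour map over extremities: each surviving extremity is
  ## joined to at most one partner
  nbr <- new.env(parent = emptyenv())
  for (e in edges) {
    assign(e[1], e[2], envir = nbr)
    assign(e[2], e[1], envir = nbr)
  }
  joined <- function(ext) if (exists(ext, envir = nbr, inherits = FALSE))
    get(ext, envir = nbr) else NA_character_
  other_end <- function(ext) {
    g <- sub("\\.[ht]$", "", ext)
    side <- sub("^.*\\.", "", ext)
    paste0(g, if (side == "h") ".t" else ".h")
  }
  ext_gene <- function(ext) sub("\\.[ht]$", "", ext)
  fragments <- list()
  circular <- FALSE
  used <- new.env(parent = emptyenv())
  for (g in all_genes) {
    if (g %in% conflicts || exists(g, envir = used, inherits = FALSE)) next
    gseq <- g; oseq <- "+"
    this_circ <- FALSE
    ## extend rightwards from g.h: entering a gene at .t reads it "+",
    ## entering at .h reads it "-"
    ext <- paste0(g, ".h")
    repeat {
      nxt <- joined(ext)
      if (is.na(nxt)) break
      g2 <- ext_gene(nxt)
      if (g2 %in% gseq) { this_circ <- TRUE; break }
      gseq <- c(gseq, g2)
      oseq <- c(oseq, if (grepl("\\.t$", nxt)) "+" else "-")
      ext <- other_end(nxt)
    }
    if (!this_circ) {
      ## extend leftwards from g.t: a predecessor joined by its .h end
      ## reads "+", by its .t end reads "-"
      ext <- paste0(g, ".t")
      repeat {
        prv <- joined(ext)
        if (is.na(prv)) break
        g2 <- ext_gene(prv)
        if (g2 %in% gseq) { this_circ <- TRUE; break }
        gseq <- c(g2, gseq)
        oseq <- c(if (grepl("\\.h$", prv)) "+" else "-", oseq)
        ext <- other_end(prv)
      }
    }
    if (this_circ) circular <- TRUE
    frag <- data.frame(gene = gseq, orient = oseq, stringsAsFactors = FALSE)
    for (gg in frag$gene) assign(gg, TRUE, envir = used)
    fragments[[length(fragments) + 1]] <- frag
  }
  frag_sizes <- vapply(fragments, nrow, integer(1))
  unplaced <- sort(unique(c(conflicts,
                            unlist(lapply(fragments[frag_sizes == 1], `[[`, "gene")))))
  fragments <- fragments[frag_sizes > 1]
  list(fragments = fragments,
       circular = circular && length(fragments) == 1 &&
         length(conflicts) == 0 && nrow(fragments[[1]]) == length(all_genes),
       unplaced = setdiff(unplaced, character(0)),
       conflicts = conflicts)
}

#' Format assembled fragments in the arrangement exchange style
#'
#' Unplaced or conflicted genes are listed at the end with a \code{?}
#' suffix, marking uncertain locations.
#' @param assembly Result of [assemble_arrangement()].
#' @return Single character string.
#' @export
format_assembly <- function(assembly) {
  frag_txt <- vapply(assembly$fragments, function(f) {
    paste(paste0(ifelse(f$orient == "-", "-", ""), f$gene), collapse = " ")
  }, "")
  unp <- if (length(assembly$unplaced) > 0)
    paste(paste0(assembly$unplaced, "?"), collapse = " ") else NULL
  paste(c(frag_txt, unp), collapse = " | ")
}
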