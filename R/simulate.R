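## Seed-deterministic generators: gene-order rearrangement along trees,
## annotated genomes with sequences, and tRNA sequences of known
## architecture.  Every generator replays exactly under the same seed, so
## downstream stages can be tested against known ground truth.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

apply_event <- function(order, type, i, span, j = NULL) {
  n <- nrow(order)
  idx <- ((i - 1 + seq_len(span) - 1) %% n) + 1
  seg <- order[idx, , drop = FALSE]
  rest <- order[-idx, , drop = FALSE]
  inv <- function(seg) {
    seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    seg$orient <- ifelse(seg$orient == "+", "-", "+")
    seg
  }
  out <- switch(type,
    inversion = {
      o <- order
      o[idx, ] <- inv(seg)
      o
    },
    transposition = {
      j <- ((j - 1) %% nrow(rest)) + 1
      rbind(rest[seq_len(j), , drop = FALSE], seg,
            if (j < nrow(rest)) rest[(j + 1):nrow(rest), , drop = FALSE])
    },
    `inverse-transposition` = {
      j <- ((j - 1) %% nrow(rest)) + 1
      rbind(rest[seq_len(j), , drop = FALSE], inv(seg),
            if (j < nrow(rest)) rest[(j + 1):nrow(rest), , drop = FALSE])
    },
    stop("unknown event type: ", type))
  rownames(out) <- NULL
  attr(out, "taxon") <- order_taxon(order)
  class(out) <- c("gene_order", "data.frame")
  out
}

#' Evolve a circular gene order by random rearrangement events
#'
#' Applies \code{n_events} events of the given mix (inversion,
#' transposition, inverse-transposition) to uniformly chosen circular
#' spans; span lengths are uniform on \eqn{[1, n-1]}.  The control region,
#' if present, rides along as an inert marker.  The returned event log is
#' sufficient to replay the history exactly.
#'
#' @param order A \code{gene_order}.
#' @param n_events Non-negative integer.
#' @param event_mix Named numeric weights over
#'   \code{c("inversion","transposition","inverse-transposition")};
#'   normalised to sum to 1.
#' @param seed Integer seed (optional but recommended).
#' @return List with \code{order} (the evolved \code{gene_order}) and
#'   \code{events} (data frame log: \code{type}, \code{start}, \code{span},
#'   \code{dest}).
#' @export
evolve_order <- function(order, n_events,
                         event_mix = c(inversion = 0.4, transposition = 0.4,
                                       `inverse-transposition` = 0.2),
                         seed = NULL) {
  stopifnot(n_events >= 0)
  event_mix <- event_mix / sum(event_mix)
  with_seed(seed, {
    n <- nrow(order)
    log <- data.frame(type = character(), start = integer(), span = integer(),
                      dest = integer(), stringsAsFactors = FALSE)
    cur <- order
    for (e in seq_len(n_events)) {
      type <- sample(names(event_mix), 1, prob = event_mix)
      span <- sample.int(n - 1, 1)
      i <- sample.int(n, 1)
      j <- if (type == "inversion") NA_integer_ else sample.int(n - span, 1)
      cur <- apply_event(cur, type, i, span, j)
      log <- rbind(log, data.frame(type = type, start = i, span = span,
                                   dest = j, stringsAsFactors = FALSE))
    }
    list(order = cur, events = log)
  })
}

#' Replay an event log from a starting order
#' @param order Starting \code{gene_order}.
#' @param events Event log as returned by [evolve_order()].
#' @return The resulting \code{gene_order}.
#' @export
replay_events <- function(order, events) {
  cur <- order
  for (e in seq_len(nrow(events))) {
    cur <- apply_event(cur, events$type[e], events$start[e], events$span[e],
                       events$dest[e])
  }
  cur
}

#' Simulate a rearrangement scenario along a rooted tree
#'
#' Evolves \code{root_order} down every edge of \code{tree}, applying
#' \code{events_per_edge} events per edge.  The returned scenario records
#' the per-edge event logs and all node orders, and replays exactly from
#' its seed.
#'
#' @param tree Rooted \code{phylo} (or Newick path).
#' @param root_order \code{gene_order} at the root.
#' @param events_per_edge Integer (recycled over edges) or vector of length
#'   \code{nrow(tree$edge)}.
#' @param event_mix See [evolve_order()].
#' @param seed Integer seed.
#' @return List of class \code{rearrangement_scenario}: \code{tree},
#'   \code{root_order}, \code{leaf_orders} (named list),
#'   \code{node_orders}, \code{edge_events}, \code{seed}.
#' @export
simulate_scenario <- function(tree, root_order, events_per_edge = 1,
                              event_mix = c(inversion = 0.4, transposition = 0.4,
                                            `inverse-transposition` = 0.2),
                              seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  n_edge <- nrow(tree$edge)
  events_per_edge <- rep_len(events_per_edge, n_edge)
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    node_orders <- vector("list", n_tip + tree$Nnode)
    node_orders[[n_tip + 1L]] <- root_order
    edge_events <- vector("list", n_edge)
    ## preorder: parents before children
    pre <- rev(ape::postorder(tree))
    for (ei in pre) {
      par <- tree$edge[ei, 1]; chi <- tree$edge[ei, 2]
      res <- evolve_order(node_orders[[par]], events_per_edge[ei], event_mix,
                          seed = NULL)
      node_orders[[chi]] <- res$order
      edge_events[[ei]] <- res$events
    }
    leaves <- stats::setNames(node_orders[seq_len(n_tip)], tree$tip.label)
    out <- list(tree = tree, root_order = root_order, leaf_orders = leaves,
                node_orders = node_orders, edge_events = edge_events,
                events_per_edge = events_per_edge, seed = seed)
    class(out) <- "rearrangement_scenario"
    out
  })
}

#' Generate a tRNA sequence with a specified architecture
#'
#' Builds a sequence that folds, under the package folder with default
#' thresholds, to the requested arm architecture: acceptor stem of 7 pairs
#' (with the requested number of mismatches), anticodon stem of
#' \code{ac_stem} perfect pairs around a 7-nt loop carrying the family
#' anticodon, and D-/T-arms either present (a perfect stem of the given
#' length plus loop) or replaced by an unpairable A/C loop.
#'
#' @param family Canonical tRNA family name (e.g. \code{"trnM"}), sets the
#'   anticodon.
#' @param d_arm,t_arm Logical: is the arm present?
#' @param d_stem,t_stem Stem lengths (pairs) when present.
#' @param d_loop,t_loop Loop lengths when present.
#' @param replacement_len Replacement-loop length when an arm is absent.
#' @param ac_stem Anticodon stem length (pairs).
#' @param acceptor_mismatches Number of acceptor-stem mismatches (0-2).
#' @param seed Integer seed.
#' @return List with \code{sequence}, \code{family}, \code{anticodon},
#'   \code{classification} (the intended ground truth) and
#'   \code{anticodon_start}.
#' @export
generate_trna <- function(family, d_arm = TRUE, t_arm = TRUE,
                          d_stem = 3, t_stem = 4, d_loop = 5, t_loop = 5,
                          replacement_len = 7, ac_stem = 5,
                          acceptor_mismatches = 0, seed = NULL) {
  family <- canonical_gene_name(family)
  if (!family %in% names(MT_ANTICODONS)) stop("not a tRNA family: ", family)
  ac <- MT_ANTICODONS[[family]]
  with_seed(seed, {
    rand <- function(k, alphabet = c("A", "C", "G", "T"))
      paste(sample(alphabet, k, replace = TRUE), collapse = "")
    pair_of <- c(A = "T", T = "A", G = "C", C = "G")
    stem_pair <- function(k) {
      s5 <- strsplit(rand(k), "")[[1]]
      list(s5 = paste(s5, collapse = ""),
           s3 = paste(rev(pair_of[s5]), collapse = ""))
    }
    ## unpairable region: A/C only (no WC or GU pair within {A,C})
    loopseq <- function(k) rand(k, c("A", "C"))
    acc <- stem_pair(7)
    acc3 <- strsplit(acc$s3, "")[[1]]
    if (acceptor_mismatches > 0) {
      pos <- sample.int(7, acceptor_mismatches)
      for (p in pos) {
        ## replace with a base that pairs with neither partner (break the pair)
        partner <- strsplit(acc$s5, "")[[1]][8 - p]
        choices <- setdiff(c("A", "C"), c(pair_of[partner],
                                          if (partner == "G") "T" else NULL))
        acc3[p] <- sample(rep(choices, 2), 1)
      }
    }
    acs <- stem_pair(ac_stem)
    dpart <- if (d_arm) {
      st <- stem_pair(d_stem)
      paste0(st$s5, loopseq(d_loop), st$s3)
    } else loopseq(replacement_len)
    tpart <- if (t_arm) {
      st <- stem_pair(t_stem)
      paste0(st$s5, loopseq(t_loop), st$s3)
    } else loopseq(replacement_len)
    ac_loop <- paste0(loopseq(2), ac, loopseq(2))
    seqs <- paste0(acc$s5, dpart, acs$s5, ac_loop, acs$s3, tpart,
                   paste(acc3, collapse = ""))
    list(sequence = seqs, family = family, anticodon = ac,
         classification = if (d_arm && t_arm) "cloverleaf"
         else if (!d_arm && t_arm) "D-armless"
         else if (d_arm && !t_arm) "T-armless" else "armless",
         anticodon_start = as.integer(7 + nchar(dpart) + ac_stem + 2 + 1))
  })
}

random_codons <- function(k) {
  ## sense codons only under the invertebrate mt code (no TAA/TAG)
  bases <- c("A", "C", "G", "T")
  out <- character(k)
  i <- 1
  while (i <= k) {
    cod <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    if (cod %in% c("TAA", "TAG")) next
    out[i] <- cod
    i <- i + 1
  }
  paste(out, collapse = "")
}

#' Generate an annotated genome realizing a gene order
#'
#' Lays the genes of \code{order} onto a circular sequence with small
#' non-negative intergenic gaps and realistic feature lengths; PCGs receive
#' an ATN start and a complete TAA/TAG stop — or a 1-nt partial \code{T}
#' stop when listed in \code{incomplete_stop} — tRNAs are built by
#' [generate_trna()] (cloverleaf by default, or per \code{trna_specs}), and
#' N-strand features are reverse-complemented into the reading strand.
#'
#' @param order A \code{gene_order} (may include CR).
#' @param seed Integer seed.
#' @param incomplete_stop Character vector of PCG names to end with a
#'   partial stop codon.
#' @param trna_specs Optional named list of argument lists passed on to
#'   [generate_trna()] per family.
#' @param max_gap Maximum intergenic gap (uniform on 0..max_gap).
#' @return List with \code{sequence} (string), \code{table}
#'   (\code{genome_table}) and \code{trna_truth} (intended classifications).
#' @export
generate_genome <- function(order, seed = NULL, incomplete_stop = character(),
                            trna_specs = list(), max_gap = 5) {
  with_seed(seed, {
    rows <- list()
    segs <- character()
    pos <- 1L
    trna_truth <- list()
    for (i in seq_len(nrow(order))) {
      g <- order$gene[i]
      cls <- gene_class(g)
      if (cls == "PCG") {
        ncod <- sample(60:200, 1)
        body <- paste0("ATG", random_codons(ncod))
        body <- if (g %in% incomplete_stop) paste0(body, "T") else paste0(body, "TAA")
        anticodon <- NA_character_
      } else if (cls == "tRNA") {
        spec <- trna_specs[[g]] %||% list()
        tr <- do.call(generate_trna, c(list(family = g), spec))
        body <- tr$sequence
        trna_truth[[g]] <- tr$classification
        anticodon <- tr$anticodon
      } else if (cls == "rRNA") {
        body <- paste(sample(c("A", "C", "G", "T"), sample(600:1000, 1),
                             replace = TRUE), collapse = "")
        anticodon <- NA_character_
      } else { # CR
        body <- paste(sample(c("A", "T"), sample(40:100, 1), replace = TRUE),
                      collapse = "")
        anticodon <- NA_character_
      }
      strand <- if (cls == "CR") NA_character_ else
        if (order$orient[i] == "+") "J" else "N"
      seg <- if (identical(strand, "N")) revcomp(body) else body
      rows[[i]] <- data.frame(gene = g, class = cls, strand = strand,
                              start = pos, end = pos + nchar(seg) - 1L,
                              anticodon = anticodon, stringsAsFactors = FALSE)
      segs <- c(segs, seg)
      gap <- sample.int(max_gap + 1, 1) - 1L
      if (gap > 0) segs <- c(segs, paste(sample(c("A", "T"), gap, replace = TRUE),
                                         collapse = ""))
      pos <- pos + nchar(seg) + gap
    }
    genome <- paste(segs, collapse = "")
    tab <- new_genome_table(order_taxon(order), sort_records(do.call(rbind, rows)),
                            nchar(genome))
    validate_genome_table(tab)
    list(sequence = genome, table = tab, trna_truth = trna_truth)
  })
}
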