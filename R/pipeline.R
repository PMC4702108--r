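## Orchestration over the analysis stages: per-genome statistics,
## breakpoint matrices, shared-derived-cluster screens, ancestral
## reconstruction and tRNA classification, with JSON/TSV report output.
## The numbered scripts under analysis/ are thin drivers over these
## functions.

#' Per-genome architecture statistics
#'
#' Computes the derived quantities of an annotation table: genome length,
#' feature-class counts, strand usage, control-region length and position,
#' intergenic gaps/overlaps (including the origin-wrapping pair), tRNA size
#' range, and codon usage.  Start/stop codons are taken from the genome
#' sequence when one is supplied, else from annotation columns when
#' present.  The TAA stop-codon tally is reported as recomputed; a
#' \code{printed_gap_mismatches} entry surfaces any disagreement between
#' printed and recomputed intergenic counts rather than hiding it.
#'
#' @param table A \code{genome_table}.
#' @param genome_seq Optional genome sequence (string).
#' @return List of statistics (JSON-serializable).
#' @export
genome_stats <- function(table, genome_seq = NULL) {
  r <- table$records
  gaps <- intergenic_gaps(table)
  non_cr <- gaps[gaps$upstream != "CR" & gaps$downstream != "CR", ]
  trna_len <- r$end[r$class == "tRNA"] - r$start[r$class == "tRNA"] + 1L
  cr <- r[r$gene == "CR", , drop = FALSE]
  codons <- NULL
  if (!is.null(genome_seq)) {
    codons <- extract_codons(genome_seq, table)
  } else if (all(c("start_codon", "stop_codon") %in% names(r))) {
    pc <- r[r$class == "PCG", ]
    codons <- data.frame(gene = pc$gene, start_codon = pc$start_codon,
                         stop_codon = pc$stop_codon,
                         complete = pc$stop_codon %in% c("TAA", "TAG"),
                         stringsAsFactors = FALSE)
  }
  gap_check <- if ("printed_gap" %in% names(r)) check_printed_gaps(table) else NULL
  list(
    taxon = table$taxon,
    genome_length = table$genome_length,
    n_features = nrow(r),
    n_genes = sum(r$gene != "CR"),
    class_counts = as.list(table(r$class)),
    strand_counts = as.list(strand_counts(table)),
    cr = if (nrow(cr) == 1) list(length = cr$end - cr$start + 1L,
                                 start = cr$start, end = cr$end) else NULL,
    trna_size_range = if (length(trna_len)) range(trna_len) else NULL,
    gaps = gaps,
    max_non_cr_gap = if (nrow(non_cr)) max(non_cr$gap) else NA,
    gap_conservation = sum(r$end - r$start + 1) + sum(gaps$gap) == table$genome_length,
    codons = codons,
    stop_codon_tally = if (!is.null(codons))
      as.list(table(substr(codons$stop_codon, 1, 3))) else NULL,
    printed_gap_mismatches = if (!is.null(gap_check))
      gap_check[!gap_check$match, , drop = FALSE] else NULL)
}

#' Genome statistics over a set of annotation tables
#'
#' @param tables Named list of \code{genome_table} objects or paths to
#'   annotation TSVs.
#' @param fastas Optional named character vector of FASTA paths (names
#'   matching \code{tables}).
#' @param out_dir Optional directory for \code{genome_stats.json} and
#'   per-genome gap TSVs.
#' @return Named list of per-genome statistics, invisibly when writing.
#' @export
run_genome_stats <- function(tables, fastas = NULL, out_dir = NULL) {
  tables <- lapply(tables, function(t) if (is.character(t)) parse_gene_table(t) else t)
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- vapply(tables, function(t) t$taxon, "")
  stats <- lapply(names(tables), function(nm) {
    seq <- NULL
    if (!is.null(fastas) && nm %in% names(fastas)) {
      fa <- seqinr::read.fasta(fastas[[nm]], as.string = TRUE, forceDNAtolower = FALSE)
      seq <- toupper(as.character(fa[[1]]))
    }
    genome_stats(tables[[nm]], seq)
  })
  names(stats) <- names(tables)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(lapply(stats, function(s) s[names(s) != "gaps"]),
                         file.path(out_dir, "genome_stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    for (nm in names(stats)) {
      utils::write.table(stats[[nm]]$gaps,
                         file.path(out_dir, paste0(nm, "_gaps.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(stats))
  }
  stats
}

#' Breakpoint distances of a set of orders against reference arrangements
#'
#' @param orders Named list of \code{gene_order} objects.
#' @param references Named list of \code{gene_order} objects (often just
#'   the hypothetical ancestor).
#' @param convention See [adjacency_set()].
#' @param out_file Optional TSV path for the taxa x references matrix.
#' @return Integer matrix, taxa x references; pairs with mismatched gene
#'   sets get \code{NA} and a warning rather than aborting the matrix.
#' @export
run_breakpoints <- function(orders, references,
                            convention = "unsigned-linear-cox1",
                            out_file = NULL) {
  if (inherits(references, "gene_order")) references <- list(references)
  if (is.null(names(orders))) names(orders) <- vapply(orders, order_taxon, "")
  if (is.null(names(references))) names(references) <- vapply(references, order_taxon, "")
  m <- matrix(NA_integer_, length(orders), length(references),
              dimnames = list(names(orders), names(references)))
  for (i in seq_along(orders)) for (j in seq_along(references)) {
    m[i, j] <- tryCatch(breakpoint_distance(orders[[i]], references[[j]], convention),
                        error = function(e) {
                          warning("skipping ", names(orders)[i], " vs ",
                                  names(references)[j], ": ", conditionMessage(e))
                          NA_integer_
                        })
  }
  if (!is.null(out_file)) {
    utils::write.table(cbind(taxon = rownames(m), as.data.frame(m)), out_file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  m
}

#' Run the full comparative pipeline on a configuration
#'
#' Stages: per-genome statistics, breakpoint matrix, shared derived
#' clusters, optional ancestral inference (when a tree is configured) and
#' optional tRNA classification (when FASTAs are configured).  A failed
#' stage is reported and later stages that depend on it are skipped with a
#' notice; the effective configuration is written next to the report so a
#' run is reproducible from its output directory.
#'
#' @param config Named list or path to a YAML file with entries:
#'   \code{tables} (named paths), \code{arrangements} (path, exchange
#'   format), \code{reference} (taxon name inside \code{arrangements}),
#'   \code{targets} (taxa treated as the focal clade), \code{screen}
#'   (taxa to screen against), \code{tree} (Newick path), \code{outgroup},
#'   \code{trna_fasta} (named paths), \code{convention}, \code{seed},
#'   \code{out_dir}.
#' @return List with per-stage results; written to \code{out_dir} when set.
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (length(config) == 0) stop("empty configuration")
  out_dir <- config$out_dir
  if (!is.null(config$seed)) set.seed(config$seed)
  results <- list()
  notices <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      notices <<- c(notices, paste0("stage '", name, "' failed: ", conditionMessage(e)))
      NULL
    })
  }
  tables <- stage("parse", lapply(config$tables, parse_gene_table))
  results$stats <- if (!is.null(tables)) stage("stats", run_genome_stats(tables))
  orders <- NULL
  if (!is.null(config$arrangements)) {
    orders <- stage("arrangements", read_arrangements(config$arrangements))
  }
  if (!is.null(tables)) {
    tab_orders <- lapply(tables, gene_order_from_table)
    names(tab_orders) <- vapply(tables, function(t) t$taxon, "")
    orders <- c(orders %||% list(), tab_orders)
  }
  conv <- config$convention %||% "unsigned-linear-cox1"
  if (!is.null(orders) && !is.null(config$reference) &&
      config$reference %in% names(orders)) {
    ref <- orders[[config$reference]]
    others <- orders[setdiff(names(orders), config$reference)]
    results$breakpoints <- stage("breakpoints",
                                 run_breakpoints(others, list(ref), convention = conv))
    targets <- orders[intersect(config$targets %||% character(), names(orders))]
    screen <- orders[intersect(config$screen %||% character(), names(orders))]
    if (length(targets) > 0) {
      results$clusters <- stage("clusters",
                                shared_derived_clusters(targets, ref, screen))
    }
    if (!is.null(config$tree)) {
      results$ancestral <- stage("ancestral", {
        keep <- orders
        m <- build_adjacency_matrix(keep, convention = "signed-circular")
        tree <- ape::read.tree(config$tree)
        tree <- ape::keep.tip(tree, intersect(tree$tip.label, rownames(m)))
        m <- m[tree$tip.label, , drop = FALSE]
        fit <- fitch_ancestral_states(m, tree, outgroup = config$outgroup)
        list(fit = fit, root_assembly = assemble_arrangement(fit$root$present))
      })
    }
  } else if (!is.null(config$reference)) {
    notices <- c(notices, "skipping breakpoints/clusters/ancestral: reference arrangement unavailable")
  }
  if (!is.null(config$trna_fasta)) {
    results$trna <- stage("trna", {
      per_genome <- lapply(config$trna_fasta, fold_trna_set)
      list(per_genome = per_genome, summary = truncation_summary(per_genome))
    })
  }
  results$notices <- notices
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(
      list(notices = notices,
           breakpoints = if (!is.null(results$breakpoints))
             as.data.frame(results$breakpoints),
           clusters = lapply(results$clusters %||% list(), function(cl)
             list(genes = paste(paste0(ifelse(cl$genes$orient == "-", "-", ""),
                                       cl$genes$gene), collapse = " "),
                  synapomorphic = cl$synapomorphic,
                  absent_from = cl$absent_from))),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  results
}
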