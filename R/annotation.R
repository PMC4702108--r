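## Annotation-table arithmetic for circular mitochondrial genomes.
##
## Coordinates are 1-based inclusive throughout; no feature spans the
## origin.  Records are kept coordinate-sorted (start, then end, then name)
## regardless of the row order of the source table, because intergenic
## counts are attributed to the pair (coordinate-predecessor, feature).

new_genome_table <- function(taxon, records, genome_length) {
  stopifnot(is.data.frame(records))
  out <- list(taxon = taxon, records = records, genome_length = genome_length)
  class(out) <- "genome_table"
  out
}

#' @export
print.genome_table <- function(x, ...) {
  cat("<genome_table> ", x$taxon, ": ", nrow(x$records), " features, ",
      if (is.na(x$genome_length)) "length unknown" else paste0(x$genome_length, " bp"),
      " (circular)\n", sep = "")
  invisible(x)
}

validate_genome_table <- function(tab) {
  r <- tab$records
  if (nrow(r) == 0) stop("annotation table is empty")
  if (any(r$end < r$start)) {
    bad <- r$gene[r$end < r$start]
    stop("end < start for feature(s): ", paste(bad, collapse = ", "))
  }
  if (any(r$start < 1)) stop("coordinates must be >= 1")
  non_cr <- r$gene[r$gene != "CR"]
  dup <- unique(non_cr[duplicated(non_cr)])
  if (length(dup) > 0) stop("duplicate gene name(s): ", paste(dup, collapse = ", "))
  if (sum(r$gene == "CR") > 1) stop("at most one control region (CR) permitted")
  is_trna <- r$class == "tRNA"
  len <- r$end - r$start + 1
  if (any(is_trna & (len < 40 | len > 100))) {
    bad <- r$gene[is_trna & (len < 40 | len > 100)]
    stop("tRNA length outside [40, 100] nt: ", paste(bad, collapse = ", "))
  }
  has_ac <- !is.na(r$anticodon) & r$anticodon != ""
  if (any(has_ac & !is_trna)) stop("anticodon on non-tRNA feature: ",
                                   paste(r$gene[has_ac & !is_trna], collapse = ", "))
  if (length(non_cr) == 37 && !setequal(non_cr, MT_GENES))
    stop("37 non-CR records do not form the full 37-gene set; missing: ",
         paste(setdiff(MT_GENES, non_cr), collapse = ", "))
  if (!is.na(tab$genome_length) && tab$genome_length < max(r$end))
    stop("genome_length (", tab$genome_length, ") smaller than max(end) (", max(r$end), ")")
  invisible(tab)
}

sort_records <- function(r) {
  r <- r[order(r$start, r$end, r$gene), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Parse a per-genome annotation table
#'
#' Reads an annotation table in either the tab-separated dialect (columns
#' \code{gene}, \code{class}, \code{strand}, \code{start}, \code{end} and
#' optionally \code{anticodon}, \code{printed_gap}, \code{start_codon},
#' \code{stop_codon}; header required; \code{#} comment lines allowed) or a
#' GenBank-like feature-table dialect (\code{gene}/\code{tRNA}/\code{rRNA}/
#' \code{CDS}/\code{misc_feature} keys with \code{complement(a..b)} spans
#' and \code{/gene=} qualifiers).
#'
#' Comment headers of the form \code{# taxon = X} and
#' \code{# genome_length = N} are honoured.  When no genome length is
#' declared it is inferred from the wrap-around intergenic count of the
#' first feature (see [infer_genome_length()]) if a \code{printed_gap}
#' column is present, and left \code{NA} otherwise.
#'
#' @param source Path to the table file.
#' @param dialect \code{"tsv"} or \code{"genbank-feature"}.
#' @param taxon Optional taxon label (overrides any header).
#' @param genome_length Optional known genome length in nucleotides
#'   (overrides any header; conflicting declarations are an error).
#' @return A \code{genome_table}: list with \code{taxon}, coordinate-sorted
#'   \code{records} data frame and \code{genome_length}.
#' @export
parse_gene_table <- function(source, dialect = c("tsv", "genbank-feature"),
                             taxon = NULL, genome_length = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(source, warn = FALSE)
  hdr_taxon <- sub("^#\\s*taxon\\s*=\\s*", "", grep("^#\\s*taxon\\s*=", lines, value = TRUE))
  hdr_len <- sub("^#\\s*genome_length\\s*=\\s*", "",
                 grep("^#\\s*genome_length\\s*=", lines, value = TRUE))
  hdr_len <- if (length(hdr_len) > 0) as.integer(hdr_len[1]) else NA_integer_
  if (!is.null(genome_length) && !is.na(hdr_len) && genome_length != hdr_len)
    stop("declared genome_length (", genome_length,
         ") conflicts with table header (", hdr_len, ")")
  if (dialect == "tsv") {
    r <- utils::read.delim(source, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("gene", "strand", "start", "end")
    if (!all(need %in% names(r)))
      stop("TSV dialect requires header columns: ", paste(need, collapse = ", "))
  } else {
    r <- parse_genbank_features(lines)
  }
  if (nrow(r) == 0) stop("annotation table is empty")
  if (!is.numeric(r$start) || !is.numeric(r$end) ||
      any(r$start != floor(r$start)) || any(r$end != floor(r$end)))
    stop("coordinates must be integers")
  if (!"anticodon" %in% names(r)) r$anticodon <- NA_character_
  r$anticodon[r$anticodon %in% c("", ".")] <- NA_character_
  r$gene <- canonical_gene_name(r$gene, r$anticodon)
  if (!"class" %in% names(r) || all(is.na(r$class))) r$class <- gene_class(r$gene)
  r$class[is.na(r$class) | r$class %in% c("", ".")] <- gene_class(r$gene)[is.na(r$class) | r$class %in% c("", ".")]
  if (!identical(r$class, gene_class(r$gene)))
    stop("declared feature class disagrees with gene vocabulary for: ",
         paste(r$gene[r$class != gene_class(r$gene)], collapse = ", "))
  r$strand <- normalize_strand(r$strand)
  if (any(is.na(r$strand) & r$gene != "CR"))
    stop("missing strand for: ", paste(r$gene[is.na(r$strand) & r$gene != "CR"], collapse = ", "))
  for (col in c("printed_gap")) if (col %in% names(r)) r[[col]] <- as.integer(r[[col]])
  for (col in c("start_codon", "stop_codon")) if (col %in% names(r)) {
    r[[col]][r[[col]] %in% c("", ".")] <- NA_character_
  }
  r <- sort_records(r)
  len <- if (!is.null(genome_length)) as.integer(genome_length) else hdr_len
  tab <- new_genome_table(taxon %||% (if (length(hdr_taxon)) trimws(hdr_taxon[1]) else basename(source)),
                          r, len)
  validate_genome_table(tab)
  if (is.na(tab$genome_length) && "printed_gap" %in% names(r) &&
      !is.na(r$printed_gap[1])) {
    tab$genome_length <- infer_genome_length(tab, r$printed_gap[1])
    validate_genome_table(tab)
  }
  tab
}

## minimal GenBank-like feature-table parser: feature keys in column 6..20,
## spans "a..b" or "complement(a..b)", qualifiers /gene= or /product=.
parse_genbank_features <- function(lines) {
  feat_keys <- c("gene", "tRNA", "rRNA", "CDS", "misc_feature", "D-loop")
  rows <- list()
  cur <- NULL
  flush <- function(cur, rows) {
    if (is.null(cur)) return(rows)
    nm <- cur$gene %||% cur$product
    if (is.null(nm)) stop("feature without /gene or /product qualifier at span ",
                          cur$start, "..", cur$end)
    if (cur$key == "misc_feature" &&
        grepl("control region|D-loop|putative control", nm, ignore.case = TRUE))
      nm <- "CR"
    if (cur$key == "D-loop") nm <- "CR"
    rows[[length(rows) + 1]] <- data.frame(
      gene = nm, strand = if (cur$complement) "N" else "J",
      start = cur$start, end = cur$end,
      anticodon = cur$anticodon %||% NA_character_, stringsAsFactors = FALSE)
    rows
  }
  for (ln in lines) {
    m <- regmatches(ln, regexec(
      "^\\s{2,}([A-Za-z_'-]+)\\s+(complement\\()?(\\d+)\\.\\.(\\d+)\\)?\\s*$", ln))[[1]]
    if (length(m) > 0 && m[2] %in% feat_keys) {
      if (!is.null(cur) && cur$key != "gene") rows <- flush(cur, rows)
      cur <- list(key = m[2], complement = nzchar(m[3]),
                  start = as.integer(m[4]), end = as.integer(m[5]))
      next
    }
    if (!is.null(cur)) {
      q <- regmatches(ln, regexec('^\\s+/(gene|product|anticodon|note)=\"?([^\"]*)\"?\\s*$', ln))[[1]]
      if (length(q) > 0) {
        if (q[2] == "gene") cur$gene <- q[3]
        if (q[2] == "product" && is.null(cur$gene)) cur$product <- q[3]
        if (q[2] == "anticodon") cur$anticodon <- toupper(gsub(".*seq:([A-Za-z]+).*", "\\1", q[3]))
        if (q[2] == "note" && is.null(cur$gene) &&
            grepl("control region|D-loop", q[3], ignore.case = TRUE)) cur$gene <- "CR"
      }
    }
  }
  if (!is.null(cur) && cur$key != "gene") rows <- flush(cur, rows)
  if (length(rows) == 0) stop("no features found in GenBank-like input")
  do.call(rbind, rows)
}

#' Write a genome table in the TSV dialect
#'
#' Inverse of [parse_gene_table()] for the TSV dialect (round-trips modulo
#' whitespace normalization and row sorting).
#' @param table A \code{genome_table}.
#' @param path Output path.
#' @export
write_gene_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# taxon = ", table$taxon),
               if (!is.na(table$genome_length))
                 paste0("# genome_length = ", table$genome_length)), con)
  r <- table$records
  r$strand[is.na(r$strand)] <- "."
  r$anticodon[is.na(r$anticodon)] <- "."
  suppressWarnings(utils::write.table(r, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = "."))
  invisible(path)
}

#' Infer circular genome length from the wrap-around intergenic count
#'
#' For a coordinate-sorted table whose first feature starts near the origin,
#' the genome length is \code{max(end) + declared_wrap_gap - (first_start - 1)},
#' where \code{declared_wrap_gap} is the intergenic count printed for the
#' first feature (the nucleotides between the last feature's end and the
#' first feature's start, across the origin).
#'
#' @param table A \code{genome_table}.
#' @param declared_wrap_gap Integer intergenic count for the first feature.
#' @return Genome length in nucleotides.
#' @export
infer_genome_length <- function(table, declared_wrap_gap) {
  r <- table$records
  len <- max(r$end) + declared_wrap_gap - (r$start[1] - 1L)
  if (len <= 0) stop("inferred genome length is not positive (", len, ")")
  as.integer(len)
}

#' Intergenic gaps and overlaps around a circular genome
#'
#' One row per adjacent feature pair in coordinate order, including the
#' origin-wrapping pair.  \code{gap = downstream_start - upstream_end - 1};
#' negative values are overlapping nucleotides.  The conservation identity
#' \eqn{\sum lengths + \sum gaps = genome\_length} holds by construction.
#'
#' @param table A \code{genome_table} with known \code{genome_length}.
#' @return Data frame with columns \code{upstream}, \code{downstream},
#'   \code{gap}.
#' @export
intergenic_gaps <- function(table) {
  if (is.na(table$genome_length)) stop("genome_length unknown; supply or infer it first")
  r <- table$records
  n <- nrow(r)
  nxt <- c(seq_len(n)[-1], 1L)
  start_next <- r$start[nxt]
  start_next[n] <- start_next[n] + table$genome_length
  data.frame(upstream = r$gene, downstream = r$gene[nxt],
             gap = as.integer(start_next - r$end - 1L),
             stringsAsFactors = FALSE)
}

#' Compare recomputed gaps with the printed intergenic counts
#'
#' For tables that carry a \code{printed_gap} column (the parenthetical
#' intergenic counts of the source annotation), recomputes every gap from
#' coordinates and reports any disagreement rather than silently accepting
#' the printed value.
#'
#' @param table A \code{genome_table} whose records have \code{printed_gap}.
#' @return Data frame with \code{gene}, \code{printed}, \code{computed},
#'   \code{match}.
#' @export
check_printed_gaps <- function(table) {
  r <- table$records
  if (!"printed_gap" %in% names(r)) stop("table has no printed_gap column")
  g <- intergenic_gaps(table)
  ## printed count belongs to the downstream feature of each pair
  computed <- stats::setNames(g$gap, g$downstream)
  data.frame(gene = r$gene, printed = r$printed_gap,
             computed = as.integer(computed[r$gene]),
             match = r$printed_gap == as.integer(computed[r$gene]),
             stringsAsFactors = FALSE)
}

#' Gene counts per strand
#'
#' @param table A \code{genome_table}.
#' @return Named integer vector \code{c(J = ..., N = ...)} over non-CR
#'   features.
#' @export
strand_counts <- function(table) {
  r <- table$records[table$records$gene != "CR", ]
  c(J = sum(r$strand == "J"), N = sum(r$strand == "N"))
}

#' Extract the circular signed gene order from an annotation table
#'
#' Features are taken in coordinate order (overlapping features ordered by
#' start); orientation is \code{+} for J-strand and \code{-} for N-strand
#' features.
#'
#' @param table A \code{genome_table}.
#' @param include_cr Keep the control region in the order?
#' @return A \code{gene_order}.
#' @export
gene_order_from_table <- function(table, include_cr = FALSE) {
  r <- table$records
  if (!include_cr) r <- r[r$gene != "CR", , drop = FALSE]
  if (nrow(r) == 0) stop("no features to build a gene order from")
  orient <- ifelse(is.na(r$strand) | r$strand == "J", "+", "-")
  gene_order(r$gene, orient, taxon = table$taxon)
}

#' Start/stop codons of the protein-coding genes
#'
#' For each PCG, reads the coding sequence in its orientation
#' (N-strand genes are reverse-complemented) and reports the start codon
#' (first 3 nt), the stop codon — a trailing complete \code{TAA}/\code{TAG},
#' or the partial \code{T}/\code{TA} left when the gene length is not a
#' multiple of 3 (completed to TAA by polyadenylation) — and completeness.
#' In-frame internal stops (invertebrate mt code: TAA/TAG) raise a warning
#' and are reported, not treated as errors.
#'
#' @param genome_seq Genome nucleotide sequence (single string, DNA).
#' @param table A \code{genome_table}.
#' @return Data frame with \code{gene}, \code{start_codon},
#'   \code{stop_codon}, \code{complete}, \code{internal_stops}.
#' @export
extract_codons <- function(genome_seq, table) {
  stopifnot(is.character(genome_seq), length(genome_seq) == 1)
  genome_seq <- toupper(gsub("U", "T", genome_seq))
  r <- table$records[table$records$class == "PCG", , drop = FALSE]
  if (any(r$end > nchar(genome_seq)))
    stop("PCG coordinates exceed sequence length")
  out <- lapply(seq_len(nrow(r)), function(i) {
    s <- substr(genome_seq, r$start[i], r$end[i])
    if (r$strand[i] == "N") s <- revcomp(s)
    len <- nchar(s)
    phase <- len %% 3
    start_codon <- substr(s, 1, 3)
    if (phase == 0) {
      stop_codon <- substr(s, len - 2, len)
      complete <- stop_codon %in% c("TAA", "TAG")
      ncod <- len / 3 - 1
    } else {
      stop_codon <- substr(s, len - phase + 1, len) # "T" or "TA"
      complete <- FALSE
      ncod <- (len - phase) / 3
    }
    codons <- substring(s, seq(1, by = 3, length.out = ncod),
                        seq(3, by = 3, length.out = ncod))
    internal <- sum(codons[-1] %in% c("TAA", "TAG"))
    data.frame(gene = r$gene[i], start_codon = start_codon,
               stop_codon = stop_codon, complete = complete,
               internal_stops = internal, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (any(out$internal_stops > 0))
    warning("in-frame internal stop codon(s) in: ",
            paste(out$gene[out$internal_stops > 0], collapse = ", "))
  out
}
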