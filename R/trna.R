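## Template-constrained folding and classification of mitochondrial tRNAs.
##
## Mt tRNAs in many acariform mites are heavily truncated: the D-arm or
## T-arm (or both) is replaced by a short loop.  The folder searches a
## cloverleaf template with explicit, configurable thresholds rather than
## free-energy minimization: an arm is "present" iff a helix of at least
## `min_stem` Watson-Crick/GU pairs closing a 3-9 nt loop fits in its
## region.  All decisions are deterministic (longest stem, then 5'-most).

trna_defaults <- function() {
  list(min_arm_stem = 2L,     # minimal stem (bp) for a D- or T-arm
       d_stem_max = 4L, t_stem_max = 5L,
       loop_min = 3L, loop_max = 9L,
       acceptor_pairs = 7L, acceptor_max_mismatch = 2L,
       ac_stem_max = 5L,
       pair_reward = 2L, mismatch_penalty = 1L)
}

base_pairs <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

norm_seq <- function(seq) {
  s <- toupper(gsub("U", "T", seq))
  if (grepl("[^ACGT]", s)) stop("sequence contains non-ACGT/U characters")
  s
}

## invertebrate mitochondrial genetic code (transl_table 5)
#' Decode an anticodon under the invertebrate mitochondrial code
#'
#' @param anticodon 3-mer (DNA or RNA alphabet, 5'->3').
#' @return List with \code{aa} (one-letter amino acid), \code{family}
#'   (canonical tRNA gene name, isoacceptors resolved by anticodon) or
#'   \code{NA}s if the anticodon is not in the 22-anticodon metazoan set.
#' @export
decode_anticodon <- function(anticodon) {
  ac <- norm_seq(anticodon)
  if (nchar(ac) != 3) stop("anticodon must be a 3-mer")
  codon <- revcomp(ac)
  aa <- toupper(seqinr::translate(strsplit(tolower(codon), "")[[1]], numcode = 5))
  fam <- names(MT_ANTICODONS)[MT_ANTICODONS == ac]
  list(aa = aa,
       family = if (length(fam) == 1) fam else NA_character_,
       known = length(fam) == 1)
}

#' Locate candidate anticodon positions in a tRNA sequence
#'
#' Candidates are the centres of 7-nt loops closed by a stem of at least 2
#' Watson-Crick/GU pairs, with enough flanking sequence for an acceptor
#' stem.  Candidates are ranked by closing-stem length, then centrality,
#' then 5' position; when \code{expected} is given, matching candidates
#' rank first.
#'
#' @param seq Nucleotide string, 40-100 nt.
#' @param expected Optional expected anticodon (3-mer).
#' @param params Folding thresholds, see \code{mitoarch:::trna_defaults}.
#' @return Data frame of candidates: \code{anticodon_start} (1-based
#'   position of the anticodon's first base), \code{loop_start},
#'   \code{stem_len}, \code{anticodon}, \code{matches_expected}; zero rows
#'   when no candidate exists.
#' @export
locate_anticodon <- function(seq, expected = NULL, params = trna_defaults()) {
  s <- norm_seq(seq)
  L <- nchar(s)
  if (L < 40 || L > 100) stop("tRNA sequence length outside [40, 100] nt: ", L)
  if (!is.null(expected)) expected <- norm_seq(expected)
  ch <- strsplit(s, "")[[1]]
  cand <- list()
  for (ls in seq_len(L - 6)) {
    le <- ls + 6L
    ## closing stem: pairs (ls-1-j, le+1+j)
    k <- 0L
    while (k < params$ac_stem_max) {
      i <- ls - 1L - k
      j <- le + 1L + k
      if (i < 1 || j > L || !base_pairs(ch[i], ch[j])) break
      k <- k + 1L
    }
    if (k < 2L) next
    ## room for at least an acceptor arm on both flanks
    if (ls - k <= params$acceptor_pairs) next
    if (le + k > L - params$acceptor_pairs) next
    ac <- substr(s, ls + 2L, ls + 4L)
    cand[[length(cand) + 1]] <- data.frame(
      anticodon_start = ls + 2L, loop_start = ls, stem_len = k,
      anticodon = ac,
      matches_expected = !is.null(expected) && ac == expected,
      stringsAsFactors = FALSE)
  }
  if (length(cand) == 0)
    return(data.frame(anticodon_start = integer(), loop_start = integer(),
                      stem_len = integer(), anticodon = character(),
                      matches_expected = logical()))
  d <- do.call(rbind, cand)
  centrality <- abs((d$loop_start + 3L) - (L + 1) / 2)
  d <- d[order(-d$matches_expected, -d$stem_len, centrality, d$loop_start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

## best strict stem-loop inside region [from, to]: stem p in [min_stem, max_stem]
## pairs, loop in [loop_min, loop_max]; tie-break longest stem then 5'-most
## then shortest loop.
find_arm <- function(ch, from, to, min_stem, max_stem, loop_min, loop_max) {
  best <- NULL
  if (to - from + 1 < 2 * min_stem + loop_min) return(NULL)
  for (p in seq(max_stem, min_stem)) {
    for (a in seq(from, to)) {
      if (a + p - 1 > to) break
      for (lam in seq(loop_min, loop_max)) {
        b <- a + p + lam
        if (b + p - 1 > to) break
        ok <- TRUE
        for (j in seq_len(p)) {
          if (!base_pairs(ch[a + j - 1], ch[b + p - j])) { ok <- FALSE; break }
        }
        if (ok) {
          cand <- list(stem = p, start = a, loop = lam)
          if (is.null(best)) best <- cand
          ## ordering guarantees: first hit at given p is 5'-most/shortest loop
        }
        if (!is.null(best)) break
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) break
  }
  best
}

#' Fold a tRNA sequence on the cloverleaf template
#'
#' Builds the acceptor stem from terminal complementarity (up to 7 pairs,
#' tolerating a bounded number of mismatches), anchors the anticodon arm at
#' the given position, then searches the region between acceptor 5' side
#' and anticodon stem for a D-arm and the region between anticodon stem and
#' acceptor 3' side for a T-arm.  An arm is present iff a strict stem-loop
#' fits (see package defaults); otherwise that region is recorded as a
#' replacement loop.
#'
#' @param seq Nucleotide string, 40-100 nt.
#' @param anticodon_pos 1-based position of the anticodon's first base.
#' @param params Folding thresholds.
#' @return An object of class \code{trna_structure}.
#' @export
fold_trna <- function(seq, anticodon_pos, params = trna_defaults()) {
  s <- norm_seq(seq)
  L <- nchar(s)
  if (L < 40 || L > 100) stop("tRNA sequence length outside [40, 100] nt: ", L)
  ch <- strsplit(s, "")[[1]]
  ls <- anticodon_pos - 2L
  le <- ls + 6L
  if (ls < 2 || le > L - 1) stop("anticodon position leaves no room for the anticodon arm")
  ## anticodon stem
  k <- 0L
  while (k < params$ac_stem_max) {
    i <- ls - 1L - k; j <- le + 1L + k
    if (i < 1 || j > L || !base_pairs(ch[i], ch[j])) break
    k <- k + 1L
  }
  if (k < 2L) stop("no anticodon stem (>= 2 bp) closes a 7-nt loop at position ",
                   anticodon_pos)
  ## acceptor stem: try 0 or 1 unpaired discriminator nt at the 3' end
  acc <- NULL
  for (d in 0:1) {
    if (L - d - params$acceptor_pairs + 1 <= le + k) next
    mism <- 0L
    pairs <- logical(params$acceptor_pairs)
    for (i in seq_len(params$acceptor_pairs)) {
      pairs[i] <- base_pairs(ch[i], ch[L - d + 1L - i])
      if (!pairs[i]) mism <- mism + 1L
    }
    if (is.null(acc) || mism < acc$mismatches)
      acc <- list(discriminator = d, paired = pairs, mismatches = mism)
  }
  if (is.null(acc)) stop("sequence too short for acceptor arm around the anticodon arm")
  d <- acc$discriminator
  ## arm regions
  d_from <- params$acceptor_pairs + 1L
  d_to <- ls - k - 1L
  t_from <- le + k + 1L
  t_to <- L - d - params$acceptor_pairs
  d_arm <- if (d_to >= d_from)
    find_arm(ch, d_from, d_to, params$min_arm_stem, params$d_stem_max,
             params$loop_min, params$loop_max) else NULL
  t_arm <- if (t_to >= t_from)
    find_arm(ch, t_from, t_to, params$min_arm_stem, params$t_stem_max,
             params$loop_min, params$loop_max) else NULL
  dec <- decode_anticodon(substr(s, anticodon_pos, anticodon_pos + 2L))
  n_pairs <- sum(acc$paired) + k +
    (if (!is.null(d_arm)) d_arm$stem else 0L) +
    (if (!is.null(t_arm)) t_arm$stem else 0L)
  out <- list(
    sequence = s,
    length = L,
    acceptor_stem = list(pairs = params$acceptor_pairs, paired = acc$paired,
                         mismatches = acc$mismatches, discriminator = d),
    anticodon_arm = list(stem = k, loop = 7L, loop_start = ls,
                         anticodon = substr(s, anticodon_pos, anticodon_pos + 2L),
                         anticodon_start = anticodon_pos),
    d_arm = list(present = !is.null(d_arm),
                 stem = if (!is.null(d_arm)) d_arm$stem else NA_integer_,
                 loop = if (!is.null(d_arm)) d_arm$loop else NA_integer_,
                 start = if (!is.null(d_arm)) d_arm$start else NA_integer_,
                 replacement_loop = if (is.null(d_arm)) max(0L, d_to - d_from + 1L) else NA_integer_),
    t_arm = list(present = !is.null(t_arm),
                 stem = if (!is.null(t_arm)) t_arm$stem else NA_integer_,
                 loop = if (!is.null(t_arm)) t_arm$loop else NA_integer_,
                 start = if (!is.null(t_arm)) t_arm$start else NA_integer_,
                 replacement_loop = if (is.null(t_arm)) max(0L, t_to - t_from + 1L) else NA_integer_),
    amino_acid = dec$aa, family = dec$family,
    total_score = params$pair_reward * n_pairs -
      params$mismatch_penalty * acc$mismatches)
  class(out) <- "trna_structure"
  out
}

#' Classify a folded tRNA structure
#'
#' @param structure A \code{trna_structure}.
#' @return One of \code{"cloverleaf"}, \code{"D-armless"},
#'   \code{"T-armless"}, \code{"armless"}.
#' @export
classify_trna <- function(structure) {
  stopifnot(inherits(structure, "trna_structure"))
  d <- structure$d_arm$present
  t <- structure$t_arm$present
  if (d && t) "cloverleaf" else if (!d && t) "D-armless"
  else if (d && !t) "T-armless" else "armless"
}

#' @export
print.trna_structure <- function(x, ...) {
  cat("<trna_structure> ", x$length, " nt, anticodon ", x$anticodon_arm$anticodon,
      " (", x$amino_acid, if (!is.na(x$family)) paste0(", ", x$family), "), ",
      classify_trna(x), "\n", sep = "")
  cat("  acceptor: ", sum(x$acceptor_stem$paired), "/", x$acceptor_stem$pairs,
      " bp (", x$acceptor_stem$mismatches, " mismatch)",
      "; AC stem ", x$anticodon_arm$stem, " bp",
      "; D ", if (x$d_arm$present) paste0(x$d_arm$stem, " bp stem") else
        paste0("absent (", x$d_arm$replacement_loop, " nt loop)"),
      "; T ", if (x$t_arm$present) paste0(x$t_arm$stem, " bp stem") else
        paste0("absent (", x$t_arm$replacement_loop, " nt loop)"), "\n", sep = "")
  invisible(x)
}

#' Paired positions of a folded structure
#'
#' All base pairs the fold asserts, for invariant checks and dot-bracket
#' rendering.  Every reported pair is Watson-Crick or GU and no base is
#' paired twice.
#' @param structure A \code{trna_structure}.
#' @return Two-column integer matrix of paired positions (i < j).
#' @export
trna_pairs <- function(structure) {
  x <- structure
  L <- x$length
  d <- x$acceptor_stem$discriminator
  out <- NULL
  for (i in seq_len(x$acceptor_stem$pairs)) {
    if (x$acceptor_stem$paired[i]) out <- rbind(out, c(i, L - d + 1L - i))
  }
  ls <- x$anticodon_arm$loop_start
  for (j in seq_len(x$anticodon_arm$stem)) {
    out <- rbind(out, c(ls - j, ls + 6L + j))
  }
  for (arm in list(x$d_arm, x$t_arm)) {
    if (isTRUE(arm$present)) {
      a <- arm$start; p <- arm$stem; b <- a + p + arm$loop
      for (j in seq_len(p)) out <- rbind(out, c(a + j - 1L, b + p - j))
    }
  }
  out[order(out[, 1]), , drop = FALSE]
}

#' Dot-bracket rendering of a folded tRNA
#' @param structure A \code{trna_structure}.
#' @return Character string of the same length as the sequence.
#' @export
trna_dot_bracket <- function(structure) {
  db <- rep(".", structure$length)
  p <- trna_pairs(structure)
  db[p[, 1]] <- "("
  db[p[, 2]] <- ")"
  paste(db, collapse = "")
}

#' Identify and fold a set of tRNA sequences
#'
#' Convenience wrapper: for each sequence, locates the anticodon (using the
#' family's expected anticodon when the family is known), folds, and
#' classifies.
#'
#' @param seqs Named character vector of sequences (names = family labels,
#'   e.g. \code{trnM}), or a FASTA path readable by \pkg{seqinr}.
#' @param params Folding thresholds.
#' @return Data frame with \code{family}, \code{length}, \code{anticodon},
#'   \code{amino_acid}, \code{classification}, \code{score} and a
#'   \code{structures} attribute holding the \code{trna_structure} objects.
#' @export
fold_trna_set <- function(seqs, params = trna_defaults()) {
  if (length(seqs) == 1 && file.exists(seqs[1])) {
    fa <- seqinr::read.fasta(seqs[1], as.string = TRUE, forceDNAtolower = FALSE)
    seqs <- stats::setNames(vapply(fa, as.character, ""), names(fa))
  }
  fams <- canonical_gene_name(names(seqs))
  structures <- vector("list", length(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    expected <- if (fams[i] %in% names(MT_ANTICODONS)) MT_ANTICODONS[[fams[i]]] else NULL
    cand <- locate_anticodon(seqs[[i]], expected = expected, params = params)
    if (nrow(cand) == 0)
      return(data.frame(family = fams[i], length = nchar(seqs[[i]]),
                        anticodon = NA_character_, amino_acid = NA_character_,
                        classification = NA_character_, score = NA_real_,
                        stringsAsFactors = FALSE))
    st <- fold_trna(seqs[[i]], cand$anticodon_start[1], params = params)
    structures[[i]] <<- st
    data.frame(family = fams[i], length = st$length,
               anticodon = st$anticodon_arm$anticodon, amino_acid = st$amino_acid,
               classification = classify_trna(st), score = st$total_score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "structures") <- stats::setNames(structures, fams)
  out
}

#' Summarise tRNA truncation across genomes
#'
#' @param per_genome Named list; one element per genome, each a data frame
#'   as returned by [fold_trna_set()] (columns \code{family},
#'   \code{classification}, \code{length}).
#' @return List with \code{counts} (genome x classification table including
#'   an \code{atypical} total), \code{family_pattern} (family x genome
#'   classification matrix), \code{shared_loss} (families lacking the same
#'   arm in every genome, split by arm) and \code{size_range}.
#' @export
truncation_summary <- function(per_genome) {
  if (length(per_genome) < 1) stop("need at least one genome")
  if (is.null(names(per_genome))) names(per_genome) <- paste0("genome", seq_along(per_genome))
  classes <- c("cloverleaf", "D-armless", "T-armless", "armless")
  counts <- t(vapply(per_genome, function(d) {
    v <- table(factor(d$classification, levels = classes))
    c(as.integer(v), atypical = sum(d$classification != "cloverleaf", na.rm = TRUE))
  }, integer(5)))
  colnames(counts) <- c(classes, "atypical")
  fams <- sort(unique(unlist(lapply(per_genome, `[[`, "family"))))
  pattern <- vapply(per_genome, function(d) {
    d$classification[match(fams, d$family)]
  }, character(length(fams)))
  pattern <- matrix(pattern, nrow = length(fams),
                    dimnames = list(fams, names(per_genome)))
  lacks_t <- apply(pattern, 1, function(x) all(x %in% c("T-armless", "armless")))
  lacks_d <- apply(pattern, 1, function(x) all(x %in% c("D-armless", "armless")))
  sizes <- range(unlist(lapply(per_genome, `[[`, "length")))
  list(counts = counts, family_pattern = pattern,
       shared_loss = list(T_arm = fams[lacks_t], D_arm = fams[lacks_d]),
       size_range = sizes)
}
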