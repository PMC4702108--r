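#' @keywords internal
"_PACKAGE"

## The 37-gene metazoan mitochondrial vocabulary: 13 protein-coding genes,
## 2 rRNAs and 22 tRNAs (leucine and serine each have two isoacceptors,
## distinguished as trnL1/trnL2 and trnS1/trnS2).  "CR" denotes the
## non-coding control region, which is carried as metadata and never takes
## part in gene-order comparisons.

MT_PCGS <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
             "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")

MT_RRNAS <- c("rrnL", "rrnS")

MT_TRNAS <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
              "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
              "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
              "trnY")

MT_GENES <- c(MT_PCGS, MT_RRNAS, MT_TRNAS)

## Standard metazoan mt tRNA anticodons (DNA alphabet, 5'->3').
MT_ANTICODONS <- c(
  trnA = "TGC", trnC = "GCA", trnD = "GTC", trnE = "TTC", trnF = "GAA",
  trnG = "TCC", trnH = "GTG", trnI = "GAT", trnK = "TTT", trnL1 = "TAG",
  trnL2 = "TAA", trnM = "CAT", trnN = "GTT", trnP = "TGG", trnQ = "TTG",
  trnR = "TCG", trnS1 = "TCT", trnS2 = "TGA", trnT = "TGT", trnV = "TAC",
  trnW = "TCA", trnY = "GTA")

#' Canonicalize a mitochondrial gene name
#'
#' Maps case and spelling variants onto the canonical 37-gene vocabulary
#' (plus \code{"CR"}).  Bare \code{trnL}/\code{trnS} are disambiguated into
#' the two isoacceptor families by their anticodon when one is supplied.
#'
#' @param name Character vector of gene labels.
#' @param anticodon Optional character vector of anticodons (3-mers, DNA
#'   alphabet) used to disambiguate \code{trnL}/\code{trnS}.
#' @return Character vector of canonical gene names.
#' @export
canonical_gene_name <- function(name, anticodon = NULL) {
  stopifnot(is.character(name))
  out <- character(length(name))
  lut <- stats::setNames(c(MT_GENES, "CR"), tolower(c(MT_GENES, "CR")))
  for (i in seq_along(name)) {
    raw <- gsub("\\s", "", name[i])
    key <- tolower(raw)
    key <- sub("^nad4l$", "nad4l", key)
    if (key %in% names(lut)) {
      out[i] <- lut[[key]]
      next
    }
    ac <- if (!is.null(anticodon)) toupper(gsub("U", "T", anticodon[i])) else NA_character_
    if (key %in% c("trnl", "l")) {
      if (identical(ac, "TAG")) { out[i] <- "trnL1"; next }
      if (identical(ac, "TAA")) { out[i] <- "trnL2"; next }
      stop("ambiguous leucine tRNA '", raw, "': supply anticodon TAG (trnL1) or TAA (trnL2)")
    }
    if (key %in% c("trns", "s")) {
      if (identical(ac, "TCT")) { out[i] <- "trnS1"; next }
      if (identical(ac, "TGA")) { out[i] <- "trnS2"; next }
      stop("ambiguous serine tRNA '", raw, "': supply anticodon TCT (trnS1) or TGA (trnS2)")
    }
    ## single-letter tRNA abbreviations as used on genome maps
    if (nchar(key) == 1 && toupper(raw) %in% sub("^trn", "", MT_TRNAS)) {
      out[i] <- paste0("trn", toupper(raw))
      next
    }
    stop("unknown gene label '", raw, "'; expected one of: ",
         paste(c(MT_GENES, "CR"), collapse = ", "))
  }
  out
}

#' Feature class of a canonical gene name
#'
#' @param gene Character vector of canonical gene names.
#' @return Character vector with values \code{"PCG"}, \code{"rRNA"},
#'   \code{"tRNA"} or \code{"CR"}.
#' @export
gene_class <- function(gene) {
  cls <- character(length(gene))
  cls[gene %in% MT_PCGS] <- "PCG"
  cls[gene %in% MT_RRNAS] <- "rRNA"
  cls[gene %in% MT_TRNAS] <- "tRNA"
  cls[gene == "CR"] <- "CR"
  if (any(cls == "")) stop("unknown gene label(s): ",
                           paste(gene[cls == ""], collapse = ", "))
  cls
}

## Strand symbols: J = majority/reading strand, N = opposite.  "+"/"-" are
## accepted as aliases on input; J/N is emitted.
normalize_strand <- function(strand) {
  s <- as.character(strand)
  s[s %in% c("+", "J", "j")] <- "J"
  s[s %in% c("-", "−", "N", "n")] <- "N"
  bad <- !(s %in% c("J", "N") | is.na(s) | s %in% c("", "."))
  if (any(bad)) stop("invalid strand symbol(s): ", paste(unique(s[bad]), collapse = ", "))
  s[s %in% c("", ".")] <- NA_character_
  s
}

## reverse complement, DNA alphabet
revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(strsplit(seq, ""), function(x) paste(rev(x), collapse = ""), ""))
}
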