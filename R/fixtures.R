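## Accessors for the fixture data shipped with the package: the two
## eriophyoid annotation tables, the hypothetical arthropod ancestral
## arrangement, a best-effort transcription of comparison arrangements for
## other mites (schematic; see file headers for provenance), and a working
## topology for the ancestral reconstruction.

#' Path to a packaged fixture file
#' @param name File name under \code{inst/extdata}.
#' @return Absolute path.
#' @export
mitoarch_file <- function(name) {
  p <- system.file("extdata", name, package = "mitoarch")
  if (p == "") stop("no packaged file named '", name, "'")
  p
}

#' Packaged eriophyoid annotation tables
#'
#' The mt genome organization tables of \emph{Phyllocoptes taishanensis}
#' (\code{"Pt"}) and \emph{Epitrimerus sabinae} (\code{"Es"}).
#' @param which \code{"Pt"} or \code{"Es"}.
#' @return A \code{genome_table}.
#' @export
fixture_genome_table <- function(which = c("Pt", "Es")) {
  which <- match.arg(which)
  f <- if (which == "Pt") "phyllocoptes_taishanensis.tsv" else "epitrimerus_sabinae.tsv"
  parse_gene_table(mitoarch_file(f))
}

#' The hypothetical arthropod ancestral gene arrangement
#'
#' The Limulus-type 37-gene arrangement used as rearrangement reference.
#' @return A \code{gene_order}.
#' @export
fixture_ancestor_order <- function() {
  read_arrangements(mitoarch_file("ancestor_arthropod.txt"))[[1]]
}

#' Packaged comparison arrangements (screen panel)
#'
#' Gene arrangements of other mites used to screen candidate
#' synapomorphies and to anchor the ancestral reconstruction.  These are
#' best-effort schematic transcriptions (see the file header); rows other
#' than the ancestral-type arrangements are not asserted in tests.
#' @return Named list of \code{gene_order} objects.
#' @export
fixture_screen_orders <- function() {
  read_arrangements(mitoarch_file("acariformes_screen.txt"))
}

#' Packaged working topology for the mite taxa
#' @return A rooted \code{phylo}.
#' @export
fixture_tree <- function() {
  ape::read.tree(mitoarch_file("acari_tree.nwk"))
}
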