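#' Read a dated species tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' gain/loss machinery relies on: unique leaf names and strictly positive
#' branch lengths (in millions of years).
#'
#' @param path Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort("could not parse Newick file")
  if (anyDuplicated(tr$tip.label)) abort("duplicate leaf names in tree")
  if (is.null(tr$edge.length) || any(tr$edge.length <= 0)) {
    abort("tree must have strictly positive branch lengths (MY)")
  }
  tr
}

#' Read an ortholog table
#'
#' A TSV with header columns `species`, `gene_id`, `ref_name` mapping each
#' species-local gene id to its reference-rooted gene symbol (the best
#' annotated model-organism name used to compare loci across species).
#'
#' @param path TSV path.
#' @return Tibble with those three columns.
#' @export
read_ortholog_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("species", "gene_id", "ref_name")
  if (!all(need %in% names(df))) {
    abort(paste("ortholog table must have columns:", paste(need, collapse = ", ")))
  }
  dup <- df |> dplyr::count(.data$species, .data$gene_id) |> dplyr::filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("ortholog table maps (%s, %s) to multiple reference names",
                  dup$species[1], dup$gene_id[1]))
  }
  df[, need]
}

#' Look up reference-rooted names for species-local gene ids
#'
#' @param map Ortholog tibble from [read_ortholog_table()].
#' @param species Single species name.
#' @param ids Character vector of local gene ids.
#' @return Character vector of reference names; unmapped ids yield the
#'   explicit `NA_character_` sentinel, never an empty string.
#' @export
ortholog_lookup <- function(map, species, ids) {
  sub <- map[map$species == species, , drop = FALSE]
  out <- sub$ref_name[match(ids, sub$gene_id)]
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

#' Read a two-column gene expression table (gene, value)
#'
#' @param path TSV with header `gene`, `value` (e.g. RPKM).
#' @return Tibble `gene`, `value`.
#' @export
read_expression_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(gene = "c", .default = "d"))
  if (!all(c("gene", "value") %in% names(df))) {
    abort("expression table must have columns gene, value")
  }
  df[, c("gene", "value")]
}

#' Read a library manifest
#'
#' The manifest records, per library, the total mapped reads used for RPM
#' normalization (library sizes come from mapping logs, never from the
#' coverage tracks, which may be strand subsets).
#'
#' @param path TSV with header including `species` and `library_size`.
#' @return Tibble.
#' @export
read_library_manifest <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols())
  if (!all(c("species", "library_size") %in% names(df))) {
    abort("manifest must have columns species, library_size")
  }
  df
}
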