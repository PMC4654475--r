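#' Read gene models from a BED12 file
#'
#' Parses a 12-column BED file into a gene-model tibble and derives the
#' 5'UTR / ORF-exon / 3'UTR segmentation of each transcript with respect to
#' its strand. Coordinates stay 0-based half-open throughout.
#'
#' The segmentation partitions the exonic bases exactly: every exon base
#' falls in exactly one of `utr5`, `orf`, `utr3`. Non-coding transcripts
#' (thickStart == thickEnd) carry all exonic bases in `utr3` on either
#' strand, so their whole length is assessed by the 3'UTR-based cluster
#' caller and they can be removed downstream by the ncRNA curation filter.
#'
#' @param path Path to a BED12 file.
#' @param names Optional named character vector mapping transcript ids
#'   (BED column 4) to reference-rooted gene symbols; defaults to the id.
#' @return A tibble with one row per gene: `chrom`, `start`, `end`, `id`,
#'   `name`, `score`, `strand`, `cds_start`, `cds_end`, and list-columns
#'   `exons`, `utr5`, `orf`, `utr3` of interval tibbles (`start`, `end`).
#'   Records with cds_start > cds_end are rejected with a warning.
#' @export
read_bed12 <- function(path, names = NULL) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(trimws(lines[idx]), "\t")
  nf <- lengths(parts)
  if (any(nf != 12)) {
    abort(sprintf("malformed BED12 line %d: expected 12 fields, got %d",
                  idx[which(nf != 12)[1]], nf[nf != 12][1]))
  }
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  df <- tibble(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    id = m[, 4],
    score = suppressWarnings(as.numeric(m[, 5])),
    strand = m[, 6],
    cds_start = as.integer(m[, 7]),
    cds_end = as.integer(m[, 8]),
    block_count = as.integer(m[, 10]),
    block_sizes = m[, 11],
    block_starts = m[, 12]
  )
  bad <- is.na(df$start) | is.na(df$end) | df$start >= df$end |
    !df$strand %in% c("+", "-", ".")
  if (any(bad)) abort(sprintf("malformed BED12 line %d", idx[which(bad)[1]]))
  rej <- df$cds_start > df$cds_end
  if (any(rej)) {
    warn(sprintf("rejected %d BED12 record(s) with cds_start > cds_end (first: %s)",
                 sum(rej), df$id[which(rej)[1]]))
    df <- df[!rej, , drop = FALSE]
  }
  exons <- purrr::pmap(
    list(df$start, df$block_sizes, df$block_starts, df$block_count),
    function(start, sizes, starts, n) {
      sz <- as.integer(strsplit(sizes, ",")[[1]])
      st <- as.integer(strsplit(starts, ",")[[1]])
      if (length(sz) != n || length(st) != n) abort("BED12 block fields disagree with blockCount")
      interval_tbl(start + st, start + st + sz)
    })
  df$exons <- exons
  df$block_count <- df$block_sizes <- df$block_starts <- NULL
  df$name <- if (is.null(names)) df$id else unname(names[df$id]) %||% df$id
  df$name <- dplyr::coalesce(df$name, df$id)
  segment_genes(df)
}

## Derive utr5/orf/utr3 list-columns from exons + CDS bounds.
segment_genes <- function(df) {
  seg <- purrr::pmap(list(df$exons, df$cds_start, df$cds_end, df$strand),
                     segment_one)
  df$utr5 <- purrr::map(seg, "utr5")
  df$orf <- purrr::map(seg, "orf")
  df$utr3 <- purrr::map(seg, "utr3")
  dplyr::arrange(df, .data$chrom, .data$start)
}

segment_one <- function(exons, cds_start, cds_end, strand) {
  empty <- interval_tbl(integer(0), integer(0))
  if (cds_start >= cds_end) {
    return(list(utr5 = empty, orf = empty, utr3 = exons))
  }
  left <- interval_clip(exons, -Inf, cds_start)
  orf <- interval_clip(exons, cds_start, cds_end)
  right <- interval_clip(exons, cds_end, Inf)
  if (strand == "-") list(utr5 = right, orf = orf, utr3 = left)
  else list(utr5 = left, orf = orf, utr3 = right)
}

#' Construct gene models from a plain tibble
#'
#' Convenience constructor used when gene models are built in code (e.g. by
#' the synthetic-data generator) rather than read from disk. Single-exon
#' genes may omit `exons`.
#'
#' @param df Tibble with `chrom`, `start`, `end`, `id`, `strand`,
#'   `cds_start`, `cds_end`, optional `name`, `score` and list-column
#'   `exons`.
#' @return A gene-model tibble as from [read_bed12()].
#' @export
as_gene_models <- function(df) {
  df <- as_tibble(df)
  if (!"exons" %in% names(df)) {
    df$exons <- purrr::map2(df$start, df$end, ~interval_tbl(.x, .y))
  }
  if (!"name" %in% names(df)) df$name <- df$id
  if (!"score" %in% names(df)) df$score <- 0
  segment_genes(df)
}

#' Write gene models as BED12
#'
#' @param genes A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(genes, path) {
  lines <- purrr::pmap_chr(
    list(genes$chrom, genes$start, genes$end, genes$id, genes$score,
         genes$strand, genes$cds_start, genes$cds_end, genes$exons),
    function(chrom, start, end, id, score, strand, cs, ce, ex) {
      sizes <- paste0(paste(ex$end - ex$start, collapse = ","), ",")
      starts <- paste0(paste(ex$start - start, collapse = ","), ",")
      paste(chrom, start, end, id, score, strand, cs, ce, "0",
            nrow(ex), sizes, starts, sep = "\t")
    })
  readr::write_lines(lines, path)
  invisible(path)
}
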