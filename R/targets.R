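## Antisense complementarity search from cluster piRNAs to transcript
## sequences, and the join against a differential-expression table.

#' Reverse complement of DNA/RNA sequences
#'
#' @param x Character vector over A/C/G/T/U/N (U treated as T).
#' @return Reverse-complemented sequences (DNA alphabet).
#' @export
revcomp <- function(x) {
  x <- chartr("Uu", "Tt", x)
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Find antisense complementarity matches of piRNAs against transcripts
#'
#' Reports every maximal exact reverse-complement match of at least
#' `min_len` nt between a piRNA and a transcript — i.e. sites where the
#' piRNA could base-pair with the transcript in antisense orientation.
#' This is the native, exact-match form of the short-query BLAST screen
#' whose effective criterion is at least 13 bp of complementarity between
#' piRNA and predicted target.
#'
#' @param pirnas Named character vector of piRNA sequences, or a tibble
#'   with `id`, `seq`.
#' @param transcripts Same, for transcript sequences.
#' @param min_len Minimum complementary stretch (default 13 nt).
#' @param max_mismatch Reserved; only 0 (exact) is implemented.
#' @return Tibble: `pirna`, `transcript`, `length`, `transcript_pos` and
#'   `pirna_offset` (1-based starts of the matched segments), ordered by
#'   (pirna, transcript, transcript_pos). The matched piRNA segment is
#'   the reverse complement of the matched transcript segment.
#' @export
antisense_matches <- function(pirnas, transcripts, min_len = 13L,
                              max_mismatch = 0L) {
  if (max_mismatch != 0) abort("only exact matching (max_mismatch = 0) is implemented")
  pirnas <- as_named_seqs(pirnas)
  transcripts <- as_named_seqs(transcripts)
  if (length(transcripts) == 0 || length(pirnas) == 0) {
    return(tibble(pirna = character(0), transcript = character(0),
                  length = integer(0), transcript_pos = integer(0),
                  pirna_offset = integer(0)))
  }
  res <- list()
  for (pi in names(pirnas)) {
    q <- revcomp(pirnas[[pi]])
    qv <- utf8ToInt(q)
    m <- length(qv)
    if (m < min_len) next
    for (tx in names(transcripts)) {
      tv <- utf8ToInt(chartr("Uu", "Tt", toupper(transcripts[[tx]])))
      n <- length(tv)
      if (n < min_len) next
      for (k in (-(m - min_len)):(n - min_len)) {
        i_lo <- max(1L, 1L - k)
        i_hi <- min(m, n - k)
        if (i_hi - i_lo + 1L < min_len) next
        eq <- qv[i_lo:i_hi] == tv[(i_lo + k):(i_hi + k)]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        hit <- which(r$values & r$lengths >= min_len)
        for (h in hit) {
          i <- i_lo + starts[h] - 1L
          j <- i_lo + ends[h] - 1L
          res[[length(res) + 1]] <- tibble(
            pirna = pi, transcript = tx, length = j - i + 1L,
            transcript_pos = i + k,
            pirna_offset = m - j + 1L)
        }
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(pirna = character(0), transcript = character(0),
                  length = integer(0), transcript_pos = integer(0),
                  pirna_offset = integer(0)))
  }
  dplyr::arrange(out, .data$pirna, .data$transcript, .data$transcript_pos)
}

as_named_seqs <- function(x) {
  if (is.data.frame(x)) return(setNames(toupper(x$seq), x$id))
  if (length(x) == 0) return(character(0))
  if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
  toupper(x)
}

#' Join antisense matches with a differential-expression table
#'
#' Aggregates matches per target gene and annotates them with fold-change
#' and significance from an upstream differential-expression analysis
#' (e.g. mutant vs heterozygote testes), classifying matched genes as
#' up- or down-regulated.
#'
#' @param matches Tibble from [antisense_matches()]; transcript ids are
#'   taken as gene names.
#' @param de_table Tibble with `gene`, `log2fc` and optionally `padj`.
#' @return Tibble per matched gene: `gene`, `n_matches`,
#'   `total_match_len`, `max_match_len`, `log2fc`, `padj` (if present),
#'   `direction` (`"up"`/`"down"`/`NA`). Genes absent from `de_table` are
#'   retained with missing fold-change (mismatches are logged, not fatal).
#' @export
join_with_expression <- function(matches, de_table) {
  agg <- matches |>
    dplyr::group_by(gene = .data$transcript) |>
    dplyr::summarise(n_matches = dplyr::n(),
                     total_match_len = sum(.data$length),
                     max_match_len = max(.data$length), .groups = "drop")
  missing <- setdiff(agg$gene, de_table$gene)
  if (length(missing) > 0) {
    message(sprintf("%d matched gene(s) absent from the DE table (kept with NA fold-change)",
                    length(missing)))
  }
  out <- dplyr::left_join(agg, de_table, by = "gene") |>
    dplyr::mutate(direction = dplyr::case_when(
      is.na(.data$log2fc) ~ NA_character_,
      .data$log2fc > 0 ~ "up",
      .data$log2fc < 0 ~ "down",
      TRUE ~ "flat"))
  out
}
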