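#' Read small-RNA sequences from FASTA or FASTQ
#'
#' @param path FASTA or FASTQ file (format sniffed from the first record).
#' @return Named character vector of sequences, uppercased, U kept as-is.
#' @export
read_reads <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readBStringSet(path, format = fmt)
  toupper(setNames(as.character(x), names(x)))
}

#' Read-length spectrum of a small-RNA library
#'
#' piRNA libraries are expected to show a main read-length distribution of
#' 23-32 nt; within that, Drosophilid piRNAs peak at 24-28 nt and mammalian
#' piRNAs at 24-31 nt. The spectrum and the fraction of reads inside the
#' declared window are the first library QC.
#'
#' @param reads Character vector of read sequences (15-50 nt).
#' @param window Length-2 integer vector, the declared piRNA window in nt.
#'   Defaults to the 23-32 nt library-QC window; see [clade_preset()] for
#'   the per-clade calling windows.
#' @return A tibble of class `length_spectrum` with columns `length`,
#'   `count`, `fraction`; attributes `window`, `frac_in_window`, `n_reads`.
#' @export
length_spectrum <- function(reads, window = c(23L, 32L)) {
  if (length(reads) == 0) abort("no reads supplied")
  len <- nchar(reads)
  tab <- tibble(length = as.integer(names(table(len))),
                count = as.integer(table(len)))
  tab$fraction <- tab$count / sum(tab$count)
  in_win <- sum(tab$count[tab$length >= window[1] & tab$length <= window[2]]) /
    sum(tab$count)
  structure(tab, class = c("length_spectrum", class(tab)),
            window = window, frac_in_window = in_win, n_reads = length(reads))
}

#' 5'-nucleotide composition
#'
#' Primary piRNAs carry a strong bias for uridine at the 5' nucleotide
#' (1U bias); this reports the 5'-base fractions. U and T are treated
#' identically; N starts are excluded from the fractions and counted.
#'
#' @param reads Character vector of read sequences.
#' @return Tibble `base` (A, C, G, U), `count`, `fraction` (sums to 1);
#'   attribute `n_excluded` counts non-ACGTU starts.
#' @export
five_prime_composition <- function(reads) {
  if (length(reads) == 0) abort("no reads supplied")
  first <- toupper(substr(reads, 1, 1))
  first[first == "T"] <- "U"
  ok <- first %in% c("A", "C", "G", "U")
  if (!any(ok)) abort("no reads start with an unambiguous base")
  counts <- table(factor(first[ok], levels = c("A", "C", "G", "U")))
  out <- tibble(base = names(counts), count = as.integer(counts),
                fraction = as.integer(counts) / sum(counts))
  structure(out, n_excluded = sum(!ok))
}

#' RPM / RPKM / housekeeping normalization
#'
#' Counts are normalized to mapping library size (RPM = count * 1e6 /
#' library_size), then to region length (RPKM = RPM * 1e3 / length_bp), and
#' finally each gene is expressed as a unitless ratio to a housekeeping
#' gene's RPKM (RpL32 in mammals and flies, where it is also known as Rp49),
#' which makes expression comparable across species and platforms.
#'
#' @param df Tibble with columns `gene`, `count`, `length_bp`.
#' @param library_size Total mapped reads (> 0).
#' @param housekeeping Name of the housekeeping gene in `df`, or `NULL` to
#'   skip the ratio.
#' @return `df` with added columns `rpm`, `rpkm` and (if requested) `norm`.
#' @export
normalize_expression <- function(df, library_size, housekeeping = NULL) {
  if (library_size <= 0) abort("library_size must be > 0")
  if (any(df$length_bp <= 0)) abort("length_bp must be > 0")
  out <- df |>
    dplyr::mutate(rpm = rpm(.data$count, library_size),
                  rpkm = .data$rpm * 1e3 / .data$length_bp)
  if (!is.null(housekeeping)) {
    hk <- out$rpkm[out$gene == housekeeping]
    if (length(hk) != 1 || is.na(hk) || hk <= 0) {
      abort("housekeeping gene absent or has zero RPKM; cannot normalize")
    }
    out$norm <- out$rpkm / hk
  }
  out
}
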