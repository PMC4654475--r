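#' Strand-specific per-base coverage track
#'
#' A coverage track holds sparse per-base read counts for one strand of one
#' small-RNA library: a tibble with columns `chrom`, `pos` (0-based) and
#' `count`, carrying the strand and the library size (total mapped reads of
#' the whole library, used for RPM normalization) as attributes. Counts are
#' by default read 5'-end tallies, the quantity piRNA cluster calling is
#' based on; per-base pileup tracks can be stored the same way
#' (`count_mode = "cover"`).
#'
#' @param df Data frame with columns `chrom`, `pos`, `count`. Duplicate
#'   positions are summed.
#' @param strand `"+"` or `"-"`.
#' @param library_size Total mapped reads of the library. Never inferred from
#'   the track itself, because a track may be a strand- or region-subset of
#'   the library.
#' @param assembly Optional assembly label.
#' @param count_mode `"five_prime"` (default) or `"cover"`.
#' @return A `coverage_track` tibble sorted by chrom, pos.
#' @export
coverage_track <- function(df, strand, library_size, assembly = NA_character_,
                           count_mode = c("five_prime", "cover")) {
  count_mode <- match.arg(count_mode)
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (!is.numeric(library_size) || length(library_size) != 1 || library_size <= 0) {
    abort("library_size must be a single positive number")
  }
  df <- as_tibble(df)[, c("chrom", "pos", "count")]
  if (any(df$count < 0)) abort("coverage counts must be >= 0")
  df <- df |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$pos)
  structure(df,
            class = c("coverage_track", class(df)),
            strand = strand, library_size = library_size,
            assembly = assembly, count_mode = count_mode)
}

track_strand <- function(track) attr(track, "strand")

#' @export
#' @rdname coverage_track
library_size <- function(track) attr(track, "library_size")

#' Reads-per-million normalization
#'
#' @param count Raw read count(s).
#' @param library_size Total mapped reads.
#' @return `count * 1e6 / library_size`.
#' @export
rpm <- function(count, library_size) count * 1e6 / library_size

#' Sum track counts over genomic intervals
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param track A [coverage_track()].
#' @return Numeric vector of per-interval count sums (same order as rows).
#' @export
count_in_intervals <- function(intervals, track) {
  n <- nrow(intervals)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  for (ch in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == ch)
    sel <- track$chrom == ch
    if (!any(sel)) next
    pos <- track$pos[sel]
    cs <- c(0, cumsum(track$count[sel]))
    hi <- findInterval(intervals$end[idx] - 0.5, pos)
    lo <- findInterval(intervals$start[idx] - 0.5, pos)
    out[idx] <- cs[hi + 1] - cs[lo + 1]
  }
  out
}

## Sum counts over a list-column of interval tibbles (per-gene segments),
## restricted to one chromosome each.
count_in_segments <- function(chrom, segments, track) {
  vapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    if (is.null(seg) || nrow(seg) == 0) return(0)
    sum(count_in_intervals(tibble(chrom = chrom[i], start = seg$start, end = seg$end),
                           track))
  }, numeric(1))
}

#' Read a coverage file (bedGraph or WIG)
#'
#' Reconstructs per-base counts from a bedGraph or a WIG
#' (fixedStep/variableStep) file. bedGraph intervals are expanded to single
#' bases; WIG `span` fields are honored and WIG's 1-based coordinates are
#' shifted to the package-wide 0-based convention on read.
#'
#' @param path File path.
#' @inheritParams coverage_track
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path, strand, library_size, assembly = NA_character_,
                          count_mode = c("five_prime", "cover")) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  is_wig <- any(grepl("^(fixedStep|variableStep)", lines))
  df <- if (is_wig) parse_wig(lines, keep) else parse_bedgraph(lines, keep)
  if (any(df$count < 0)) abort("negative coverage values")
  coverage_track(df, strand = strand, library_size = library_size,
                 assembly = assembly, count_mode = match.arg(count_mode))
}

parse_bedgraph <- function(lines, keep) {
  idx <- which(keep)
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 4)) {
    abort(sprintf("malformed bedGraph line %d: expected 4 fields, got %d",
                  idx[which(nf != 4)[1]], nf[nf != 4][1]))
  }
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  val <- suppressWarnings(as.numeric(m[, 4]))
  bad <- is.na(start) | is.na(end) | is.na(val) | start >= end
  if (any(bad)) abort(sprintf("malformed bedGraph line %d", idx[which(bad)[1]]))
  w <- end - start
  tibble(chrom = rep(m[, 1], w),
         pos = sequence(w) - 1L + rep(start, w),
         count = rep(val, w))
}

parse_wig <- function(lines, keep) {
  chroms <- character(0); poss <- integer(0); vals <- numeric(0)
  mode <- NA_character_; chrom <- NA_character_
  start <- NA_integer_; step <- 1L; span <- 1L; i_fixed <- 0L
  for (li in which(keep)) {
    ln <- trimws(lines[li])
    if (grepl("^(fixedStep|variableStep)", ln)) {
      kv <- wig_header_fields(ln)
      mode <- sub("\\s.*", "", ln)
      chrom <- kv[["chrom"]]
      span <- as.integer(kv[["span"]] %||% "1")
      if (mode == "fixedStep") {
        start <- as.integer(kv[["start"]])
        step <- as.integer(kv[["step"]] %||% "1")
        i_fixed <- 0L
      }
      if (is.na(chrom)) abort(sprintf("malformed WIG header line %d", li))
      next
    }
    if (is.na(mode)) abort(sprintf("WIG data line %d before any step header", li))
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (mode == "variableStep") {
      if (length(f) != 2) abort(sprintf("malformed variableStep line %d", li))
      p1 <- as.integer(f[1]); v <- as.numeric(f[2])
      if (is.na(p1) || is.na(v)) abort(sprintf("malformed variableStep line %d", li))
      p0 <- p1 - 1L  # 1-based -> 0-based
    } else {
      if (length(f) != 1) abort(sprintf("malformed fixedStep line %d", li))
      v <- as.numeric(f[1])
      if (is.na(v)) abort(sprintf("malformed fixedStep line %d", li))
      p0 <- start - 1L + i_fixed * step
      i_fixed <- i_fixed + 1L
    }
    chroms <- c(chroms, rep(chrom, span))
    poss <- c(poss, p0 + seq_len(span) - 1L)
    vals <- c(vals, rep(v, span))
  }
  tibble(chrom = chroms, pos = poss, count = vals)
}

wig_header_fields <- function(ln) {
  f <- strsplit(ln, "\\s+")[[1]][-1]
  kv <- strsplit(f, "=")
  setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

#' Write a coverage track as bedGraph
#'
#' Consecutive equal-count bases are collapsed into intervals.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (nrow(track) == 0) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  df <- as_tibble(track) |> dplyr::arrange(.data$chrom, .data$pos)
  new_run <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                 df$pos[-1] != df$pos[-nrow(df)] + 1L |
                 df$count[-1] != df$count[-nrow(df)])
  run <- cumsum(new_run)
  out <- df |>
    dplyr::group_by(run = run) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$pos),
                     end = max(.data$pos) + 1L, count = .data$count[1],
                     .groups = "drop")
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s", out$chrom, out$start, out$end,
            format(out$count, trim = TRUE, scientific = FALSE)),
    path)
  invisible(path)
}
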