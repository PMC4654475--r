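## Gene-centric piC calling: count piRNAs over 5'UTR / ORF / 3'UTR with
## conditional UTR extension, then apply RPM thresholds and curation filters.

#' Compute the conditional UTR extension of one gene end
#'
#' Annotated UTRs often miss the true transcript end, so the caller extends
#' a UTR window-by-window: a window of `window_bp` (2000 bp for mammals,
#' 500 bp for Drosophilids) is appended whenever it holds at least
#' `min_rpm` of same-strand reads, and extension stops at the first failing
#' window, at the next same-strand annotated gene, at the chromosome end,
#' or after `max_windows` windows.
#'
#' @param from 0-based boundary position to extend from.
#' @param direction `+1` to extend rightwards, `-1` leftwards.
#' @param chrom Chromosome of the gene.
#' @param track Same-strand [coverage_track()].
#' @param window_bp Window size in bp.
#' @param min_rpm Minimum same-strand RPM a window must hold (default 1).
#' @param bound Hard coordinate bound (next same-strand gene or chromosome
#'   end); `NA` for unbounded.
#' @param max_windows Cap on appended windows.
#' @return Extension length in bp (0 if the first window fails).
#' @export
utr_extension <- function(from, direction, chrom, track, window_bp,
                          min_rpm = 1, bound = NA, max_windows = 5L) {
  lib <- library_size(track)
  avail <- if (is.na(bound)) Inf else max(0, direction * (bound - from))
  ext <- 0
  for (k in seq_len(max_windows)) {
    lo <- ext
    hi <- min(ext + window_bp, avail)
    if (hi <= lo) break
    win <- if (direction > 0) {
      tibble(chrom = chrom, start = from + lo, end = from + hi)
    } else {
      tibble(chrom = chrom, start = from - hi, end = from - lo)
    }
    if (rpm(count_in_intervals(win, track), lib) >= min_rpm) {
      ext <- hi
      if (ext >= avail) break
    } else break
  }
  as.integer(ext)
}

## Next same-strand gene boundary on each side, per gene. Returns tibble
## with columns bound_up (max end of a same-strand gene left of start) and
## bound_down (min start of a same-strand gene right of end); NA if none.
neighbor_bounds <- function(genes) {
  n <- nrow(genes)
  up <- rep(NA_integer_, n)
  down <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    same <- genes$chrom == genes$chrom[i] & genes$strand == genes$strand[i] &
      seq_len(n) != i
    le <- genes$end[same & genes$end <= genes$start[i]]
    rs <- genes$start[same & genes$start >= genes$end[i]]
    if (length(le)) up[i] <- max(le)
    if (length(rs)) down[i] <- min(rs)
  }
  tibble(bound_up = up, bound_down = down)
}

#' Count piRNA reads over gene regions
#'
#' Counts reads on the mRNA strand only, over the exon-partition segments
#' (5'UTR, ORF exons, 3'UTR) of each gene, with the conditional 3'UTR (and
#' 5'UTR) extension applied. The 5'UTR extension is computed and reported
#' but plays no role in cluster retention, which is a 3'UTR rule.
#'
#' @param genes Gene-model tibble from [read_bed12()] / [as_gene_models()].
#' @param plus_track,minus_track [coverage_track()]s for the two strands.
#' @param window_bp Extension window (2000 mammal, 500 fly); see
#'   [clade_preset()].
#' @param min_ext_rpm RPM a window needs to extend (default 1).
#' @param max_windows Extension cap (default 5 windows).
#' @param extend Set `FALSE` to skip UTR extension.
#' @param chrom_sizes Optional named vector of chromosome lengths; bounds
#'   extension at contig ends.
#' @return Tibble: gene columns plus `utr5_count`, `orf_count`,
#'   `utr3_count`, the matching `_rpm` columns, `utr3_ext_bp`,
#'   `utr5_ext_bp`, and `utr3_len` (annotated + extension).
#' @export
count_gene_regions <- function(genes, plus_track, minus_track,
                               window_bp = 2000L, min_ext_rpm = 1,
                               max_windows = 5L, extend = TRUE,
                               chrom_sizes = NULL) {
  lib <- library_size(plus_track)
  if (!isTRUE(all.equal(lib, library_size(minus_track)))) {
    abort("plus and minus tracks disagree on library_size")
  }
  bounds <- neighbor_bounds(genes)
  n <- nrow(genes)
  utr3_ext <- utr5_ext <- integer(n)
  utr5_cnt <- orf_cnt <- utr3_cnt <- numeric(n)
  utr3_len <- integer(n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    tr <- if (g$strand == "+") plus_track else minus_track
    chrlen <- if (!is.null(chrom_sizes)) unname(chrom_sizes[g$chrom]) else NA
    min_na <- function(...) {
      v <- c(...); v <- v[!is.na(v)]
      if (length(v) == 0) NA_integer_ else min(v)
    }
    ## 3' end and 5' end in genomic coordinates, direction of extension
    if (g$strand == "+") {
      b3 <- min_na(bounds$bound_down[i], chrlen); d3 <- +1; from3 <- g$end
      b5 <- max(bounds$bound_up[i], 0, na.rm = TRUE); d5 <- -1; from5 <- g$start
    } else {
      b3 <- max(bounds$bound_up[i], 0, na.rm = TRUE); d3 <- -1; from3 <- g$start
      b5 <- min_na(bounds$bound_down[i], chrlen); d5 <- +1; from5 <- g$end
    }
    if (extend) {
      utr3_ext[i] <- utr_extension(from3, d3, g$chrom, tr, window_bp,
                                   min_ext_rpm, b3, max_windows)
      utr5_ext[i] <- utr_extension(from5, d5, g$chrom, tr, window_bp,
                                   min_ext_rpm, b5, max_windows)
    }
    utr3 <- g$utr3[[1]]
    if (utr3_ext[i] > 0) {
      ext_iv <- if (d3 > 0) interval_tbl(from3, from3 + utr3_ext[i])
                else interval_tbl(from3 - utr3_ext[i], from3)
      utr3 <- dplyr::bind_rows(utr3, ext_iv)
    }
    utr5_cnt[i] <- count_in_segments(g$chrom, g$utr5, tr)
    orf_cnt[i] <- count_in_segments(g$chrom, g$orf, tr)
    utr3_cnt[i] <- count_in_segments(g$chrom, list(utr3), tr)
    utr3_len[i] <- interval_width(utr3)
  }
  genes |>
    dplyr::mutate(utr5_count = utr5_cnt, orf_count = orf_cnt,
                  utr3_count = utr3_cnt,
                  utr5_rpm = rpm(utr5_cnt, lib), orf_rpm = rpm(orf_cnt, lib),
                  utr3_rpm = rpm(utr3_cnt, lib),
                  utr5_ext_bp = utr5_ext, utr3_ext_bp = utr3_ext,
                  utr3_len = utr3_len)
}

#' Call genic piRNA cluster loci
#'
#' A gene is retained as a genic piC locus when its 3'UTR holds at least
#' `genic_min_rpm` RPM of piRNA reads in the same strand orientation as the
#' mRNA (default 10 RPM; 20 RPM is the twice-as-stringent mode). Genes
#' whose ORF additionally carries at least `orf_min_rpm` RPM (default 50)
#' are flagged `orf_retained` — in mammals a few percent of genic piCs also
#' produce abundant ORF piRNAs.
#'
#' @inheritParams count_gene_regions
#' @param genic_min_rpm Retention threshold on same-strand 3'UTR RPM
#'   (inclusive).
#' @param orf_min_rpm Threshold for the `orf_retained` flag.
#' @param clade `"mammal"` or `"fly"`; sets `window_bp` unless given.
#' @param keep_all Return non-passing genes too (with `kept = FALSE`).
#' @param ... Passed on to [count_gene_regions()].
#' @return Tibble of called loci ordered by (chrom, start), with region
#'   counts/RPMs, `kept`, `orf_retained`, `status` (`"kept"`) and `reason`
#'   (`NA`; filled by [apply_curation_filters()]).
#' @export
call_genic_pics <- function(genes, plus_track, minus_track,
                            genic_min_rpm = 10, orf_min_rpm = 50,
                            clade = c("mammal", "fly"),
                            window_bp = NULL, keep_all = FALSE, ...) {
  clade <- match.arg(clade)
  if (is.null(window_bp)) window_bp <- clade_preset(clade)$utr_window_bp
  counts <- count_gene_regions(genes, plus_track, minus_track,
                               window_bp = window_bp, ...)
  out <- counts |>
    dplyr::mutate(kept = .data$utr3_rpm >= genic_min_rpm,
                  orf_retained = .data$orf_rpm >= orf_min_rpm,
                  status = ifelse(.data$kept, "kept", "below_threshold"),
                  reason = NA_character_) |>
    dplyr::arrange(.data$chrom, .data$start)
  if (keep_all) out else dplyr::filter(out, .data$kept)
}

#' Curate called genic piC loci
#'
#' Quantified version of the study-style manual grooming of genic piC
#' candidate lists. A candidate is removed, with a machine-readable reason,
#' when
#' * `TE_overlap`: at least `te_frac` of its same-strand 3'UTR signal lies
#'   inside annotated repeat intervals (signal ambiguously attributable to
#'   a nearby transposable element);
#' * `neighbor_gene_source`: at least `neighbor_frac` of that signal lies
#'   inside another same-strand gene's body (the neighbor is the real
#'   source);
#' * `duplicate_name`: a second candidate with the same gene name (first
#'   occurrence kept);
#' * `ncRNA_pattern`: the name matches an ncRNA identifier pattern (e.g.
#'   mouse RefSeq "Gm####" models);
#' * `blacklist_family`: the name starts with a blacklisted family prefix
#'   (histones, olfactory receptors, zinc-finger genes and similar
#'   repetitive-domain families whose homolog alignments are unreliable).
#'
#' @param pics Output of [call_genic_pics()].
#' @param plus_track,minus_track The coverage tracks used for calling.
#' @param genes Full gene-model tibble (for the neighbor rule).
#' @param te_annotation Optional repeat BED tibble (`chrom`,`start`,`end`).
#' @param family_blacklist Character vector of name prefixes.
#' @param ncrna_patterns Regexes flagging ncRNA identifiers.
#' @param te_frac,neighbor_frac Signal fractions that trigger removal.
#' @return `pics` with updated `status` / `reason`.
#' @export
apply_curation_filters <- function(pics, plus_track, minus_track, genes,
                                   te_annotation = NULL,
                                   family_blacklist = character(),
                                   ncrna_patterns = "^[Gg][Mm][0-9]+$",
                                   te_frac = 0.5, neighbor_frac = 0.5) {
  n <- nrow(pics)
  if (n == 0) return(pics)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- pics[i, ]
    tr <- if (g$strand == "+") plus_track else minus_track
    utr3 <- g$utr3[[1]]
    if (g$utr3_ext_bp > 0) {
      ext_iv <- if (g$strand == "+") {
        interval_tbl(g$end, g$end + g$utr3_ext_bp)
      } else interval_tbl(g$start - g$utr3_ext_bp, g$start)
      utr3 <- dplyr::bind_rows(utr3, ext_iv)
    }
    iv <- tibble(chrom = g$chrom, start = utr3$start, end = utr3$end)
    total <- sum(count_in_intervals(iv, tr))
    if (total <= 0) next
    signal_in <- function(regions) {
      if (is.null(regions) || nrow(regions) == 0) return(0)
      sub <- regions[regions$chrom == g$chrom, , drop = FALSE]
      if (nrow(sub) == 0) return(0)
      s <- 0
      for (j in seq_len(nrow(iv))) {
        cl <- interval_clip(sub[, c("start", "end")], iv$start[j], iv$end[j])
        if (nrow(cl)) {
          s <- s + sum(count_in_intervals(
            tibble(chrom = g$chrom, start = cl$start, end = cl$end), tr))
        }
      }
      s
    }
    if (!is.null(te_annotation) && signal_in(te_annotation) / total >= te_frac) {
      reason[i] <- "TE_overlap"
      next
    }
    others <- genes[genes$id != g$id & genes$strand == g$strand, , drop = FALSE]
    if (nrow(others) > 0 &&
        signal_in(others[, c("chrom", "start", "end")]) / total >= neighbor_frac) {
      reason[i] <- "neighbor_gene_source"
    }
  }
  dup <- duplicated(pics$name)
  reason[dup & is.na(reason)] <- "duplicate_name"
  nc <- Reduce(`|`, lapply(ncrna_patterns, function(p) grepl(p, pics$name)))
  reason[nc & is.na(reason)] <- "ncRNA_pattern"
  if (length(family_blacklist) > 0) {
    bl <- Reduce(`|`, lapply(family_blacklist, function(p) {
      startsWith(tolower(pics$name), tolower(p))
    }))
    reason[bl & is.na(reason)] <- "blacklist_family"
  }
  pics$reason <- reason
  pics$status <- ifelse(is.na(reason), pics$status, "removed")
  pics
}
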