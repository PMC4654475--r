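## Per-base conservation-score averaging over gene segments, structural
## element counting, and selection of length-matched negative-control genes.

#' Build a per-base score track
#'
#' @param df Tibble with `chrom`, `pos` (0-based), `score` (phastCons in
#'   `[0,1]` or unbounded phyloP).
#' @param assembly Optional label.
#' @return Sorted tibble of class `score_track`.
#' @export
score_track <- function(df, assembly = NA_character_) {
  df <- as_tibble(df)[, c("chrom", "pos", "score")]
  if (anyDuplicated(df[, c("chrom", "pos")])) abort("duplicate score positions")
  df <- dplyr::arrange(df, .data$chrom, .data$pos)
  structure(df, class = c("score_track", class(df)), assembly = assembly)
}

sum_in_intervals <- function(intervals, chrom, pos, value) {
  n <- nrow(intervals)
  out <- numeric(n)
  for (ch in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == ch)
    sel <- chrom == ch
    if (!any(sel)) next
    p <- pos[sel]
    cs <- c(0, cumsum(value[sel]))
    hi <- findInterval(intervals$end[idx] - 0.5, p)
    lo <- findInterval(intervals$start[idx] - 0.5, p)
    out[idx] <- cs[hi + 1] - cs[lo + 1]
  }
  out
}

#' Mean conservation score over intervals
#'
#' Per-base score values are summed over each interval group and averaged
#' by base length. Bases absent from the track count as 0 by default (the
#' convention of genome-wide phastCons dumps, where absent means
#' unscored/unconserved); `missing = "exclude"` divides by covered bases
#' only, which is the safer choice for phyloP.
#'
#' @param intervals Tibble `chrom`, `start`, `end`, optional `group`
#'   (means are per group; otherwise per row).
#' @param track A [score_track()].
#' @param missing `"zero"` (default) or `"exclude"`.
#' @return Tibble `group`, `bases`, `covered`, `mean_score`.
#' @export
interval_mean_score <- function(intervals, track, missing = c("zero", "exclude")) {
  missing <- match.arg(missing)
  if (nrow(intervals) == 0) abort("no intervals supplied")
  if (!"group" %in% names(intervals)) {
    intervals$group <- as.character(seq_len(nrow(intervals)))
  }
  ssum <- sum_in_intervals(intervals, track$chrom, track$pos, track$score)
  cov <- sum_in_intervals(intervals, track$chrom, track$pos,
                          rep(1, nrow(track)))
  intervals |>
    dplyr::mutate(.ssum = ssum, .cov = cov) |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(
      bases = sum(.data$end - .data$start),
      covered = sum(.data$.cov),
      mean_score = if (missing == "zero") sum(.data$.ssum) / sum(.data$end - .data$start)
                   else sum(.data$.ssum) / max(sum(.data$.cov), 1),
      .groups = "drop")
}

#' Count structural elements over ORF and 3'UTR segments per gene set
#'
#' Counts externally predicted conserved RNA structural elements (BED
#' intervals) overlapping the ORF exons and the 3'UTR of each gene, then
#' compares sets (e.g. genic piC loci vs negative-control genes) by the
#' per-gene element counts with a Mann-Whitney test. An element spanning
#' an ORF/3'UTR boundary counts once in each segment it overlaps.
#'
#' @param elements Tibble `chrom`, `start`, `end`.
#' @param gene_sets Named list of gene-model tibbles.
#' @return List: `per_gene` (set, id, `orf_elements`, `utr3_elements`),
#'   `summary` (set x region mean counts), `tests` (pairwise
#'   Mann-Whitney p-values per region).
#' @export
count_elements <- function(elements, gene_sets) {
  count_over <- function(gene_chrom, segs) {
    vapply(seq_along(segs), function(i) {
      seg <- segs[[i]]
      if (is.null(seg) || nrow(seg) == 0) return(0L)
      iv <- tibble(chrom = gene_chrom[i], start = seg$start, end = seg$end)
      ee <- elements[elements$chrom == gene_chrom[i], , drop = FALSE]
      if (nrow(ee) == 0) return(0L)
      hit <- vapply(seq_len(nrow(ee)), function(j) {
        any(iv$start < ee$end[j] & iv$end > ee$start[j])
      }, logical(1))
      sum(hit)
    }, integer(1))
  }
  per_gene <- purrr::imap(gene_sets, function(genes, set) {
    tibble(set = set, id = genes$id,
           orf_elements = count_over(genes$chrom, genes$orf),
           utr3_elements = count_over(genes$chrom, genes$utr3))
  }) |> dplyr::bind_rows()
  summary <- per_gene |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(orf_mean = mean(.data$orf_elements),
                     utr3_mean = mean(.data$utr3_elements), .groups = "drop")
  sets <- names(gene_sets)
  tests <- NULL
  if (length(sets) >= 2) {
    prs <- utils::combn(sets, 2)
    tests <- purrr::map(seq_len(ncol(prs)), function(j) {
      a <- per_gene[per_gene$set == prs[1, j], ]
      b <- per_gene[per_gene$set == prs[2, j], ]
      safe_wilcox <- function(x, y) {
        if (length(unique(c(x, y))) < 2) return(1)  # no variation, no difference
        stats::wilcox.test(x, y, exact = FALSE)$p.value
      }
      tibble(set_a = prs[1, j], set_b = prs[2, j],
             region = c("orf", "utr3"),
             p = c(safe_wilcox(a$orf_elements, b$orf_elements),
                   safe_wilcox(a$utr3_elements, b$utr3_elements)))
    }) |> dplyr::bind_rows()
  }
  list(per_gene = per_gene, summary = summary, tests = tests)
}

#' Select length-matched negative-control genes
#'
#' Draws `multiplier` times as many control genes as there are genic piC
#' loci (to diminish selection bias) from expressed genes that produce no
#' piRNAs, then pads each control's 3'UTR within `pad_range` (fly 250-500,
#' mouse 500-1100 bp) toward the mean piC 3'UTR length, truncating the pad
#' where it would run into a same-strand neighboring gene.
#'
#' @param genes Gene-model tibble (the candidate pool universe).
#' @param pic_genes Gene-model tibble of called genic piCs (needs
#'   `utr3_len` if extensions apply, else annotated 3'UTR length is used).
#' @param multiplier Controls per piC gene (default 3).
#' @param pad_range Length-2 numeric, clade padding bounds in bp.
#' @param expressed Optional character vector of expressed gene ids the
#'   pool is restricted to.
#' @param seed Optional integer for reproducible sampling.
#' @return Tibble of controls: gene columns plus `utr3_len`, `pad_bp`,
#'   `utr3_len_padded`, `pad_truncated`; attribute `partial` is `TRUE`
#'   when the pool was smaller than requested.
#' @export
select_negative_controls <- function(genes, pic_genes, multiplier = 3,
                                     pad_range = c(500, 1100),
                                     expressed = NULL, seed = NULL) {
  pool <- genes[!genes$id %in% pic_genes$id, , drop = FALSE]
  if (!is.null(expressed)) pool <- pool[pool$id %in% expressed, , drop = FALSE]
  n_req <- multiplier * nrow(pic_genes)
  partial <- nrow(pool) < n_req
  if (partial) warn(sprintf("control pool (%d) smaller than requested (%d)",
                            nrow(pool), n_req))
  pick <- local({
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    sample(nrow(pool), min(n_req, nrow(pool)))
  })
  ctl <- pool[sort(pick), , drop = FALSE]
  target_len <- mean(if ("utr3_len" %in% names(pic_genes)) pic_genes$utr3_len
                     else vapply(pic_genes$utr3, interval_width, numeric(1)))
  bounds <- neighbor_bounds(ctl)
  utr3_len <- vapply(ctl$utr3, interval_width, numeric(1))
  want <- pmin(pmax(target_len - utr3_len, pad_range[1]), pad_range[2])
  avail <- ifelse(ctl$strand == "+",
                  ifelse(is.na(bounds$bound_down), Inf, bounds$bound_down - ctl$end),
                  ifelse(is.na(bounds$bound_up), Inf, ctl$start - bounds$bound_up))
  pad <- pmin(want, pmax(avail, 0))
  out <- ctl |>
    dplyr::mutate(utr3_len = utr3_len, pad_bp = as.integer(pad),
                  utr3_len_padded = utr3_len + as.integer(pad),
                  pad_truncated = pad < want)
  structure(out, partial = partial, target_utr3_len = target_len)
}
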