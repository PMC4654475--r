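## Intergenic piC calling by sliding-window read density, and synteny
## anchoring of clusters to flanking-gene orthologs.

#' Call intergenic piRNA cluster loci
#'
#' Tiles each chromosome in 5 kb windows (step = window size by default), a
#' cluster is initiated when a window's combined-strand read density
#' exceeds `start_rpm` (> 1 RPM) and terminated at the first window below
#' `stop_rpm` (< 1 RPM); contiguous qualifying windows form the cluster
#' interval, kept only if it totals at least `min_total` RPM (>= 10 RPM).
#' Both strands are summed for detection; per-strand RPMs are retained for
#' the strand-configuration index.
#'
#' @param plus_track,minus_track [coverage_track()]s of one library.
#' @param chrom_sizes Named integer vector of chromosome lengths. If
#'   `NULL`, taken as the last covered position + 1 per chromosome.
#' @param window_bp Window size (default 5000).
#' @param step_bp Window step; defaults to `window_bp` (non-overlapping
#'   tiling, which makes calls deterministic).
#' @param start_rpm Strict lower bound to open a cluster.
#' @param stop_rpm A window below this closes the cluster.
#' @param min_total Minimum total cluster RPM to keep.
#' @param genic_pics Optional called genic piC tibble; overlapping clusters
#'   are flagged and, when `genic_overlap = "drop"`, removed.
#' @param genic_overlap `"flag"` (default) or `"drop"`.
#' @return Tibble: `cluster_id`, `chrom`, `start`, `end`, `total_rpm`,
#'   `plus_rpm`, `minus_rpm`, `n_windows`, `overlaps_genic`, and a
#'   list-column `windows` with the per-window trace
#'   (`start`, `end`, `rpm`, `plus_rpm`, `minus_rpm`).
#' @export
call_intergenic_pics <- function(plus_track, minus_track, chrom_sizes = NULL,
                                 window_bp = 5000L, step_bp = window_bp,
                                 start_rpm = 1, stop_rpm = 1, min_total = 10,
                                 genic_pics = NULL,
                                 genic_overlap = c("flag", "drop")) {
  genic_overlap <- match.arg(genic_overlap)
  lib <- library_size(plus_track)
  if (!isTRUE(all.equal(lib, library_size(minus_track)))) {
    abort("plus and minus tracks disagree on library_size")
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- dplyr::bind_rows(as_tibble(plus_track), as_tibble(minus_track)) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(size = max(.data$pos) + 1L) |>
      tibble::deframe()
  }
  res <- list()
  for (ch in sort(names(chrom_sizes))) {
    size <- chrom_sizes[[ch]]
    starts <- seq.int(0L, max(0L, size - 1L), by = step_bp)
    wins <- tibble(chrom = ch, start = starts,
                   end = pmin(starts + window_bp, size))
    p <- rpm(count_in_intervals(wins, plus_track), lib)
    m <- rpm(count_in_intervals(wins, minus_track), lib)
    tot <- p + m
    ## linear scan: open on > start_rpm, close on < stop_rpm
    in_cl <- FALSE
    cl_first <- integer(0); cl_last <- integer(0)
    for (i in seq_along(tot)) {
      if (!in_cl) {
        if (tot[i] > start_rpm) {
          in_cl <- TRUE
          cl_first <- c(cl_first, i); cl_last <- c(cl_last, i)
        }
      } else {
        if (tot[i] < stop_rpm) in_cl <- FALSE
        else cl_last[length(cl_last)] <- i
      }
    }
    for (k in seq_along(cl_first)) {
      ii <- cl_first[k]:cl_last[k]
      res[[length(res) + 1]] <- tibble(
        chrom = ch, start = wins$start[ii[1]], end = wins$end[ii[length(ii)]],
        total_rpm = sum(tot[ii]), plus_rpm = sum(p[ii]), minus_rpm = sum(m[ii]),
        n_windows = length(ii),
        windows = list(tibble(start = wins$start[ii], end = wins$end[ii],
                              rpm = tot[ii], plus_rpm = p[ii], minus_rpm = m[ii])))
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(cluster_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), total_rpm = numeric(0),
                  plus_rpm = numeric(0), minus_rpm = numeric(0),
                  n_windows = integer(0), overlaps_genic = logical(0),
                  windows = list()))
  }
  out <- out |>
    dplyr::filter(.data$total_rpm >= min_total) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(cluster_id = sprintf("ipic_%03d", dplyr::row_number()),
                  .before = 1)
  out$overlaps_genic <- if (!is.null(genic_pics) && nrow(genic_pics) > 0) {
    intervals_overlap_any(out[, c("chrom", "start", "end")],
                          genic_pics[, c("chrom", "start", "end")])
  } else rep(FALSE, nrow(out))
  if (genic_overlap == "drop") out <- dplyr::filter(out, !.data$overlaps_genic)
  out
}

#' Anchor intergenic clusters by flanking-gene synteny
#'
#' Intergenic loci have no gene name to root them across species, so each
#' cluster is keyed by the reference-rooted names of its nearest
#' non-overlapping annotated gene on each side. Clusters from different
#' species sharing an anchor key are declared syntenic orthologs (e.g. a
#' cluster lying between the CCAR1 and DDX50 orthologs in two genomes).
#'
#' @param clusters Tibble from [call_intergenic_pics()].
#' @param genes Gene-model tibble of the same assembly.
#' @param ortholog_map Optional tibble from [read_ortholog_table()];
#'   translates gene ids to reference names.
#' @param species Species name for the ortholog lookup.
#' @param max_anchor_dist Genes farther than this from the cluster edge do
#'   not anchor (default 1 Mb); missing sides yield a one-sided key,
#'   flagged.
#' @return `clusters` with `anchor_up`, `anchor_down`, `anchor_key`
#'   (`"up|down"`, `NA` side rendered as `"."`), `one_sided`.
#' @export
anchor_by_synteny <- function(clusters, genes, ortholog_map = NULL,
                              species = NULL, max_anchor_dist = 1e6) {
  name_of <- function(ids) {
    if (is.null(ortholog_map)) {
      genes$name[match(ids, genes$id)]
    } else {
      ortholog_lookup(ortholog_map, species, ids)
    }
  }
  up <- dn <- rep(NA_character_, nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    gg <- genes[genes$chrom == cl$chrom, , drop = FALSE]
    left <- gg[gg$end <= cl$start & cl$start - gg$end <= max_anchor_dist, ]
    right <- gg[gg$start >= cl$end & gg$start - cl$end <= max_anchor_dist, ]
    if (nrow(left)) up[i] <- name_of(left$id[which.max(left$end)])
    if (nrow(right)) dn[i] <- name_of(right$id[which.min(right$start)])
  }
  clusters |>
    dplyr::mutate(anchor_up = up, anchor_down = dn,
                  anchor_key = paste(dplyr::coalesce(up, "."),
                                     dplyr::coalesce(dn, "."), sep = "|"),
                  one_sided = is.na(up) | is.na(dn))
}
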