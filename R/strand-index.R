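## Single-stranded configuration index: (A - B)^2 / (A^2 + B^2) per 5 kb
## window, averaged over a cluster. 1 = all reads on one strand,
## 0 = perfectly balanced dual-strand configuration.

#' Per-window single-stranded configuration index
#'
#' @param A Plus-strand read density (RPM) in one window.
#' @param B Minus-strand read density (RPM) in the same window.
#' @return `(A - B)^2 / (A^2 + B^2)`, in `[0, 1]`; `NA` where both are 0
#'   (undefined; such windows are excluded from cluster averages). The
#'   index is scale-invariant, so raw counts and RPMs give the same value.
#' @export
window_index <- function(A, B) {
  if (any(A < 0 | B < 0, na.rm = TRUE)) abort("strand densities must be >= 0")
  out <- (A - B)^2 / (A^2 + B^2)
  out[A == 0 & B == 0] <- NA_real_
  out
}

#' Cluster strand-configuration index
#'
#' Splits each cluster into windows of `window_bp` from its start (the
#' terminal partial window is included by default: its read densities are
#' genuine) and averages the per-window index over windows where it is
#' defined. Zero-zero windows are excluded from the mean rather than
#' imputed, since either imputation would bias it; set
#' `zero_policy = "zero"` to score them 0 for sensitivity analysis.
#'
#' @param clusters Tibble with `chrom`, `start`, `end` and ideally a
#'   `cluster_id` column.
#' @param plus_track,minus_track [coverage_track()]s.
#' @param window_bp Window size (default 5000).
#' @param zero_policy `"exclude"` (default) or `"zero"`.
#' @param include_partial Include the terminal partial window.
#' @return `clusters` with `strand_index`, `n_windows`, `n_undefined`.
#'   A cluster with no defined window is an error.
#' @export
cluster_strand_index <- function(clusters, plus_track, minus_track,
                                 window_bp = 5000L,
                                 zero_policy = c("exclude", "zero"),
                                 include_partial = TRUE) {
  zero_policy <- match.arg(zero_policy)
  lib <- library_size(plus_track)
  n <- nrow(clusters)
  idx <- numeric(n); nw <- nu <- integer(n)
  for (i in seq_len(n)) {
    cl <- clusters[i, ]
    if (cl$end <= cl$start) abort("cluster length must be >= 1 bp")
    starts <- seq.int(cl$start, cl$end - 1L, by = window_bp)
    ends <- pmin(starts + window_bp, cl$end)
    if (!include_partial && length(starts) > 1) {
      full <- ends - starts == window_bp
      starts <- starts[full]; ends <- ends[full]
    }
    wins <- tibble(chrom = cl$chrom, start = starts, end = ends)
    A <- rpm(count_in_intervals(wins, plus_track), lib)
    B <- rpm(count_in_intervals(wins, minus_track), lib)
    wi <- window_index(A, B)
    if (zero_policy == "zero") wi[is.na(wi)] <- 0
    nw[i] <- length(wi)
    nu[i] <- sum(is.na(wi))
    if (all(is.na(wi))) {
      abort(sprintf("cluster %s:%d-%d has no window with reads; index undefined",
                    cl$chrom, cl$start, cl$end))
    }
    idx[i] <- mean(wi, na.rm = TRUE)
  }
  clusters |>
    dplyr::mutate(strand_index = idx, n_windows = nw, n_undefined = nu)
}
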