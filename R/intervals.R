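## Interval utilities. All coordinates are 0-based half-open [start, end).

#' Build an interval tibble
#'
#' @param start,end Integer vectors of 0-based half-open bounds.
#' @param chrom Optional chromosome names (recycled).
#' @return A tibble with columns `chrom` (if given), `start`, `end`.
#' @keywords internal
#' @noRd
interval_tbl <- function(start, end, chrom = NULL) {
  stopifnot(length(start) == length(end))
  if (any(start > end)) abort("interval start > end")
  if (is.null(chrom)) {
    tibble(start = as.integer(start), end = as.integer(end))
  } else {
    tibble(chrom = chrom, start = as.integer(start), end = as.integer(end))
  }
}

interval_width <- function(ints) sum(ints$end - ints$start)

## Clip intervals to [lo, hi); drops empties.
interval_clip <- function(ints, lo, hi) {
  s <- pmax(ints$start, lo)
  e <- pmin(ints$end, hi)
  keep <- s < e
  out <- ints[keep, , drop = FALSE]
  out$start <- s[keep]
  out$end <- e[keep]
  out
}

## TRUE where intervals a (rows) overlap any interval in b on the same chrom.
intervals_overlap_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i) {
    bb <- b[b$chrom == a$chrom[i], , drop = FALSE]
    any(bb$start < a$end[i] & bb$end > a$start[i])
  }, logical(1))
}

## Total bases of each row of a covered by the union of b (same chrom assumed
## handled by caller via chrom column).
interval_overlap_bases <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    bb <- b
    if ("chrom" %in% names(a) && "chrom" %in% names(b)) {
      bb <- b[b$chrom == a$chrom[i], , drop = FALSE]
    }
    if (nrow(bb) == 0) return(0L)
    s <- pmax(bb$start, a$start[i])
    e <- pmin(bb$end, a$end[i])
    w <- pmax(e - s, 0L)
    ## union length via sorted merge to avoid double counting
    keep <- w > 0
    if (!any(keep)) return(0L)
    ss <- s[keep]; ee <- e[keep]
    o <- order(ss)
    ss <- ss[o]; ee <- ee[o]
    tot <- 0L; cur_s <- ss[1]; cur_e <- ee[1]
    for (j in seq_along(ss)[-1]) {
      if (ss[j] <= cur_e) cur_e <- max(cur_e, ee[j])
      else { tot <- tot + (cur_e - cur_s); cur_s <- ss[j]; cur_e <- ee[j] }
    }
    as.integer(tot + (cur_e - cur_s))
  }, integer(1))
}
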