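## Independent brute-force oracles used to check the implementation.

## Linear window scan over per-window RPM values computed straight from
## read-start positions (no package counting code). Returns a data frame
## of cluster window ranges (first/last window index, total rpm).
oracle_window_scan <- function(pos_plus, pos_minus, chrom_len, library_size,
                               window_bp = 5000, start_rpm = 1, stop_rpm = 1,
                               min_total = 10) {
  n_win <- ceiling(chrom_len / window_bp)
  wsum <- function(pos) {
    w <- floor(pos / window_bp) + 1
    tabulate(w, nbins = n_win)
  }
  tot <- (wsum(pos_plus) + wsum(pos_minus)) * 1e6 / library_size
  out <- list()
  i <- 1
  while (i <= n_win) {
    if (tot[i] > start_rpm) {
      j <- i
      while (j + 1 <= n_win && tot[j + 1] >= stop_rpm) j <- j + 1
      total <- sum(tot[i:j])
      if (total >= min_total) {
        out[[length(out) + 1]] <- data.frame(first = i, last = j, total = total)
      }
      i <- j + 2  # window j+1 is below stop_rpm (or past the end)
    } else {
      i <- i + 1
    }
  }
  do.call(rbind, out)
}

## Exhaustive Wagner parsimony cost: minimum over all ancestral labelings.
oracle_wagner_cost <- function(tree, tip_states, gain_cost = 1, loss_cost = 1) {
  ntip <- length(tree$tip.label)
  n_int <- tree$Nnode
  states <- numeric(ntip + n_int)
  states[seq_len(ntip)] <- tip_states[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    states[ntip + seq_len(n_int)] <- bitwAnd(bitwShiftR(mask, seq_len(n_int) - 1), 1)
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      s <- states[tree$edge[e, 1]]; t <- states[tree$edge[e, 2]]
      if (s == 0 && t == 1) cost <- cost + gain_cost
      if (s == 1 && t == 0) cost <- cost + loss_cost
    }
    best <- min(best, cost)
  }
  best
}

## All maximal exact reverse-complement matches by direct enumeration.
oracle_antisense <- function(pirna, transcript, min_len = 13) {
  rc1 <- function(ch) c(A = "T", C = "G", G = "C", T = "A")[[ch]]
  p <- strsplit(toupper(chartr("Uu", "Tt", pirna)), "")[[1]]
  t <- strsplit(toupper(chartr("Uu", "Tt", transcript)), "")[[1]]
  m <- length(p); n <- length(t)
  hits <- list()
  for (a in seq_len(n)) {
    for (b in seq_len(m)) {
      ## pair up t[a + i] with p[b - i] as complements, i = 0,1,...
      L <- 0
      while (a + L <= n && b - L >= 1 && t[a + L] == rc1(p[b - L])) L <- L + 1
      if (L < min_len) next
      ## maximal: not extendable to the left in t / right in p
      if (a > 1 && b < m && t[a - 1] == rc1(p[b + 1])) next
      hits[[length(hits) + 1]] <- data.frame(
        length = L, transcript_pos = a, pirna_offset = b - L + 1)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(length = integer(0), transcript_pos = integer(0),
                      pirna_offset = integer(0)))
  }
  out <- unique(do.call(rbind, hits))
  out[order(out$transcript_pos, out$pirna_offset), , drop = FALSE]
}

## Venn partition by direct set algebra on an rpm matrix (loci x species).
oracle_venn_counts <- function(mat, min_rpm) {
  sets <- apply(mat, 1, function(r) {
    s <- sort(colnames(mat)[r >= min_rpm])
    if (length(s) == 0) NA_character_ else paste(s, collapse = "+")
  })
  table(sets[!is.na(sets)])
}

## Random small rooted binary tree with branch lengths.
random_tree <- function(ntip) {
  tr <- ape::rtree(ntip, rooted = TRUE)
  tr$edge.length <- tr$edge.length + 0.5
  tr$tip.label <- paste0("t", seq_len(ntip))
  tr
}

make_track <- function(pos, strand = "+", lib = 1e6, chrom = "chr1",
                       count = 1) {
  coverage_track(tibble::tibble(chrom = chrom, pos = pos, count = count),
                 strand = strand, library_size = lib)
}

empty_track <- function(strand = "-", lib = 1e6) {
  coverage_track(tibble::tibble(chrom = character(0), pos = integer(0),
                                count = numeric(0)),
                 strand = strand, library_size = lib)
}

## one single-exon gene model
one_gene <- function(chrom = "chr1", start = 1000L, end = 5000L,
                     cds_start = 1300L, cds_end = 3000L, strand = "+",
                     id = "g1", name = id) {
  as_gene_models(tibble::tibble(
    chrom = chrom, start = start, end = end, id = id, name = name,
    strand = strand, cds_start = cds_start, cds_end = cds_end))
}
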