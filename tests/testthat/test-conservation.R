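test_that("interval mean scores follow the sum/length definition", {
  tr <- score_track(tibble::tibble(chrom = "chr1", pos = 0:99, score = 0.8))
  out <- interval_mean_score(tibble::tibble(chrom = "chr1", start = 0L,
                                            end = 100L), tr)
  expect_equal(out$mean_score, 0.8)
  tr2 <- score_track(tibble::tibble(chrom = "chr1", pos = 0:99,
                                    score = rep(c(1, 0), each = 50)))
  out2 <- interval_mean_score(tibble::tibble(chrom = "chr1", start = 0L,
                                             end = 100L), tr2)
  expect_equal(out2$mean_score, 0.5)
  ## uncovered bases count 0 by default, or are excluded on request
  iv <- tibble::tibble(chrom = "chr1", start = 0L, end = 200L)
  expect_equal(interval_mean_score(iv, tr)$mean_score, 0.4)
  expect_equal(interval_mean_score(iv, tr, missing = "exclude")$mean_score, 0.8)
  expect_error(interval_mean_score(tr2[0, c("chrom", "pos")], tr2), "no intervals")
})

test_that("interval means equal a per-base loop oracle and scale linearly", {
  set.seed(55)
  pos <- sort(sample(0:999, 400))
  sc <- stats::rnorm(400)
  tr <- score_track(tibble::tibble(chrom = "chr1", pos = pos, score = sc))
  lookup <- setNames(sc, pos)
  for (i in 1:10) {
    b <- sort(sample(0:1000, 2)); if (b[1] == b[2]) next
    iv <- tibble::tibble(chrom = "chr1", start = b[1], end = b[2])
    want <- sum(lookup[as.character(b[1]:(b[2] - 1))], na.rm = TRUE) /
      (b[2] - b[1])
    expect_equal(interval_mean_score(iv, tr)$mean_score, want,
                 tolerance = 1e-12)
    ## linearity in the track values
    tr3 <- score_track(tibble::tibble(chrom = "chr1", pos = pos,
                                      score = 3 * sc))
    expect_equal(interval_mean_score(iv, tr3)$mean_score, 3 * want,
                 tolerance = 1e-12)
  }
})

test_that("element counts per region average over gene sets", {
  g1 <- one_gene(id = "g1")                          # utr3 [3000,5000)
  g2 <- one_gene(start = 11000L, end = 15000L, cds_start = 11300L,
                 cds_end = 13000L, id = "g2")        # utr3 [13000,15000)
  els <- tibble::tibble(chrom = "chr1",
                        start = c(3100L, 3500L, 4200L, 13500L, 2900L),
                        end = c(3200L, 3600L, 4300L, 13600L, 3100L))
  out <- count_elements(els, list(pic = dplyr::bind_rows(g1, g2)))
  ## g1 has 4 elements in utr3 (one spans the ORF boundary), g2 has 1
  pg <- out$per_gene
  expect_equal(pg$utr3_elements[pg$id == "g1"], 4L)
  expect_equal(pg$utr3_elements[pg$id == "g2"], 1L)
  expect_equal(out$summary$utr3_mean, 2.5)
  ## the boundary-spanning element is counted once per segment it overlaps
  expect_equal(pg$orf_elements[pg$id == "g1"], 1L)
  ## order of elements does not matter
  out2 <- count_elements(els[sample(5), ], list(pic = dplyr::bind_rows(g1, g2)))
  expect_equal(out2$summary, out$summary)
})

test_that("set comparisons include a Mann-Whitney test", {
  set.seed(2)
  mk_set <- function(n, offset) dplyr::bind_rows(lapply(seq_len(n), function(i) {
    s <- offset + (i - 1) * 10000L + 1000L
    one_gene(start = s, end = s + 4000L, cds_start = s + 300L,
             cds_end = s + 2000L, id = paste0("s", offset, "_", i))
  }))
  pic <- mk_set(8, 0L); ctl <- mk_set(8, 100000L)
  els <- tibble::tibble(chrom = "chr1",
                        start = sort(sample(3000:5000, 12)) +
                          rep(seq(0, 70000, by = 10000), length.out = 12))
  els$end <- els$start + 50L
  out <- count_elements(els, list(pic = pic, control = ctl))
  expect_true(all(c("set_a", "set_b", "region", "p") %in% names(out$tests)))
  expect_true(all(out$tests$p >= 0 & out$tests$p <= 1))
})

test_that("negative-control selection sizes, pads and truncates correctly", {
  set.seed(8)
  genes <- dplyr::bind_rows(lapply(1:50, function(i) {
    s <- (i - 1) * 20000L + 1000L
    one_gene(start = s, end = s + 4000L, cds_start = s + 300L,
             cds_end = s + 2000L, id = paste0("g", i), strand = "+")
  }))
  pic <- genes[1:10, ]
  ctl <- select_negative_controls(genes, pic, multiplier = 3,
                                  pad_range = c(500, 1100), seed = 42)
  expect_equal(nrow(ctl), 30)
  expect_false(any(ctl$id %in% pic$id))
  ## reproducible under the same seed
  ctl2 <- select_negative_controls(genes, pic, multiplier = 3,
                                   pad_range = c(500, 1100), seed = 42)
  expect_equal(ctl$id, ctl2$id)
  ## pads stay within the clade range
  expect_true(all(ctl$pad_bp >= 0 & ctl$pad_bp <= 1100))
  ## a same-strand gene 300 bp downstream truncates the pad to 300
  tight <- dplyr::bind_rows(
    one_gene(id = "c1", start = 1000L, end = 5000L, cds_start = 1300L,
             cds_end = 3000L),
    one_gene(id = "n1", start = 5300L, end = 9000L, cds_start = 5600L,
             cds_end = 8000L))
  out <- select_negative_controls(
    tight, one_gene(id = "pic", start = 50000L, end = 54000L,
                    cds_start = 50300L, cds_end = 52000L),
    multiplier = 3, pad_range = c(500, 1100), seed = 1) |>
    suppressWarnings()
  c1 <- out[out$id == "c1", ]
  expect_equal(c1$pad_bp, 300L)
  expect_true(c1$pad_truncated)
  expect_true(attr(out, "partial"))
})

test_that("padded control 3'UTR lengths approach the piC mean", {
  set.seed(4)
  ## piC 3'UTRs are 2000 bp; control genes have 1000 bp 3'UTRs
  genes <- dplyr::bind_rows(lapply(1:40, function(i) {
    s <- (i - 1) * 20000L + 1000L
    if (i <= 10) {
      one_gene(start = s, end = s + 4000L, cds_start = s + 300L,
               cds_end = s + 2000L, id = paste0("pic", i))
    } else {
      one_gene(start = s, end = s + 3000L, cds_start = s + 300L,
               cds_end = s + 2000L, id = paste0("ctl", i))
    }
  }))
  pic <- genes[1:10, ]
  ctl <- select_negative_controls(genes, pic, multiplier = 3,
                                  pad_range = c(500, 1100), seed = 9)
  expect_lt(abs(mean(ctl$utr3_len_padded) - 2000) / 2000, 0.2)
})
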