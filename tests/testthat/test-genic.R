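lib <- 1e6

test_that("UTR extension is window-wise, conditional, and clade-sized", {
  ## + strand gene ending at 5000; 2 reads (2 RPM) at +1500, silence after
  g <- one_gene()
  tr <- make_track(c(6500, 6501))
  ## mammalian 2000 bp window: one window added
  expect_equal(utr_extension(5000, +1, "chr1", tr, 2000), 2000L)
  ## fly 500 bp windows: +1500 never reached, first window empty
  expect_equal(utr_extension(5000, +1, "chr1", tr, 500), 0L)
  ## fly mode reaches +1500 only if every intervening window qualifies
  tr2 <- make_track(c(5100, 5600, 6100, 6500, 6501))
  expect_equal(utr_extension(5000, +1, "chr1", tr2, 500), 2000L)
  ## no reads at all
  expect_equal(utr_extension(5000, +1, "chr1", empty_track("+"), 2000), 0L)
  ## capped at max_windows
  tr3 <- make_track(seq(5100, 30000, by = 400))
  expect_equal(utr_extension(5000, +1, "chr1", tr3, 2000, max_windows = 5), 10000L)
  ## truncated at a same-strand neighbor 300 bp away: the qualifying
  ## window is clipped to the available span
  tr4 <- make_track(c(5050, 5100))
  expect_equal(utr_extension(5000, +1, "chr1", tr4, 2000, bound = 5300), 300L)
  ## reads beyond the bound are out of reach
  expect_equal(utr_extension(5000, +1, "chr1", tr, 2000, bound = 5300), 0L)
})

test_that("region counting is strand-specific and intron-exclusive", {
  ## + gene, utr3 = [3000, 5000); 100 reads on plus there, 500 on minus
  g <- one_gene()
  plus <- make_track(sample(3000:4999, 100, replace = TRUE))
  minus <- make_track(sample(3000:4999, 500, replace = TRUE), strand = "-")
  cc <- count_gene_regions(g, plus, minus, extend = FALSE)
  expect_equal(cc$utr3_count, 100)
  expect_equal(cc$utr3_rpm, 100)
  ## two-exon 3'UTR: both blocks counted, intron excluded
  g2 <- as_gene_models(tibble::tibble(
    chrom = "chr1", start = 0L, end = 1000L, id = "g2", strand = "+",
    cds_start = 100L, cds_end = 300L,
    exons = list(tibble::tibble(start = c(0L, 600L), end = c(400L, 1000L)))))
  plus2 <- make_track(c(350, 700, 500))  # 500 is intronic
  cc2 <- count_gene_regions(g2, plus2, empty_track(), extend = FALSE)
  expect_equal(cc2$utr3_count, 2)
})

test_that("genic retention threshold is inclusive at the boundary", {
  g <- dplyr::bind_rows(
    one_gene(id = "at_thresh"),
    one_gene(start = 101000L, end = 105000L, cds_start = 101300L,
             cds_end = 103000L, id = "below"))
  lib8 <- 1e8
  mk <- function(pos) coverage_track(
    tibble::tibble(chrom = "chr1", pos = pos, count = 1), "+", lib8)
  ## 1000 reads of 1e8 = 10.00 RPM (kept); 999 = 9.99 RPM (excluded)
  plus <- mk(c(sample(3000:4999, 1000, replace = TRUE),
               sample(103000:104999, 999, replace = TRUE)))
  minus <- coverage_track(tibble::tibble(chrom = character(0),
                                         pos = integer(0), count = numeric(0)),
                          "-", lib8)
  called <- call_genic_pics(g, plus, minus, extend = FALSE)
  expect_equal(called$id, "at_thresh")
  expect_equal(called$utr3_rpm, 10)
})

test_that("raising genic_min_rpm never adds loci (monotone stringency)", {
  set.seed(11)
  genes <- dplyr::bind_rows(lapply(1:12, function(i) {
    s <- (i - 1) * 10000L + 1000L
    one_gene(start = s, end = s + 4000L, cds_start = s + 300L,
             cds_end = s + 2000L, id = paste0("g", i))
  }))
  pos <- unlist(lapply(1:12, function(i) {
    s <- (i - 1) * 10000L + 3000L
    sample(s:(s + 1999), sample(c(0, 5, 12, 25, 60), 1), replace = TRUE)
  }))
  plus <- make_track(pos)
  loose <- call_genic_pics(genes, plus, empty_track(), genic_min_rpm = 10,
                           extend = FALSE)
  strict <- call_genic_pics(genes, plus, empty_track(), genic_min_rpm = 20,
                            extend = FALSE)
  expect_true(all(strict$id %in% loose$id))
  ## counting is invariant to track storage order
  shuf <- make_track(sample(pos))
  loose2 <- call_genic_pics(genes, shuf, empty_track(), genic_min_rpm = 10,
                            extend = FALSE)
  expect_equal(loose$id, loose2$id)
  expect_equal(loose$utr3_rpm, loose2$utr3_rpm)
})

test_that("ORF retention flag follows the 50 RPM rule", {
  g <- one_gene()
  plus <- make_track(c(sample(1300:2999, 60, replace = TRUE),
                       sample(3000:4999, 20, replace = TRUE)))
  called <- call_genic_pics(g, plus, empty_track(), extend = FALSE)
  expect_true(called$orf_retained)
  plus2 <- make_track(c(sample(1300:2999, 49, replace = TRUE),
                        sample(3000:4999, 20, replace = TRUE)))
  called2 <- call_genic_pics(g, plus2, empty_track(), extend = FALSE)
  expect_false(called2$orf_retained)
})

test_that("curation filters remove candidates with coded reasons", {
  genes <- dplyr::bind_rows(
    one_gene(id = "te_gene", name = "TeGene"),
    one_gene(start = 101000L, end = 105000L, cds_start = 101300L,
             cds_end = 103000L, id = "dupA", name = "SameName"),
    one_gene(start = 201000L, end = 205000L, cds_start = 201300L,
             cds_end = 203000L, id = "dupB", name = "SameName"),
    one_gene(start = 301000L, end = 305000L, cds_start = 301300L,
             cds_end = 303000L, id = "nc", name = "Gm12345"),
    one_gene(start = 401000L, end = 405000L, cds_start = 401300L,
             cds_end = 403000L, id = "olf", name = "Olfr1234"))
  pos <- c(sample(3000:4999, 50, replace = TRUE),
           sample(103000:104999, 50, replace = TRUE),
           sample(203000:204999, 50, replace = TRUE),
           sample(303000:304999, 50, replace = TRUE),
           sample(403000:404999, 50, replace = TRUE))
  plus <- make_track(pos)
  called <- call_genic_pics(genes, plus, empty_track(), extend = FALSE)
  expect_equal(nrow(called), 5)
  te <- tibble::tibble(chrom = "chr1", start = 2900L, end = 5100L)
  curated <- apply_curation_filters(called, plus, empty_track(), genes,
                                    te_annotation = te,
                                    family_blacklist = c("Olfr", "Hist", "Zfp"))
  reasons <- setNames(curated$reason, curated$id)
  expect_equal(reasons[["te_gene"]], "TE_overlap")
  expect_equal(reasons[["dupB"]], "duplicate_name")
  expect_true(is.na(reasons[["dupA"]]))
  expect_equal(reasons[["nc"]], "ncRNA_pattern")
  expect_equal(reasons[["olf"]], "blacklist_family")
  expect_equal(sum(curated$status == "kept"), 1)  # only dupA survives
})

test_that("a neighbor gene explaining the signal triggers removal", {
  ## candidate's 3'UTR lies inside a same-strand neighbor's body
  genes <- dplyr::bind_rows(
    one_gene(id = "cand", start = 1000L, end = 5000L,
             cds_start = 1300L, cds_end = 3000L),
    one_gene(id = "host", start = 2500L, end = 9000L,
             cds_start = 2800L, cds_end = 8000L))
  plus <- make_track(sample(3000:4999, 80, replace = TRUE))
  called <- call_genic_pics(genes, plus, empty_track(), extend = FALSE)
  curated <- apply_curation_filters(called, plus, empty_track(), genes)
  expect_equal(curated$reason[curated$id == "cand"], "neighbor_gene_source")
})
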