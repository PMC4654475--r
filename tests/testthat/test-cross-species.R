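long_tbl <- function(mat) {
  tibble::as_tibble(as.data.frame(mat)) |>
    dplyr::mutate(locus = rownames(mat)) |>
    tidyr::pivot_longer(-locus, names_to = "species", values_to = "rpm")
}

test_that("piC overlap assigns loci to species subsets at both stringencies", {
  df <- tibble::tribble(
    ~locus, ~species, ~rpm,
    "L1", "sp1", 15, "L1", "sp2", 12, "L1", "sp3", 0,
    "L2", "sp1", 5, "L2", "sp2", 4, "L2", "sp3", 3)
  v10 <- pic_overlap(df, min_rpm = 10)
  expect_equal(v10$species_set, "sp1+sp2")
  expect_equal(v10$n, 1L)
  v20 <- pic_overlap(df, min_rpm = 20)
  expect_equal(nrow(v20), 0L)
  v20b <- pic_overlap(dplyr::mutate(df, rpm = rpm * 2), min_rpm = 20)
  expect_equal(v20b$species_set, "sp1+sp2")
})

test_that("Venn partition equals brute-force set algebra on random loci", {
  set.seed(77)
  mat <- matrix(stats::rexp(300 * 4, rate = 1 / 15), 300, 4,
                dimnames = list(paste0("L", 1:300), paste0("sp", 1:4)))
  got <- pic_overlap(long_tbl(mat), min_rpm = 10)
  want <- oracle_venn_counts(mat, 10)
  expect_equal(setNames(got$n, got$species_set),
               setNames(as.integer(want), names(want))[got$species_set])
  expect_equal(sum(got$n), sum(want))
  ## counts conserve loci and subsets shrink as min_rpm rises
  asg10 <- attr(pic_overlap(long_tbl(mat), 10), "assignment")
  asg20 <- attr(pic_overlap(long_tbl(mat), 20), "assignment")
  j <- dplyr::inner_join(asg10, asg20, by = "locus")
  sets <- function(s) strsplit(s, "+", fixed = TRUE)
  expect_true(all(purrr::map2_lgl(sets(j$species_set.y), sets(j$species_set.x),
                                  ~all(.x %in% .y))))
})

test_that("expression-overlap criteria reproduce hand-computed decisions", {
  mk <- function(values, species = paste0("sp", seq_along(values))) {
    tibble::tibble(locus = "L", species = species, value = values)
  }
  ## pair (100, 250): |log10 delta| = 0.39794 -> shared at 0.5, split at 0.3
  expect_equal(expression_overlap(mk(c(100, 250)))$species_set, "sp1+sp2")
  str <- expression_overlap(mk(c(100, 250)), mode = "stringent")
  expect_equal(str$species_set, "sp2")  # singleton at the higher level
  ## triple with identical levels: SD = 0, shared in all modes
  expect_equal(expression_overlap(mk(c(100, 100, 100)))$species_set,
               "sp1+sp2+sp3")
  expect_equal(expression_overlap(mk(c(100, 100, 100)),
                                  mode = "stringent")$species_set,
               "sp1+sp2+sp3")
  ## triple (10, 100, 1000): SD(log10) = 1 > 0.3, no pair within 0.5 either
  out <- expression_overlap(mk(c(10, 100, 1000)))
  expect_equal(out$species_set, "sp3")
  ## triple where one pair qualifies: (100, 120, 1000)
  out2 <- expression_overlap(mk(c(100, 120, 1000)))
  expect_equal(out2$species_set, "sp1+sp2")
  ## sd(log10(c(100,120,250))) = 0.2069 <= 0.3: triple-shared by SD rule
  expect_equal(expression_overlap(mk(c(100, 120, 250)))$species_set,
               "sp1+sp2+sp3")
  ## non-positive values make the locus absent in that species
  out3 <- expression_overlap(mk(c(100, 0, 110)))
  expect_equal(out3$species_set, "sp1+sp3")
})

test_that("partition comparison matches the closed-form statistics", {
  mkv <- function(n1, n2, species = c("a", "b")) {
    df <- tibble::tibble(
      locus = paste0("L", seq_len(n1 + n2)),
      species_set = c(rep("a", n1), rep("a+b", n2)))
    picluster:::new_venn_partition(df, species)
  }
  ## identical partitions: statistic 0, p = 1
  same <- suppressWarnings(compare_partitions(mkv(30, 70), mkv(30, 70)))
  expect_equal(same$chisq_statistic, 0)
  expect_equal(same$chisq_p, 1)
  ## 30/100 vs 60/100: pooled two-proportion Z closed form
  z <- prop_z_test(30, 100, 60, 100)
  pool <- 90 / 200
  z_hand <- (0.3 - 0.6) / sqrt(pool * (1 - pool) * (1 / 100 + 1 / 100))
  expect_equal(z$z, z_hand, tolerance = 1e-10)
  expect_equal(z$p, 2 * stats::pnorm(-abs(z_hand)), tolerance = 1e-10)
  expect_equal(round(z$z, 2), -4.26)
  ## 2x2 Pearson chi-square closed form on the same counts
  cmp <- compare_partitions(mkv(30, 70), mkv(60, 40))
  a <- c(30, 70); b <- c(60, 40); N <- 200
  exp_tab <- outer(c(100, 100), c(90, 110)) / N
  chi_hand <- sum((rbind(a, b) - exp_tab)^2 / exp_tab)
  expect_equal(cmp$chisq_statistic, chi_hand, tolerance = 1e-10)
  ## per-subset Z for subset "a" equals the closed form above
  expect_equal(cmp$table$z[cmp$table$species_set == "a"], z_hand,
               tolerance = 1e-10)
  ## Bonferroni multiplies by the number of subsets, capped at 1
  expect_equal(cmp$table$p_bonferroni,
               pmin(1, cmp$table$p * nrow(cmp$table)))
})

test_that("small expected cells flag the exact-test fallback", {
  mkv <- function(counts, species = c("a", "b")) {
    sets <- rep(c("a", "b", "a+b"), counts)
    picluster:::new_venn_partition(
      tibble::tibble(locus = paste0("L", seq_along(sets)), species_set = sets),
      species)
  }
  expect_warning(cmp <- compare_partitions(mkv(c(1, 0, 1)), mkv(c(0, 1, 1))),
                 "expected cell")
  expect_true(cmp$exact_flagged)
  expect_false(is.na(cmp$fisher_p))
})

test_that("ECpiC/LCpiC classification follows the per-clade quorum", {
  clades <- c(human = "Primates", mouse = "Glires", dog = "Laurasiatheria")
  df <- tibble::tribble(
    ~locus, ~species, ~rpm,
    "A", "human", 12, "A", "mouse", 30, "A", "dog", 11,
    "B", "human", 12, "B", "mouse", 30, "B", "dog", 3)
  out <- classify_conservation(df, clades)
  expect_equal(out$class[out$locus == "A"], "ECpiC")
  expect_equal(out$class[out$locus == "B"], "LCpiC")
  expect_error(classify_conservation(df, c(clades, yeti = "Cryptids")),
               "no species")
  ## quorum of 2 demotes single-species clades
  clades2 <- c(human = "P", chimp = "P", mouse = "G", rat = "G")
  df2 <- tibble::tibble(locus = "A",
                        species = c("human", "chimp", "mouse", "rat"),
                        rpm = c(15, 15, 15, 2))
  expect_equal(classify_conservation(df2, clades2)$class, "ECpiC")
  expect_equal(classify_conservation(df2, clades2,
                                     min_species_per_clade = 2)$class, "LCpiC")
})
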