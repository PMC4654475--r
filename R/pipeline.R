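#' Clade presets
#'
#' Bundles the per-clade constants: the conditional UTR extension window
#' (2000 bp in mammals, 500 bp in Drosophilids), the piRNA calling length
#' window (24-31 nt mammals, 24-28 nt Drosophilids), the 23-32 nt
#' library-QC window, and the negative-control 3'UTR padding range
#' (500-1100 bp mouse, 250-500 bp fly).
#'
#' @param clade `"mammal"` or `"fly"`.
#' @return Named list of preset values.
#' @export
clade_preset <- function(clade = c("mammal", "fly")) {
  clade <- match.arg(clade)
  if (clade == "mammal") {
    list(clade = clade, utr_window_bp = 2000L, pirna_window = c(24L, 31L),
         qc_window = c(23L, 32L), pad_range = c(500L, 1100L))
  } else {
    list(clade = clade, utr_window_bp = 500L, pirna_window = c(24L, 28L),
         qc_window = c(23L, 32L), pad_range = c(250L, 500L))
  }
}

#' Run the full comparative piC pipeline on a scenario bundle
#'
#' Executes the stages in order — genic calling, intergenic calling,
#' strand-configuration indexing, cross-species overlap comparison,
#' conservation classification, gain/loss inference — and returns all
#' stage outputs plus a manifest of the thresholds and seeds used.
#' `mode = "stringent"` switches the expression-overlap criteria from
#' delta 0.5 / sigma 0.3 to 0.3 / 0.177 and the RPM threshold from 10
#' to 20.
#'
#' @param scenario A `pic_scenario` from [simulate_scenario()], or an
#'   equivalently shaped list of real data.
#' @param clade `"mammal"` or `"fly"` preset.
#' @param mode `"default"` or `"stringent"`.
#' @param compare_species Species trio for the overlap-vs-expression
#'   comparison; defaults to the first species of each of up to three
#'   clades.
#' @param out_dir Optional directory; stage TSVs and a JSON manifest are
#'   written there.
#' @return List: `genic` (per-species called loci), `intergenic` (with
#'   anchors and strand index), `pic_venn`, `expr_venn`, `comparison`,
#'   `conservation`, `gainloss` (a `wagner_fit`), `rates`, `manifest`.
#' @export
run_pipeline <- function(scenario, clade = "mammal",
                         mode = c("default", "stringent"),
                         compare_species = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  min_rpm <- if (mode == "default") 10 else 20
  cfg <- scenario$config
  species <- names(scenario$species_data)
  genic <- list(); intergenic <- list()
  for (sp in species) {
    d <- scenario$species_data[[sp]]
    g <- call_genic_pics(d$genes, d$plus, d$minus, genic_min_rpm = min_rpm,
                         clade = clade, chrom_sizes = scenario$chrom_sizes)
    genic[[sp]] <- dplyr::mutate(g, species = sp, .before = 1)
    ig <- call_intergenic_pics(d$plus, d$minus,
                               chrom_sizes = scenario$chrom_sizes,
                               genic_pics = g, genic_overlap = "drop")
    if (nrow(ig) > 0) {
      ig <- cluster_strand_index(ig, d$plus, d$minus)
      ig <- anchor_by_synteny(ig, d$genes, scenario$orthologs, species = sp)
    }
    intergenic[[sp]] <- dplyr::mutate(ig, species = sp, .before = 1)
  }
  genic_all <- dplyr::bind_rows(genic)
  intergenic_all <- dplyr::bind_rows(intergenic)

  repertoire <- genic_all |>
    dplyr::select(locus = "name", "species", rpm = "utr3_rpm")
  pic_venn_all <- pic_overlap(repertoire, min_rpm = min_rpm)

  if (is.null(compare_species)) {
    cl <- cfg$clades %||% setNames(rep("all", length(species)), species)
    compare_species <- unname(vapply(
      unique(unname(cl))[seq_len(min(3, length(unique(unname(cl)))))],
      function(cc) intersect(species, names(cl)[cl == cc])[1], character(1)))
  }
  pic_venn <- pic_overlap(dplyr::filter(repertoire,
                                        .data$species %in% compare_species),
                          min_rpm = min_rpm)
  expr <- purrr::imap(scenario$species_data[compare_species],
                      function(d, sp) {
    hk <- d$expression$value[d$expression$gene == cfg$housekeeping]
    tibble(species = sp,
           locus = ortholog_lookup(scenario$orthologs, sp, d$expression$gene),
           value = d$expression$value / hk)
  }) |> dplyr::bind_rows() |> dplyr::filter(!is.na(.data$locus))
  expr_venn <- expression_overlap(expr, mode = mode)
  comparison <- compare_partitions(pic_venn, expr_venn,
                                   labels = c("piC", "mRNA"))

  conservation <- classify_conservation(repertoire, cfg$clades,
                                        min_rpm = min_rpm)

  loci <- sort(unique(repertoire$locus))
  pres <- repertoire |>
    dplyr::group_by(.data$locus, .data$species) |>
    dplyr::summarise(rpm = max(.data$rpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = "rpm",
                       values_fill = 0)
  pm <- as.matrix(pres[setdiff(names(pres), "locus")] >= min_rpm) * 1L
  rownames(pm) <- pres$locus
  missing_sp <- setdiff(scenario$tree$tip.label, colnames(pm))
  if (length(missing_sp) > 0) {
    pm <- cbind(pm, matrix(0L, nrow(pm), length(missing_sp),
                           dimnames = list(NULL, missing_sp)))
  }
  fit <- wagner_parsimony(scenario$tree, pm)
  rates <- branch_rates(fit)

  manifest <- list(
    package_version = as.character(utils::packageVersion("picluster")),
    clade = clade, mode = mode, min_rpm = min_rpm,
    orf_min_rpm = 50, intergenic = list(window_bp = 5000, start_rpm = 1,
                                        stop_rpm = 1, min_total = 10),
    expression_criteria = if (mode == "default") {
      list(delta = 0.5, sigma = 0.3)
    } else list(delta = 0.3, sigma = 0.177),
    compare_species = compare_species,
    seed = cfg$seed, species = species)
  out <- list(genic = genic_all, intergenic = intergenic_all,
              pic_venn = pic_venn, pic_venn_all = pic_venn_all,
              expr_venn = expr_venn, comparison = comparison,
              conservation = conservation, gainloss = fit, rates = rates,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    drop_lists <- function(df) df[!vapply(df, is.list, logical(1))]
    readr::write_tsv(drop_lists(genic_all), file.path(out_dir, "genic_pics.tsv"))
    readr::write_tsv(drop_lists(intergenic_all),
                     file.path(out_dir, "intergenic_pics.tsv"))
    readr::write_tsv(conservation, file.path(out_dir, "conservation.tsv"))
    readr::write_tsv(rates, file.path(out_dir, "branch_rates.tsv"))
    readr::write_tsv(tidy(pic_venn), file.path(out_dir, "pic_venn.tsv"))
    readr::write_tsv(tidy(expr_venn), file.path(out_dir, "expr_venn.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
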