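## Synthetic multi-species scenario generator. Emits, with known ground
## truth, everything the pipeline consumes: gene models, strand-specific
## read-start coverage, piRNA-length reads, expression tables, ortholog
## table, dated tree and library manifest.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults emulate a mammalian testes small-RNA study: nine species in
#' three Eutherian clades on a dated tree, piRNA reads of 24-31 nt peaking
#' at 26 with an 80% 5'-uridine bias, designated genic piC loci at 50 RPM
#' over a 0.2 RPM 3'UTR background, and highly expressed intergenic
#' clusters (300 RPM) in single- or dual-stranded configuration.
#'
#' @param species Character vector of species names.
#' @param clades Named character vector species -> clade.
#' @param tree Optional [ape::phylo]; built from `clades` if `NULL`
#'   (ultrametric, branch lengths in MY, clades joined around 90 MY).
#' @param n_genes Genes per species (orthologous 1:1 across species).
#' @param n_genic_pics Reference genic piC loci planted on the tree.
#' @param frac_conserved Fraction of planted loci conserved in all
#'   species (ECpiC by construction).
#' @param p_loss_type Among non-conserved loci, probability of an
#'   ancestral-presence-with-one-loss history (vs a single gain).
#' @param n_intergenic Intergenic clusters per species (syntenic).
#' @param intergenic_single_frac Fraction with single-stranded
#'   configuration; the rest are balanced dual-strand.
#' @param pirna_len_range,pirna_len_mode Read-length law (triangular).
#' @param u_bias Probability a read starts with U.
#' @param genic_target_rpm,intergenic_target_rpm,background_rpm Poisson
#'   read-placement targets.
#' @param library_size Mapped reads per library.
#' @param housekeeping Housekeeping gene name in expression tables.
#' @param expression_sd_log10 Cross-species log10 noise on shared gene
#'   expression levels.
#' @param seed Integer fixing all randomness.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(
    species = c("hsap", "mmul", "cjac", "mmus", "rnor", "ocun",
                "cfam", "ecab", "sscr"),
    clades = setNames(rep(c("Primates", "Glires", "Laurasiatheria"),
                          each = 3), species),
    tree = NULL,
    n_genes = 200L,
    n_genic_pics = 20L,
    frac_conserved = 0.5,
    p_loss_type = 0.3,
    n_intergenic = 8L,
    intergenic_single_frac = 0.5,
    pirna_len_range = c(24L, 31L),
    pirna_len_mode = 26L,
    u_bias = 0.8,
    genic_target_rpm = 50,
    intergenic_target_rpm = 300,
    background_rpm = 0.2,
    library_size = 1e6,
    housekeeping = "Rpl32",
    expression_sd_log10 = 0.1,
    seed = 1L) {
  if (n_genic_pics > n_genes) abort("more designated piC loci than genes")
  if (is.null(tree)) tree <- build_species_tree(clades)
  if (!setequal(tree$tip.label, species)) {
    abort("tree tips do not match species")
  }
  structure(as.list(environment()), class = "scenario_config")
}

#' Build a dated ultrametric species tree from a clade map
#'
#' Species ladder up within each clade (12 MY steps) and clades join
#' successively from 90 MY rootwards (4 MY steps), echoing Eutherian
#' divergence times.
#'
#' @param clades Named character vector species -> clade.
#' @param within_step,clade_depth,root_step Timing knobs in MY.
#' @return An [ape::phylo].
#' @export
build_species_tree <- function(clades, within_step = 12, clade_depth = 90,
                               root_step = 4) {
  ladder <- function(tips) {
    ## ultrametric ladder; returns list(newick, depth)
    nwk <- tips[1]; depth <- 0
    for (t in tips[-1]) {
      d2 <- depth + within_step
      nwk <- sprintf("(%s:%g,%s:%g)", nwk, d2 - depth, t, d2)
      depth <- d2
    }
    list(nwk = nwk, depth = depth)
  }
  cl <- split(names(clades), unname(clades))
  subs <- lapply(cl, function(tips) ladder(tips))
  nwk <- subs[[1]]$nwk; depth <- subs[[1]]$depth
  join <- clade_depth
  for (i in seq_along(subs)[-1]) {
    nwk <- sprintf("(%s:%g,%s:%g)", nwk, join - depth,
                   subs[[i]]$nwk, join - subs[[i]]$depth)
    depth <- join
    join <- join + root_step
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Plant a conservation pattern of piC loci on a tree
#'
#' Assigns each reference locus an evolutionary history: conserved loci
#' are present at the root with no events (present in every species);
#' the rest receive a single gain on a branch whose subtree misses at
#' least one clade, or ancestral presence with a single loss of a whole
#' clade. Leaf presence follows by propagating events, so Wagner
#' parsimony under 1:1 costs and [classify_conservation()] can be checked
#' against the planted truth.
#'
#' @param tree Rooted dated [ape::phylo].
#' @param clades Named character vector species -> clade.
#' @param n_loci Number of reference loci.
#' @param loci Optional locus names (default `REFG0001`, ...).
#' @param frac_conserved,p_loss_type See [scenario_config()].
#' @return List: `presence` (loci x tips 0/1 matrix), `events` tibble
#'   (`locus`, `edge`, `child_label`, `type`), `classes` tibble
#'   (`locus`, `class`).
#' @export
plant_conservation_pattern <- function(tree, clades, n_loci,
                                       loci = sprintf("REFG%04d", seq_len(n_loci)),
                                       frac_conserved = 0.5,
                                       p_loss_type = 0.3) {
  ntip <- length(tree$tip.label)
  tipsets <- edge_tipsets(tree)
  all_clades <- unique(unname(clades))
  covers <- lapply(tipsets, function(t) unique(unname(clades[t])))
  gain_edges <- which(vapply(covers, function(cc) {
    length(setdiff(all_clades, cc)) >= 1
  }, logical(1)))
  ## loss candidates: subtree is exactly one full clade, and the remaining
  ## species do not form a single subtree themselves — otherwise a lone
  ## gain is equally parsimonious and the planted loss is not the unique
  ## minimum-cost history
  loss_edges <- which(vapply(seq_along(tipsets), function(e) {
    cc <- covers[[e]]
    if (!(length(cc) == 1 && setequal(tipsets[[e]], names(clades)[clades == cc]))) {
      return(FALSE)
    }
    comp <- setdiff(tree$tip.label, tipsets[[e]])
    !any(vapply(tipsets, function(t) setequal(t, comp), logical(1)))
  }, logical(1)))
  if (length(all_clades) < 3) loss_edges <- integer(0)
  stopifnot(length(loci) == n_loci)
  n_cons <- round(frac_conserved * n_loci)
  presence <- matrix(0L, n_loci, ntip,
                     dimnames = list(loci, tree$tip.label))
  events <- list()
  node_lab <- c(tree$tip.label,
                paste0("node_", seq_len(tree$Nnode) + ntip))
  for (i in seq_len(n_loci)) {
    if (i <= n_cons) {
      presence[i, ] <- 1L
      next
    }
    use_loss <- length(loss_edges) > 0 && runif(1) < p_loss_type
    if (use_loss) {
      e <- if (length(loss_edges) == 1) loss_edges else sample(loss_edges, 1)
      presence[i, ] <- 1L
      presence[i, tipsets[[e]]] <- 0L
      type <- "loss"
    } else {
      e <- if (length(gain_edges) == 1) gain_edges else sample(gain_edges, 1)
      presence[i, tipsets[[e]]] <- 1L
      type <- "gain"
    }
    events[[length(events) + 1]] <- tibble(
      locus = loci[i], edge = e,
      child_label = node_lab[tree$edge[e, 2]], type = type)
  }
  per_clade <- vapply(all_clades, function(cc) {
    rowSums(presence[, names(clades)[clades == cc], drop = FALSE]) >= 1
  }, logical(n_loci))
  classes <- tibble(locus = loci,
                    class = unname(ifelse(rowSums(per_clade) == length(all_clades),
                                          "ECpiC", "LCpiC")))
  list(presence = presence, events = dplyr::bind_rows(events),
       classes = classes)
}

## tip labels descending from each edge's child
edge_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) sets[[tree$edge[e, 2]]])
}

#' Simulate a full multi-species scenario
#'
#' Generates the complete input bundle for the pipeline plus its ground
#' truth. Designated genic piC loci receive Poisson read placement on the
#' mRNA strand of their 3'UTR at the configured target RPM; all other
#' genes receive sub-RPM background; syntenic intergenic clusters (three
#' 5 kb windows each) receive reads in the labeled single- or
#' dual-stranded configuration. Read counts are Poisson and positions
#' uniform within the target region. Two runs with the same config are
#' identical.
#'
#' @param config A [scenario_config()].
#' @param dir Optional directory; when given, the bundle is written there
#'   (BED12, bedGraph per strand, FASTA reads, expression TSV per
#'   species, plus ortholog TSV, Newick tree, manifest TSV).
#' @return A `pic_scenario` list: `config`, `tree`, `species_data` (per
#'   species: `genes`, `plus`, `minus`, `reads`, `expression`),
#'   `orthologs`, `chrom_sizes`, and `truth` (designated genic piCs per
#'   species, intergenic intervals with strand labels, presence matrix,
#'   planted events and conservation classes).
#' @export
simulate_scenario <- function(config, dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  cfg <- config
  n_sp <- length(cfg$species)

  ## --- layout (shared across species: 1:1 orthologs, conserved synteny)
  gene_slot <- 10000L
  ig_slot <- 40000L
  n_g <- cfg$n_genes
  genome_len <- n_g * gene_slot + cfg$n_intergenic * ig_slot + 50000L
  two_exon <- runif(n_g) < 0.2
  strand <- sample(c("+", "-"), n_g, replace = TRUE)
  slot0 <- (seq_len(n_g) - 1L) * gene_slot
  ref_names <- sprintf("REFG%04d", seq_len(n_g))

  layout_genes <- function(sp) {
    s <- slot0 + 1000L
    start <- s
    end <- ifelse(two_exon, s + 5000L, s + 4000L)
    cds_start <- s + 300L
    cds_end <- ifelse(two_exon, s + 3800L, s + 2000L)
    exons <- purrr::pmap(list(s, two_exon), function(s, te) {
      if (te) interval_tbl(c(s, s + 2800L), c(s + 1800L, s + 5000L))
      else interval_tbl(s, s + 4000L)
    })
    as_gene_models(tibble(
      chrom = "chr1", start = start, end = end,
      id = sprintf("%s_g%04d", sp, seq_len(n_g)),
      name = ref_names, score = 0, strand = strand,
      cds_start = cds_start, cds_end = cds_end, exons = exons))
  }

  ig0 <- n_g * gene_slot
  ig_start <- ig0 + (seq_len(cfg$n_intergenic) - 1L) * ig_slot + 10000L
  ig_end <- ig_start + 15000L
  ig_single <- seq_len(cfg$n_intergenic) <=
    round(cfg$intergenic_single_frac * cfg$n_intergenic)
  ig_strand <- sample(c("+", "-"), cfg$n_intergenic, replace = TRUE)

  ## --- conservation pattern over genic piC loci; loci are named by the
  ## reference gene that hosts them
  pic_slots <- sort(sample(n_g, cfg$n_genic_pics))
  pat <- plant_conservation_pattern(cfg$tree, cfg$clades, cfg$n_genic_pics,
                                    loci = ref_names[pic_slots],
                                    frac_conserved = cfg$frac_conserved,
                                    p_loss_type = cfg$p_loss_type)
  locus_gene <- setNames(ref_names[pic_slots], rownames(pat$presence))

  ## --- shared expression levels
  base_log10 <- stats::rnorm(n_g, mean = 0.5, sd = 0.6)

  sample_len <- function(n) {
    lo <- cfg$pirna_len_range[1]; hi <- cfg$pirna_len_range[2]
    ll <- lo:hi
    w <- (hi - lo + 2) - abs(ll - cfg$pirna_len_mode)
    sample(ll, n, replace = TRUE, prob = w / sum(w))
  }
  sample_seq <- function(len) {
    first <- ifelse(runif(length(len)) < cfg$u_bias, "T",
                    sample(c("A", "C", "G"), length(len), replace = TRUE))
    vapply(seq_along(len), function(i) {
      paste0(first[i], paste(sample(c("A", "C", "G", "T"), len[i] - 1L,
                                    replace = TRUE), collapse = ""))
    }, character(1))
  }

  species_data <- list()
  truth_genic <- list()
  for (sp in cfg$species) {
    genes <- layout_genes(sp)
    designated <- names(locus_gene)[pat$presence[, sp] == 1L]
    des_genes <- unname(locus_gene[designated])
    pos <- integer(0); str <- character(0)

    place_uniform <- function(iv_start, iv_end, n) {
      if (n == 0) return(integer(0))
      iv_start + sample.int(iv_end - iv_start, n, replace = TRUE) - 1L
    }
    for (gi in seq_len(n_g)) {
      is_pic <- ref_names[gi] %in% des_genes
      lambda <- (if (is_pic) cfg$genic_target_rpm else cfg$background_rpm) *
        cfg$library_size / 1e6
      nn <- rpois(1, lambda)
      if (nn == 0) next
      utr3 <- genes$utr3[[gi]]
      w <- utr3$end - utr3$start
      block <- sample.int(nrow(utr3), nn, replace = TRUE, prob = w)
      p <- utr3$start[block] +
        vapply(block, function(b) sample.int(w[b], 1), integer(1)) - 1L
      pos <- c(pos, p)
      str <- c(str, rep(genes$strand[gi], nn))
    }
    for (ci in seq_len(cfg$n_intergenic)) {
      nn <- rpois(1, cfg$intergenic_target_rpm * cfg$library_size / 1e6)
      if (nn == 0) next
      p <- place_uniform(ig_start[ci], ig_end[ci], nn)
      s <- if (ig_single[ci]) rep(ig_strand[ci], nn)
           else sample(c("+", "-"), nn, replace = TRUE)
      pos <- c(pos, p); str <- c(str, s)
    }
    len <- sample_len(length(pos))
    reads <- tibble(
      id = sprintf("%s_r%06d", sp, seq_along(pos)),
      chrom = "chr1", pos = pos, strand = str, length = len,
      seq = sample_seq(len))
    mk_track <- function(s) {
      coverage_track(tibble(chrom = "chr1", pos = pos[str == s], count = 1),
                     strand = s, library_size = cfg$library_size,
                     assembly = sp)
    }
    expr_noise <- stats::rnorm(n_g, 0, cfg$expression_sd_log10)
    expression <- tibble(
      gene = c(genes$id, cfg$housekeeping),
      value = c(10^(base_log10 + expr_noise), 1))
    species_data[[sp]] <- list(genes = genes, plus = mk_track("+"),
                               minus = mk_track("-"), reads = reads,
                               expression = expression)
    if (length(designated) > 0) {
      gi <- match(unname(locus_gene[designated]), ref_names)
      truth_genic[[sp]] <- tibble(
        species = sp, locus = designated, gene_id = genes$id[gi],
        name = ref_names[gi], chrom = "chr1",
        start = genes$start[gi], end = genes$end[gi])
    }
  }

  orthologs <- tidyr::expand_grid(species = cfg$species,
                                  idx = seq_len(n_g)) |>
    dplyr::mutate(gene_id = sprintf("%s_g%04d", .data$species, .data$idx),
                  ref_name = ref_names[.data$idx]) |>
    dplyr::select("species", "gene_id", "ref_name")

  truth <- list(
    genic = dplyr::bind_rows(truth_genic),
    intergenic = tibble(chrom = "chr1", start = ig_start, end = ig_end,
                        label = ifelse(ig_single, "single", "dual"),
                        strand = ifelse(ig_single, ig_strand, ".")),
    presence = pat$presence, events = pat$events, classes = pat$classes,
    locus_gene = locus_gene)

  out <- structure(list(config = cfg, tree = cfg$tree,
                        species_data = species_data, orthologs = orthologs,
                        chrom_sizes = c(chr1 = genome_len), truth = truth),
                   class = "pic_scenario")
  if (!is.null(dir)) write_scenario(out, dir)
  out
}

#' Write a simulated scenario bundle to disk
#'
#' @param scenario A `pic_scenario` from [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scenario$config
  rows <- list()
  for (sp in names(scenario$species_data)) {
    d <- scenario$species_data[[sp]]
    f <- function(suffix) file.path(dir, paste0(sp, suffix))
    write_bed12(d$genes, f("_genes.bed"))
    write_bedgraph(d$plus, f("_plus.bedgraph"))
    write_bedgraph(d$minus, f("_minus.bedgraph"))
    readr::write_lines(
      paste0(">", d$reads$id, " chr1:", d$reads$pos, ":", d$reads$strand,
             "\n", d$reads$seq),
      f("_reads.fa"))
    readr::write_tsv(d$expression, f("_expression.tsv"))
    rows[[sp]] <- tibble(
      species = sp, library_size = cfg$library_size,
      genes_file = basename(f("_genes.bed")),
      plus_file = basename(f("_plus.bedgraph")),
      minus_file = basename(f("_minus.bedgraph")),
      reads_file = basename(f("_reads.fa")),
      expression_file = basename(f("_expression.tsv")))
  }
  readr::write_tsv(scenario$orthologs, file.path(dir, "orthologs.tsv"))
  ape::write.tree(scenario$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(dplyr::bind_rows(rows), file.path(dir, "manifest.tsv"))
  invisible(dir)
}
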