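## Cross-species repertoire comparison: Venn partitions of piC expression
## and of mRNA expression profiles, tests of their difference, and
## Eutherian-conserved (ECpiC) vs less-conserved (LCpiC) classification.

SET_SEP <- "+"

new_venn_partition <- function(assignment, species) {
  part <- assignment |>
    dplyr::filter(!is.na(.data$species_set)) |>
    dplyr::group_by(.data$species_set) |>
    dplyr::summarise(n = dplyr::n(), loci = list(.data$locus), .groups = "drop") |>
    dplyr::arrange(.data$species_set)
  structure(part, class = c("venn_partition", class(part)),
            species = species, assignment = assignment)
}

set_key <- function(sp) paste(sort(sp), collapse = SET_SEP)

#' Venn partition of piC repertoires across species
#'
#' Each reference-rooted locus is assigned to the subset of species in
#' which its piRNA expression reaches `min_rpm` (10 RPM by default; 20 RPM
#' in the twice-as-stringent mode). Loci below threshold everywhere are
#' excluded.
#'
#' @param df Long tibble: `locus` (reference-rooted name), `species`,
#'   `rpm`. Missing (locus, species) rows mean absent.
#' @param min_rpm Expression threshold (inclusive).
#' @return A `venn_partition`: tibble `species_set` (sorted names joined
#'   by `"+"`), `n`, list-column `loci`; per-locus assignment in
#'   `attr(, "assignment")`.
#' @export
pic_overlap <- function(df, min_rpm = 10) {
  species <- sort(unique(df$species))
  assignment <- df |>
    dplyr::filter(.data$rpm >= min_rpm) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(species_set = set_key(unique(.data$species)), .groups = "drop")
  new_venn_partition(assignment, species)
}

#' Venn partition of mRNA expression profiles across species
#'
#' A locus counts as shared between two species when its
#' housekeeping-normalized expression levels are within 3-fold
#' (|log10 delta| <= 0.5), and among three species when the standard
#' deviation of the three log10 values is <= 0.3 (about 2-fold). The
#' stringent mode tightens these to |log10 delta| <= 0.3 and SD <= 0.177.
#' Assignment precedence is triple > pairwise > singleton; a locus
#' qualifying in several pairs but not the triple is placed in the pair
#' with the smallest log10 difference, and a locus similar to no other
#' species is assigned to the species where it is most expressed.
#' Zero/negative/missing values make the locus absent in that species.
#'
#' @param df Long tibble: `locus`, `species`, `value`
#'   (housekeeping-normalized RPKM ratio).
#' @param mode `"default"` or `"stringent"`; sets `delta`/`sigma` unless
#'   supplied.
#' @param delta Pairwise |log10 x - log10 y| bound.
#' @param sigma Triple SD(log10) bound.
#' @return A `venn_partition` (see [pic_overlap()]).
#' @export
expression_overlap <- function(df, mode = c("default", "stringent"),
                               delta = NULL, sigma = NULL) {
  mode <- match.arg(mode)
  if (is.null(delta)) delta <- if (mode == "default") 0.5 else 0.3
  if (is.null(sigma)) sigma <- if (mode == "default") 0.3 else 0.177
  species <- sort(unique(df$species))
  if (length(species) > 3) {
    abort("expression_overlap supports 2 or 3 species")
  }
  dfd <- df |> dplyr::filter(!is.na(.data$value), .data$value > 0)
  rows <- dfd |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(sp = list(.data$species), lv = list(log10(.data$value)),
                     .groups = "drop")
  assign_one <- function(sp, lv) {
    if (length(sp) == 0) return(NA_character_)
    if (length(sp) == 1) return(sp)
    if (length(sp) == 3 && stats::sd(lv) <= sigma) return(set_key(sp))
    prs <- utils::combn(seq_along(sp), 2)
    d <- abs(lv[prs[1, ]] - lv[prs[2, ]])
    keys <- vapply(seq_len(ncol(prs)),
                   function(j) set_key(sp[prs[, j]]), character(1))
    ok <- d <= delta
    if (any(ok)) {
      o <- order(d[ok], keys[ok])
      return(keys[ok][o[1]])
    }
    sp[order(-lv, sp)[1]]  # singleton: species of highest expression
  }
  assignment <- rows |>
    dplyr::mutate(species_set = purrr::map2_chr(.data$sp, .data$lv, assign_one)) |>
    dplyr::select("locus", "species_set")
  new_venn_partition(assignment, species)
}

#' Pooled two-proportion Z test
#'
#' @param x1,n1,x2,n2 Successes and totals of the two groups.
#' @return List with `z` (pooled-variance Z statistic) and `p` (two-sided).
#' @export
prop_z_test <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare two Venn partitions
#'
#' Tests whether two repertoire partitions over the same species set (e.g.
#' piC expression vs mRNA expression) are distributed differently: a
#' chi-square test over the subset-count vectors plus per-subset pooled
#' two-proportion Z tests with Bonferroni correction (raw p multiplied by
#' the number of subsets, capped at 1). If any expected cell is below 1
#' the chi-square is unreliable; a warning is raised, an exact
#' (Fisher) p-value is computed, and `exact_flagged` is set.
#'
#' @param venn_a,venn_b `venn_partition` objects over the same species.
#' @param labels Length-2 labels for reporting.
#' @return A `partition_comparison` object; see [tidy()] and [glance()].
#' @export
compare_partitions <- function(venn_a, venn_b, labels = c("A", "B")) {
  if (!identical(attr(venn_a, "species"), attr(venn_b, "species"))) {
    abort("partitions are over different species sets")
  }
  keys <- sort(union(venn_a$species_set, venn_b$species_set))
  a <- venn_a$n[match(keys, venn_a$species_set)]
  b <- venn_b$n[match(keys, venn_b$species_set)]
  a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
  tab <- rbind(a, b)
  exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  exact_flagged <- any(exp_cells < 1)
  fisher_p <- NA_real_
  if (exact_flagged) {
    warn("expected cell below 1; chi-square unreliable, exact test flagged")
    fisher_p <- tryCatch(stats::fisher.test(tab)$p.value,
                         error = function(e) NA_real_)
  }
  ## plain Pearson statistic (no Yates correction), the classical closed form
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  k <- length(keys)
  per <- purrr::map(seq_len(k), function(i) prop_z_test(a[i], sum(a), b[i], sum(b)))
  res <- tibble(
    species_set = keys, n_a = a, n_b = b,
    prop_a = a / sum(a), prop_b = b / sum(b),
    z = map_dbl(per, "z"), p = map_dbl(per, "p"),
    p_bonferroni = pmin(1, map_dbl(per, "p") * k))
  structure(list(table = res, chisq_statistic = unname(chi$statistic),
                 chisq_df = unname(chi$parameter),
                 chisq_p = unname(chi$p.value),
                 exact_flagged = exact_flagged, fisher_p = fisher_p,
                 labels = labels),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf("Partition comparison (%s vs %s)\n", x$labels[1], x$labels[2]))
  cat(sprintf("  chi-square = %.4g, df = %d, p = %.3g%s\n",
              x$chisq_statistic, x$chisq_df, x$chisq_p,
              if (x$exact_flagged) sprintf(" [exact p = %.3g]", x$fisher_p) else ""))
  print(x$table)
  invisible(x)
}

#' Classify locus conservation across clades (ECpiC / LCpiC)
#'
#' A locus is Eutherian-Conserved (ECpiC) when it is expressed (RPM >=
#' `min_rpm`) in at least `min_species_per_clade` species of every clade
#' (Primates, Glires, Laurasiatherians in the mammalian analysis);
#' otherwise it is Less-Conserved (LCpiC).
#'
#' @param df Long tibble: `locus`, `species`, `rpm`.
#' @param clades Named character vector mapping species to clade.
#' @param min_rpm Expression threshold (inclusive).
#' @param min_species_per_clade Quorum per clade (default 1).
#' @return Tibble: `locus`, per-clade expressed-species counts
#'   (`n_<clade>`), `class` (`"ECpiC"`/`"LCpiC"`).
#' @export
classify_conservation <- function(df, clades, min_rpm = 10,
                                  min_species_per_clade = 1L) {
  clade_levels <- unique(unname(clades))
  for (cl in clade_levels) {
    if (!any(names(clades)[clades == cl] %in% unique(df$species))) {
      abort(sprintf("clade '%s' has no species in the data", cl))
    }
  }
  wide <- df |>
    dplyr::mutate(clade = unname(clades[.data$species])) |>
    dplyr::filter(!is.na(.data$clade)) |>
    dplyr::group_by(.data$locus, .data$clade) |>
    dplyr::summarise(n_expr = sum(.data$rpm >= min_rpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "clade", values_from = "n_expr",
                       values_fill = 0L, names_prefix = "n_")
  cols <- paste0("n_", clade_levels)
  wide$class <- ifelse(
    rowSums(as.matrix(wide[, cols]) >= min_species_per_clade) == length(cols),
    "ECpiC", "LCpiC")
  dplyr::arrange(wide, .data$locus)
}
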