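## ggplot2 displays for the main result types.

#' @method tidy venn_partition
#' @export
tidy.venn_partition <- function(x, ...) {
  tibble(species_set = x$species_set, n = x$n)
}

#' @method glance venn_partition
#' @export
glance.venn_partition <- function(x, ...) {
  tibble(n_subsets = nrow(x), n_loci = sum(x$n),
         n_species = length(attr(x, "species")))
}

#' @method tidy partition_comparison
#' @export
tidy.partition_comparison <- function(x, ...) x$table

#' @method glance partition_comparison
#' @export
glance.partition_comparison <- function(x, ...) {
  tibble(chisq_statistic = x$chisq_statistic, chisq_df = x$chisq_df,
         chisq_p = x$chisq_p, exact_flagged = x$exact_flagged,
         fisher_p = x$fisher_p)
}

#' @method autoplot length_spectrum
#' @export
autoplot.length_spectrum <- function(object, ...) {
  win <- attr(object, "window")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$fraction)) +
    ggplot2::annotate("rect", xmin = win[1] - 0.5, xmax = win[2] + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "read length (nt)", y = "fraction of reads",
                  title = sprintf("%.1f%% of reads in %d-%d nt window",
                                  100 * attr(object, "frac_in_window"),
                                  win[1], win[2])) +
    ggplot2::theme_minimal()
}

#' @method autoplot venn_partition
#' @export
autoplot.venn_partition <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = stats::reorder(.data$species_set, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "species subset", y = "loci") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot wagner_fit
#' @export
autoplot.wagner_fit <- function(object, ...) {
  df <- branch_rates(object) |>
    tidyr::pivot_longer(c("gains", "losses"), names_to = "event",
                        values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$child_label, y = .data$n,
                                   fill = .data$event)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "branch (by child node)", y = "events") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of cluster strand-configuration indexes
#'
#' @param df Output of [cluster_strand_index()].
#' @param bins Number of bins.
#' @return A ggplot.
#' @export
plot_strand_index <- function(df, bins = 25) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strand_index)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::xlim(-0.02, 1.02) +
    ggplot2::labs(x = "single-stranded configuration index", y = "clusters") +
    ggplot2::theme_minimal()
}
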