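#' Plot methods for srnakit summaries
#'
#' `autoplot()` methods render the standard report figures: the RNA-class
#' composition per sample, the isomiR modification-class partition with
#' per-end length histograms and base composition, the top expressed
#' miRNAs, and the cross-dataset comparison.
#'
#' @param object A summary object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name srnakit-autoplot
NULL

#' @rdname srnakit-autoplot
#' @export
autoplot.class_summary <- function(object, ...) {
  ggplot2::ggplot(
    object$per_sample,
    ggplot2::aes(x = .data$sample_id, y = .data$pct_reads, fill = .data$rna_class)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "% of reads", fill = "RNA class",
      title = "Read-count proportions per RNA class"
    )
}

#' @rdname srnakit-autoplot
#' @export
autoplot.isomir_summary <- function(object, ...) {
  ggplot2::ggplot(
    object$mod_class,
    ggplot2::aes(x = .data$mod_class, y = .data$pct)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "modification class", y = "% of isomiRs",
      title = "IsomiR end-modification classes"
    )
}

#' Base composition of added/deleted end nucleotides
#'
#' @param summary An `isomir_summary`.
#' @return A ggplot object (bars by base, faceted end x change).
#' @export
plot_base_composition <- function(summary) {
  ggplot2::ggplot(
    summary$base_composition,
    ggplot2::aes(x = .data$base, y = .data$fraction)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$change), cols = ggplot2::vars(.data$end)
    ) +
    ggplot2::labs(
      x = NULL, y = "fraction of bases",
      title = "Base composition of end modifications"
    )
}

#' @rdname srnakit-autoplot
#' @export
autoplot.top_expressed <- function(object, ...) {
  dat <- object |>
    mutate(mirna = factor(.data$mirna, levels = rev(.data$mirna)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pct, y = .data$mirna)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "% of miRNA-assigned reads", y = NULL,
      title = "Top expressed miRNAs"
    )
}

#' @rdname srnakit-autoplot
#' @export
autoplot.profile_comparison <- function(object, ...) {
  ids <- setdiff(names(object), c("mirna", "status"))
  long <- tidyr::pivot_longer(
    as_tibble(object), all_of(ids),
    names_to = "dataset_id", values_to = "pct"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$pct, y = .data$mirna, fill = .data$dataset_id)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "% of miRNA-assigned reads", y = NULL, fill = "dataset",
      title = "Top expressed miRNAs across datasets"
    )
}
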