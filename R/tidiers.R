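#' Tidy and glance at srnakit summary objects
#'
#' `tidy()` returns the principal tibble of a summary; `glance()` returns
#' a one-row overview, broom style.
#'
#' @param x A `class_summary`, `novelty_summary`, `isomir_summary` or
#'   `recovery_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name srnakit-tidiers
NULL

#' @rdname srnakit-tidiers
#' @export
tidy.class_summary <- function(x, ...) x$overall

#' @rdname srnakit-tidiers
#' @export
glance.class_summary <- function(x, ...) {
  tibble(
    n_classes = nrow(x$overall),
    n_unique = sum(x$overall$n_unique),
    reads = sum(x$overall$reads),
    pct_unannotated = sum(x$overall$pct_unique[
      x$overall$rna_class == "unannotated"
    ])
  )
}

#' @rdname srnakit-tidiers
#' @export
tidy.novelty_summary <- function(x, ...) x$by_origin

#' @rdname srnakit-tidiers
#' @export
glance.novelty_summary <- function(x, ...) {
  tibble(
    n_sequences = sum(x$by_origin$n_sequences),
    n_mature_mirnas = x$n_mature_mirnas,
    novel_mature_known_precursor = x$novel_mature_known_precursor
  )
}

#' @rdname srnakit-tidiers
#' @export
tidy.isomir_summary <- function(x, ...) x$mod_class

#' @rdname srnakit-tidiers
#' @export
glance.isomir_summary <- function(x, ...) x$totals

#' @rdname srnakit-tidiers
#' @export
tidy.recovery_report <- function(x, ...) {
  bind_cols(x$class, x$exclusion, x$isomir |>
    rename(isomir_sequences = "n_sequences"))
}

#' @rdname srnakit-tidiers
#' @export
glance.recovery_report <- function(x, ...) {
  tibble(
    class_accuracy = x$class$class_accuracy,
    exclusion_rate = x$exclusion$exclusion_rate,
    false_exclusions = x$exclusion$n_false_exclusions,
    isomir_recovery = x$isomir$recovery_rate
  )
}

#' @export
print.class_summary <- function(x, ...) {
  cat("Annotation class summary\n")
  print(x$overall)
  invisible(x)
}

#' @export
print.novelty_summary <- function(x, ...) {
  cat("miRNA novelty breakdown (", sum(x$by_origin$n_sequences),
    " sequences, ", x$n_mature_mirnas, " mature miRNAs)\n",
    sep = ""
  )
  print(x$by_origin)
  cat(
    x$novel_mature_known_precursor,
    "orthologue-only mature(s) lie within a pig precursor\n"
  )
  invisible(x)
}

#' @export
print.isomir_summary <- function(x, ...) {
  cat("IsomiR summary:", x$totals$n_isomirs, "isomiRs in",
    x$totals$n_groups, "miRNA groups (mean",
    format(x$totals$mean_isomirs_per_group, digits = 3), "per group)\n"
  )
  print(x$mod_class)
  invisible(x)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("End-to-end recovery report\n")
  print(glance(x))
  invisible(x)
}
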