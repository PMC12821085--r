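# broom-style tidiers and ggplot2 visualisations for the package's result
# objects: the ABCC cutoff-selection curve, the transplantation null and its
# enrichment summary, and gene-score tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for capcogs result objects
#'
#' `tidy()` returns the per-unit detail (the correlation curve for an
#' `abcc_cutoff`; the per-permutation null proportions for a
#' `transplant_null`; the one-row summary for an `enrichment_result`).
#' `glance()` returns a one-row model summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name capcogs-tidiers
NULL

#' @rdname capcogs-tidiers
#' @export
tidy.abcc_cutoff <- function(x, ...) x$curve

#' @rdname capcogs-tidiers
#' @export
glance.abcc_cutoff <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff,
                 correlation = x$curve$correlation[match(x$cutoff, x$curve$cutoff)],
                 n_genes = x$n_genes, n_grid = nrow(x$curve))
}

#' @rdname capcogs-tidiers
#' @export
tidy.transplant_null <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname capcogs-tidiers
#' @export
glance.transplant_null <- function(x, ...) {
  tibble::tibble(n_perm = nrow(x), null_mean = mean(x$prop),
                 null_sd = stats::sd(x$prop),
                 n_redrawn = attr(x, "n_redrawn"),
                 n_cpirs = attr(x, "n_cpirs"))
}

#' @rdname capcogs-tidiers
#' @export
tidy.enrichment_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname capcogs-tidiers
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))[, c("fold", "ci_lo", "ci_hi", "n_perm")]
}

#' Plot the cutoff-selection correlation curve
#'
#' Pearson correlation between the per-gene sum of above-cutoff ABCC
#' numerators and gene expression, across the cutoff grid; the selected
#' cutoff is marked.
#'
#' @param object An `abcc_cutoff` from [select_cutoff()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abcc_cutoff <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$cutoff,
                                             y = .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "ABCC score cutoff",
                  y = "Pearson r (numerator sum vs expression)",
                  title = sprintf("Selected cutoff: %g", object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result against its permutation null
#'
#' @param object An `enrichment_result` from [feature_enrichment()].
#' @param null Optional `transplant_null` to show as a histogram behind the
#'   observed proportion.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, null = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(null)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::as_tibble(unclass(null)),
      ggplot2::aes(x = .data$prop), bins = 30, fill = "grey80")
  }
  p +
    ggplot2::geom_vline(xintercept = object$observed_prop,
                        colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$null_mean, linetype = "dashed") +
    ggplot2::labs(x = "proportion of cPIRs overlapping features",
                  y = "permutations",
                  title = sprintf("fold = %.2f [%.2f, %.2f]", object$fold,
                                  object$ci_lo, object$ci_hi)) +
    ggplot2::theme_minimal()
}

#' Plot top-ranked gene prioritisation scores
#'
#' @param scores Gene-score tibble from [compute_cogs()] /
#'   [prioritise()].
#' @param top Number of top genes to show (default 20).
#' @param cutoff Prioritisation cutoff line (default 0.5).
#' @return A ggplot.
#' @export
plot_gene_scores <- function(scores, top = 20, cutoff = 0.5) {
  d <- dplyr::slice_head(dplyr::arrange(scores, dplyr::desc(.data$multicogs)),
                         n = top)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$multicogs,
                                  y = stats::reorder(.data$gene_id,
                                                     .data$multicogs))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$gene_id),
                          colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "multiCOGS score", y = NULL) +
    ggplot2::theme_minimal()
}
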