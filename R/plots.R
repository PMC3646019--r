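# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a core-genome MK result
#'
#' Histogram of per-gene DoS values with the neutral expectation (DoS = 0)
#' marked; the subtitle reports the pooled weighted Neutrality Index and its
#' bootstrap confidence interval.
#'
#' @param object A `core_mk_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.core_mk_result <- function(object, ...) {
  df <- object$per_gene[!is.na(object$per_gene$dos), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dos)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Direction of Selection (DoS)",
      y = "genes",
      title = "Per-gene direction of selection",
      subtitle = sprintf(
        "NI_TG = %.3f [%.3f, %.3f], %d genes",
        object$ni_tg, object$ci_low, object$ci_high, object$n_genes_included
      )
    )
}

#' Alignment QC scatterplot
#'
#' Original vs trimmed alignment length for every gene, coloured by QC
#' outcome — the at-a-glance summary of the trimming stage.
#'
#' @param report QC report tibble from [qc_genes()].
#' @return A ggplot object.
#' @export
plot_qc_summary <- function(report) {
  ggplot2::ggplot(
    report,
    ggplot2::aes(
      x = .data$original_length_codons,
      y = .data$trimmed_length_codons,
      colour = .data$passed
    )
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "original length (codons)", y = "trimmed length (codons)",
      colour = "passed QC", title = "Alignment trimming and QC"
    )
}

#' Plot a site-frequency spectrum
#'
#' @param sfs A `coremk_sfs` from [site_frequency_spectrum()].
#' @param folded Plot the folded spectrum instead of the unfolded one.
#' @return A ggplot object.
#' @export
plot_sfs <- function(sfs, folded = FALSE) {
  counts <- if (folded) sfs$folded else sfs$unfolded
  df <- tibble(frequency_class = seq_along(counts), count = counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_class, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = if (folded) "minor-allele count" else "derived-allele count",
      y = "sites",
      title = sprintf(
        "%s site-frequency spectrum (n = %d)",
        if (folded) "Folded" else "Unfolded", sfs$n
      )
    )
}
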