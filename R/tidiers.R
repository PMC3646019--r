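# broom-style methods for fitted core-genome MK results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a core-genome MK result
#'
#' `tidy()` returns the per-gene table (one row per ortholog, with MK
#' counts, NI, DoS, test p/q-values, diversity and filter flags);
#' `glance()` returns the one-row pooled summary.
#'
#' @param x A `core_mk_result` from [ni_tg()] or [mk_core_genome()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.core_mk_result <- function(x, ...) {
  x$per_gene
}

#' @rdname tidy.core_mk_result
#' @export
glance.core_mk_result <- function(x, ...) {
  tibble(
    direction_label = x$direction_label,
    ni_tg = x$ni_tg,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    conf_level = x$conf_level,
    n_genes_included = x$n_genes_included,
    n_genes_total = x$n_genes_total,
    n_boot = x$n_boot
  )
}
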