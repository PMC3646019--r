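# Per-gene McDonald-Kreitman counting and statistics, and the pooled
# core-genome weighted Neutrality Index.

# A codon is usable when it is gap-free, unambiguous and not a stop.
usable_codon_matrix <- function(cod, code) {
  matrix(cod %in% sense_codons(code), nrow = nrow(cod))
}

#' Count MK polymorphisms and fixed differences for one gene
#'
#' Walks the codon columns of an alignment and classifies nucleotide changes
#' into the four cells of the MK 2x2 table:
#' * `p_n`, `p_s` — non-synonymous / synonymous changes segregating within
#'   the ingroup;
#' * `d_n`, `d_s` — non-synonymous / synonymous fixed differences between the
#'   ingroup and the outgroup representative.
#'
#' A codon column is used only when every counted sequence carries a gap-free,
#' unambiguous, non-stop codon. Within-ingroup variation is counted from the
#' most frequent ingroup codon (ties broken lexicographically) to each other
#' observed codon; such columns contribute only to polymorphism, never to
#' divergence. At ingroup-monomorphic columns, differences from the outgroup
#' representative (the single outgroup sequence, or the strict-majority
#' consensus codon when the outgroup has several strains; columns without a
#' majority are skipped) are counted as divergence. Multi-step codon
#' differences are averaged over all shortest stop-free mutational pathways
#' (see [codon_path_counts()]), so counts may be fractional.
#'
#' @param alignment A [gene_alignment()].
#' @param ingroup Character vector of at least two genome labels.
#' @param outgroup Character vector of at least one genome label, disjoint
#'   from `ingroup`.
#' @param code A [genetic_code()] object.
#' @return One-row tibble: `gene_id`, `n_ingroup`, `n_outgroup`,
#'   `codons_used`, `p_n`, `p_s`, `d_n`, `d_s`.
#' @examples
#' aln <- gene_alignment(c(i1 = "AAA", i2 = "AAA", i3 = "AAG", o1 = "AAA"))
#' count_mk(aln, ingroup = c("i1", "i2", "i3"), outgroup = "o1")
#' @export
count_mk <- function(alignment, ingroup, outgroup, code = genetic_code(11)) {
  labs <- alignment_labels(alignment)
  missing_labs <- setdiff(c(ingroup, outgroup), labs)
  if (length(missing_labs) > 0L) {
    coremk_abort(
      sprintf("labels not in alignment: %s", paste(missing_labs, collapse = ", ")),
      "input_error"
    )
  }
  if (length(ingroup) < 2L) {
    coremk_abort("ingroup must contain at least 2 sequences", "input_error")
  }
  if (length(outgroup) < 1L) {
    coremk_abort("outgroup must contain at least 1 sequence", "input_error")
  }
  if (length(intersect(ingroup, outgroup)) > 0L) {
    coremk_abort("ingroup and outgroup must be disjoint", "input_error")
  }

  mat <- unclass_aln(alignment)
  cod <- codon_strings(mat)
  cod_in <- cod[ingroup, , drop = FALSE]
  cod_out <- cod[outgroup, , drop = FALSE]
  ok_in <- usable_codon_matrix(cod_in, code)
  ok_out <- usable_codon_matrix(cod_out, code)
  usable <- colSums(!ok_in) == 0L & colSums(!ok_out) == 0L

  # outgroup representative per usable column (strict majority); only
  # outgroup-polymorphic columns need an actual vote
  rep_codon <- rep(NA_character_, ncol(cod))
  rep_codon[usable] <- cod_out[1L, usable]
  if (nrow(cod_out) > 1L) {
    out_poly <- colSums(cod_out != matrix(cod_out[1L, ], nrow(cod_out),
      ncol(cod_out),
      byrow = TRUE
    )) > 0L
    for (j in which(usable & out_poly)) {
      rep_codon[j] <- strict_majority(cod_out[, j])
    }
  }
  counted <- usable & !is.na(rep_codon)
  if (!any(counted)) {
    coremk_abort(
      sprintf("gene '%s': no usable codon column", gene_id(alignment)),
      "count_error"
    )
  }

  mono <- colSums(cod_in != matrix(cod_in[1L, ], nrow(cod_in), ncol(cod_in),
    byrow = TRUE
  )) == 0L
  tabs <- pathway_tables(code)

  p_n <- p_s <- 0
  for (j in which(counted & !mono)) {
    col <- cod_in[, j]
    major <- modal_value(col)
    others <- setdiff(unique(col), major)
    p_s <- p_s + sum(tabs$syn[major, others])
    p_n <- p_n + sum(tabs$nonsyn[major, others])
  }

  div_cols <- which(counted & mono & cod_in[1L, ] != rep_codon)
  d_n <- d_s <- 0
  if (length(div_cols) > 0L) {
    idx <- cbind(cod_in[1L, div_cols], rep_codon[div_cols])
    d_s <- sum(tabs$syn[idx])
    d_n <- sum(tabs$nonsyn[idx])
  }

  tibble(
    gene_id = gene_id(alignment),
    n_ingroup = length(ingroup),
    n_outgroup = length(outgroup),
    codons_used = sum(counted),
    p_n = p_n, p_s = p_s, d_n = d_n, d_s = d_s
  )
}

check_counts_df <- function(counts) {
  need <- c("p_n", "p_s", "d_n", "d_s")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    coremk_abort(
      "counts must be a data frame with columns p_n, p_s, d_n, d_s",
      "input_error"
    )
  }
  if (any(counts$p_n < 0 | counts$p_s < 0 | counts$d_n < 0 | counts$d_s < 0,
    na.rm = TRUE
  )) {
    coremk_abort("MK counts must be non-negative", "input_error")
  }
  counts
}

#' Neutrality Index
#'
#' `NI = (p_n / p_s) / (d_n / d_s)`, computed in cross-product form
#' `(p_n * d_s) / (p_s * d_n)`. `NI = 1` indicates neutral divergence,
#' `NI < 1` an excess of non-synonymous divergence (positive selection),
#' `NI > 1` purifying constraint on divergence. Being a ratio of ratios, NI
#' is undefined (`NA`) whenever `d_n == 0` or `p_s == 0`.
#'
#' @param counts Data frame with columns `p_n`, `p_s`, `d_n`, `d_s` (one row
#'   per gene), e.g. from [count_mk()].
#' @return Numeric vector of NI values, `NA` where undefined.
#' @examples
#' neutrality_index(data.frame(p_n = 2, p_s = 42, d_n = 7, d_s = 17))
#' @export
neutrality_index <- function(counts) {
  counts <- check_counts_df(counts)
  with(counts, if_else(d_n == 0 | p_s == 0, NA_real_, (p_n * d_s) / (p_s * d_n)))
}

#' Direction of Selection
#'
#' `DoS = d_n / (d_n + d_s) - p_n / (p_n + p_s)`. Zero under neutrality,
#' positive under adaptive divergence, negative under segregating slightly
#' deleterious non-synonymous variants. Undefined (`NA`) only when
#' `p_n + p_s == 0` or `d_n + d_s == 0`, so it is computable for many genes
#' where NI is not.
#'
#' @inheritParams neutrality_index
#' @return Numeric vector of DoS values, `NA` where undefined.
#' @examples
#' direction_of_selection(data.frame(p_n = 2, p_s = 42, d_n = 7, d_s = 17))
#' @export
direction_of_selection <- function(counts) {
  counts <- check_counts_df(counts)
  with(counts, if_else((p_n + p_s) == 0 | (d_n + d_s) == 0, NA_real_,
    d_n / (d_n + d_s) - p_n / (p_n + p_s)
  ))
}

#' MK contingency-table significance test
#'
#' Tests each gene's 2x2 table `[[p_n, p_s], [d_n, d_s]]` for departure from
#' equal polymorphism and divergence ratios. Counts are rounded to the
#' nearest integer for the table. A chi-squared test without continuity
#' correction is used unless any expected cell is below 5, in which case
#' Fisher's exact test is substituted; the column `test_used` records which.
#' An all-zero table yields `NA`.
#'
#' @inheritParams neutrality_index
#' @return Tibble with columns `test_used` (`"chisq"`, `"fisher"` or `NA`)
#'   and `p_value`, one row per input row.
#' @export
mk_significance <- function(counts) {
  counts <- check_counts_df(counts)
  n <- nrow(counts)
  test_used <- rep(NA_character_, n)
  p_value <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tab <- round(matrix(
      c(
        counts$p_n[i], counts$p_s[i],
        counts$d_n[i], counts$d_s[i]
      ),
      nrow = 2L, byrow = TRUE
    ))
    if (anyNA(tab) || sum(tab) == 0) next
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      test_used[i] <- "fisher"
      p_value[i] <- stats::fisher.test(tab)$p.value
    } else {
      test_used[i] <- "chisq"
      p_value[i] <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value
      )
    }
  }
  tibble(test_used = test_used, p_value = p_value)
}

#' Append per-gene MK statistics to a count table
#'
#' Adds `ni`, `dos`, `test_used`, `p_value` and Benjamini-Hochberg `q_value`
#' columns to a per-gene MK count table.
#'
#' @inheritParams neutrality_index
#' @return The input as a tibble with the five statistic columns appended.
#' @export
add_mk_statistics <- function(counts) {
  counts <- check_counts_df(counts)
  sig <- mk_significance(counts)
  out <- as_tibble(counts)
  out$ni <- neutrality_index(counts)
  out$dos <- direction_of_selection(counts)
  out$test_used <- sig$test_used
  out$p_value <- sig$p_value
  out$q_value <- stats::p.adjust(sig$p_value, method = "BH")
  out
}

#' Core-genome weighted Neutrality Index with bootstrap CI
#'
#' Pools the per-gene MK tables into the Tarone-Greenland weighted-average
#' Neutrality Index
#' \deqn{NI_{TG} = \frac{\sum_i D_{S,i} P_{N,i} / (P_{S,i}+D_{S,i})}
#'                     {\sum_i P_{S,i} D_{N,i} / (P_{S,i}+D_{S,i})}}
#' a Mantel-Haenszel-style estimator that is robust to across-gene
#' heterogeneity and does not require every gene's own NI to be defined.
#' Genes with `p_s + d_s == 0` carry no weight and are skipped. The 95%
#' confidence interval is a seeded nonparametric bootstrap over genes
#' (percentile method).
#'
#' @inheritParams neutrality_index
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap, or `NULL` to use the current
#'   RNG state.
#' @param direction_label Optional label recording which clade was the
#'   ingroup.
#' @return An object of class `core_mk_result`; see [tidy.core_mk_result()]
#'   and [glance.core_mk_result()].
#' @examples
#' counts <- data.frame(
#'   gene_id = c("g1", "g2"),
#'   p_n = c(2, 1), p_s = c(42, 10), d_n = c(7, 2), d_s = c(17, 4)
#' )
#' res <- ni_tg(counts, n_boot = 100, seed = 1)
#' glance(res)
#' @export
ni_tg <- function(counts, n_boot = 10000, conf_level = 0.95, seed = NULL,
                  direction_label = NA_character_) {
  counts <- check_counts_df(counts)
  if (nrow(counts) == 0L) {
    coremk_abort("no genes supplied", "input_error")
  }
  w_den <- counts$p_s + counts$d_s
  keep <- !is.na(w_den) & w_den > 0
  num_terms <- (counts$d_s * counts$p_n / w_den)[keep]
  den_terms <- (counts$p_s * counts$d_n / w_den)[keep]
  if (length(num_terms) == 0L || sum(den_terms) == 0) {
    coremk_abort(
      "NI_TG is undefined: no gene contributes a positive denominator term",
      "aggregate_error"
    )
  }
  est <- sum(num_terms) / sum(den_terms)

  ci <- c(NA_real_, NA_real_)
  boot_ok <- 0L
  if (n_boot > 0L) {
    k <- length(num_terms)
    stats_boot <- with_seed(seed, {
      idx <- matrix(sample.int(k, k * n_boot, replace = TRUE), nrow = k)
      colSums(matrix(num_terms[idx], nrow = k)) /
        colSums(matrix(den_terms[idx], nrow = k))
    })
    stats_boot <- stats_boot[is.finite(stats_boot)]
    boot_ok <- length(stats_boot)
    if (boot_ok > 0L) {
      alpha <- (1 - conf_level) / 2
      ci <- unname(stats::quantile(stats_boot, c(alpha, 1 - alpha)))
    }
  }

  structure(
    list(
      ni_tg = est,
      ci_low = ci[1L],
      ci_high = ci[2L],
      conf_level = conf_level,
      n_genes_included = length(num_terms),
      n_genes_total = nrow(counts),
      n_boot = n_boot,
      n_boot_finite = boot_ok,
      seed = seed,
      direction_label = direction_label,
      per_gene = as_tibble(counts)
    ),
    class = "core_mk_result"
  )
}

#' @export
print.core_mk_result <- function(x, ...) {
  cat(sprintf(
    "<core-genome MK result%s>\n  NI_TG = %.4f, %d%% CI [%.4f, %.4f]\n  %d of %d genes weighted, %d bootstrap resamples\n",
    if (is.na(x$direction_label)) "" else paste0(" (", x$direction_label, ")"),
    x$ni_tg, round(100 * x$conf_level), x$ci_low, x$ci_high,
    x$n_genes_included, x$n_genes_total, x$n_boot
  ))
  invisible(x)
}
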