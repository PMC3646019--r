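# One test direction over the core genome: per-gene MK tables, statistics
# and diversity, pooled into the weighted Neutrality Index.

#' Run the MK test across the core genome for one direction
#'
#' For a chosen ingroup/outgroup direction, computes per-gene MK counts
#' ([count_mk()]), NI/DoS/significance ([add_mk_statistics()]), diversity
#' summaries ([diversity_stats()]) and site-frequency spectra, then pools the
#' genes into the weighted Neutrality Index ([ni_tg()]). Genes flagged as
#' incongruent with the reference split, or as recombinant by the PHI test,
#' can be excluded from the pooled statistic.
#'
#' @param genes Named list of [gene_alignment()] objects.
#' @param ingroup Genome labels of the clade whose polymorphism is tested
#'   (at least 2).
#' @param outgroup Genome labels of the outgroup clade.
#' @param code A [genetic_code()].
#' @param gene_flags Optional tibble with `gene_id` and any of `congruent`
#'   (logical) and `phi_p` (PHI p-value), merged into the per-gene table.
#' @param exclude_incongruent Drop genes with `congruent == FALSE` from the
#'   pooled statistic (default `TRUE`; flagged rows stay in the table).
#' @param exclude_recombinants Drop genes with `phi_p <= phi_alpha` from the
#'   pooled statistic (default `FALSE`: flag only).
#' @param phi_alpha Significance level for the PHI flag (default 0.05).
#' @param n_boot,conf_level,seed Bootstrap settings passed to [ni_tg()].
#' @param direction_label Label for this direction (default derived from the
#'   ingroup labels).
#' @return A `core_mk_result` whose `per_gene` table has one row per gene
#'   that produced counts (columns: `gene_id`, `n_ingroup`, `n_outgroup`,
#'   `codons_used`, `p_n`, `p_s`, `d_n`, `d_s`, `ni`, `dos`, `test_used`,
#'   `p_value`, `q_value`, `s`, `pi`, `theta_w`, `sfs`, `congruent`,
#'   `phi_p`, `included`), plus `sfs` (summed spectra over included genes)
#'   and `errors` (per-gene failures).
#' @export
mk_core_genome <- function(genes, ingroup, outgroup, code = genetic_code(11),
                           gene_flags = NULL,
                           exclude_incongruent = TRUE,
                           exclude_recombinants = FALSE,
                           phi_alpha = 0.05,
                           n_boot = 10000, conf_level = 0.95, seed = NULL,
                           direction_label = NULL) {
  if (length(genes) == 0L) {
    coremk_abort("no genes supplied", "input_error")
  }
  if (length(ingroup) < 2L) {
    coremk_abort(
      "direction skipped: ingroup must contain at least 2 strains",
      "direction_error"
    )
  }
  direction_label <- direction_label %||%
    sprintf("ingroup={%s}", paste(sort(ingroup), collapse = ","))

  rows <- list()
  sfs_list <- list()
  errors <- list()
  for (aln in genes) {
    id <- gene_id(aln)
    res <- tryCatch(
      {
        cts <- count_mk(aln, ingroup, outgroup, code = code)
        div <- diversity_stats(aln, ingroup = ingroup)
        sfs <- site_frequency_spectrum(aln,
          ingroup = ingroup, outgroup = outgroup, code = code
        )
        list(cts = cts, div = div, sfs = sfs)
      },
      coremk_error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[id]] <- tibble(gene_id = id, error = conditionMessage(res))
      next
    }
    sfs_list[[id]] <- res$sfs
    rows[[id]] <- mutate(res$cts,
      s = res$div$s, pi = res$div$pi, theta_w = res$div$theta_w,
      sfs = paste(res$sfs$unfolded, collapse = ",")
    )
  }
  if (length(rows) == 0L) {
    coremk_abort(
      sprintf("direction '%s': no gene produced MK counts", direction_label),
      "direction_error"
    )
  }

  per_gene <- add_mk_statistics(bind_rows(rows))
  per_gene <- per_gene[, c(
    "gene_id", "n_ingroup", "n_outgroup", "codons_used",
    "p_n", "p_s", "d_n", "d_s", "ni", "dos", "test_used",
    "p_value", "q_value", "s", "pi", "theta_w", "sfs"
  )]

  flags <- tibble(gene_id = per_gene$gene_id)
  if (!is.null(gene_flags)) {
    keep_cols <- intersect(c("gene_id", "congruent", "phi_p"), names(gene_flags))
    flags <- left_join(flags, gene_flags[, keep_cols], by = "gene_id")
  }
  if (!"congruent" %in% names(flags)) flags$congruent <- NA
  if (!"phi_p" %in% names(flags)) flags$phi_p <- NA_real_
  per_gene <- left_join(per_gene, flags[, c("gene_id", "congruent", "phi_p")],
    by = "gene_id"
  )

  excluded <- rep(FALSE, nrow(per_gene))
  if (exclude_incongruent) {
    excluded <- excluded | (!is.na(per_gene$congruent) & !per_gene$congruent)
  }
  if (exclude_recombinants) {
    excluded <- excluded | (!is.na(per_gene$phi_p) & per_gene$phi_p <= phi_alpha)
  }
  per_gene$included <- !excluded

  agg <- ni_tg(per_gene[per_gene$included, ],
    n_boot = n_boot, conf_level = conf_level, seed = seed,
    direction_label = direction_label
  )
  agg$per_gene <- per_gene
  agg$sfs <- sum_sfs(sfs_list[per_gene$gene_id[per_gene$included]])
  agg$errors <- bind_rows(errors)
  agg
}

# Element-wise sum of equal-n site-frequency spectra.
sum_sfs <- function(sfs_list) {
  sfs_list <- sfs_list[!vapply(sfs_list, is.null, logical(1L))]
  if (length(sfs_list) == 0L) {
    return(NULL)
  }
  out <- sfs_list[[1L]]
  for (s in sfs_list[-1L]) {
    if (s$n != out$n) {
      return(NULL)
    }
    out$unfolded <- out$unfolded + s$unfolded
    out$folded <- out$folded + s$folded
    out$syn <- out$syn + s$syn
    out$nonsyn <- out$nonsyn + s$nonsyn
    out$biallelic_sites <- out$biallelic_sites + s$biallelic_sites
    out$polarizable_sites <- out$polarizable_sites + s$polarizable_sites
  }
  out
}
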