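# Trimming and alignment quality control. Orthologs whose trimmed alignments
# fall below an overlap threshold or contain long gap runs are excluded from
# downstream counting, mirroring per-gene QC on codon alignments.

# Logical vector: does each codon column contain a gap in any sequence?
gapped_codon_columns <- function(alignment) {
  mat <- unclass_aln(alignment)
  i1 <- seq(1L, ncol(mat), by = 3L)
  has_gap <- mat == "-"
  (colSums(has_gap[, i1, drop = FALSE]) +
    colSums(has_gap[, i1 + 1L, drop = FALSE]) +
    colSums(has_gap[, i1 + 2L, drop = FALSE])) > 0L
}

#' Trim a codon alignment to gap-free flanks
#'
#' Removes leading and trailing codon columns in which any sequence has a gap,
#' so both retained flanks are fully gap-free. Interior columns are left
#' untouched.
#'
#' @param alignment A [gene_alignment()].
#' @return The trimmed [gene_alignment()]. Trimming is idempotent.
#' @examples
#' aln <- gene_alignment(c(a = "---ATGAAA", b = "ATGATGAAA"))
#' n_codons(trim_alignment(aln))
#' @export
trim_alignment <- function(alignment) {
  gapped <- gapped_codon_columns(alignment)
  clean <- which(!gapped)
  if (length(clean) == 0L) {
    coremk_abort(
      sprintf("gene '%s': no gap-free codon column remains after trimming", gene_id(alignment)),
      "qc_error"
    )
  }
  keep <- seq(min(clean), max(clean))
  jj <- rep((keep - 1L) * 3L, each = 3L) + 1:3
  new_gene_alignment(
    unclass_aln(alignment)[, jj, drop = FALSE],
    gene_id(alignment)
  )
}

#' Alignment quality metrics for one gene
#'
#' Computes, over codon columns of a (normally trimmed) alignment: the overlap
#' fraction (share of columns in which no sequence has a gap) and the longest
#' run of codon columns containing at least one gap. A gene passes when
#' `overlap_fraction >= min_overlap` and `longest_indel_codons <= max_indel`.
#'
#' @param alignment A [gene_alignment()], normally the output of
#'   [trim_alignment()].
#' @param min_overlap Minimum overlap fraction in `[0, 1]` (default 0.85).
#' @param max_indel Maximum allowed gap-run length in codon columns
#'   (default 15).
#' @return One-row tibble: `gene_id`, `length_codons`, `overlap_fraction`,
#'   `longest_indel_codons`, `passed`.
#' @export
evaluate_qc <- function(alignment, min_overlap = 0.85, max_indel = 15) {
  if (min_overlap < 0 || min_overlap > 1) {
    coremk_abort("min_overlap must be in [0, 1]", "input_error")
  }
  if (max_indel < 1) {
    coremk_abort("max_indel must be >= 1", "input_error")
  }
  gapped <- gapped_codon_columns(alignment)
  overlap <- 1 - mean(gapped)
  runs <- rle(gapped)
  longest <- if (any(gapped)) max(runs$lengths[runs$values]) else 0L
  tibble(
    gene_id = gene_id(alignment),
    length_codons = n_codons(alignment),
    overlap_fraction = overlap,
    longest_indel_codons = as.integer(longest),
    passed = overlap >= min_overlap && longest <= max_indel
  )
}

#' Trim and quality-filter a set of gene alignments
#'
#' Applies [trim_alignment()] then [evaluate_qc()] to every gene. Genes that
#' are empty after trimming are reported as failures rather than errors.
#'
#' @param alignments Named list of [gene_alignment()] objects (names are
#'   ignored; `gene_id`s are used).
#' @inheritParams evaluate_qc
#' @return A list with
#'   \describe{
#'     \item{alignments}{named list of trimmed alignments that passed QC}
#'     \item{rejected}{named list of trimmed alignments that failed QC}
#'     \item{report}{tibble with one row per input gene: `gene_id`,
#'       `original_length_codons`, `trimmed_length_codons`,
#'       `overlap_fraction`, `longest_indel_codons`, `passed`}
#'   }
#' @export
qc_genes <- function(alignments, min_overlap = 0.85, max_indel = 15) {
  kept <- list()
  rejected <- list()
  rows <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    id <- gene_id(aln)
    trimmed <- tryCatch(trim_alignment(aln), coremk_qc_error = function(e) NULL)
    if (is.null(trimmed)) {
      rows[[i]] <- tibble(
        gene_id = id,
        original_length_codons = n_codons(aln),
        trimmed_length_codons = 0L,
        overlap_fraction = 0,
        longest_indel_codons = n_codons(aln),
        passed = FALSE
      )
      next
    }
    qc <- evaluate_qc(trimmed, min_overlap = min_overlap, max_indel = max_indel)
    rows[[i]] <- tibble(
      gene_id = id,
      original_length_codons = n_codons(aln),
      trimmed_length_codons = qc$length_codons,
      overlap_fraction = qc$overlap_fraction,
      longest_indel_codons = qc$longest_indel_codons,
      passed = qc$passed
    )
    if (qc$passed) {
      kept[[id]] <- trimmed
    } else {
      rejected[[id]] <- trimmed
    }
  }
  list(alignments = kept, rejected = rejected, report = bind_rows(rows))
}
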