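# End-to-end orchestration: read -> trim/QC -> concatenate -> UPGMA tree ->
# outgroup designation -> congruency -> PHI -> per-direction MK tables and
# pooled statistics, with per-stage logs and deterministic outputs.

#' Run the full core-genome MK pipeline
#'
#' Executes the whole analysis over a directory of per-gene FASTA alignments
#' (or an in-memory list of [gene_alignment()]s) and writes all artifacts to
#' `out_dir`:
#' * `qc_report.tsv` — per-gene trimming/QC metrics;
#' * `concatemer.fasta`, `concatemer.nwk` — concatenated orthologs and their
#'   UPGMA tree;
#' * `summary_<direction>.tsv` — one row per gene with counts, NI, DoS,
#'   p/q-values, diversity, SFS and filter flags; one file per eligible test
#'   direction;
#' * `aggregate_<direction>.tsv` — the pooled weighted Neutrality Index with
#'   its bootstrap CI;
#' * `sfs_<direction>.tsv` — the summed unfolded spectrum (frequency class,
#'   count);
#' * `pipeline.log` — stage-prefixed log lines.
#'
#' The outgroup is designated automatically from the first split of the
#' concatemer UPGMA tree; the MK test is run once for each side of the split
#' that has at least two strains, mirroring the dual-direction output of
#' multi-strain outgroups. All randomness (PHI permutations, bootstrap)
#' derives from `seed`, so identical inputs and seed give byte-identical
#' outputs.
#'
#' @param input Directory containing per-gene FASTA files (`.fa`, `.fasta`,
#'   `.fna`, `.ffn`), or a named list of [gene_alignment()] objects.
#' @param out_dir Output directory (created if needed).
#' @param min_overlap,max_indel QC thresholds, see [evaluate_qc()].
#' @param split Optional explicit [taxon_split()]; by default the first
#'   split of the concatemer tree.
#' @param congruency Compute per-gene UPGMA trees and flag genes whose first
#'   split disagrees with the reference split (default `TRUE`).
#' @param exclude_incongruent,exclude_recombinants,phi_alpha Exclusion
#'   policy, see [mk_core_genome()].
#' @param phi Run the PHI recombination test per gene (default `TRUE`).
#' @param phi_window,phi_permutations PHI settings, see [phi_test()].
#' @param n_boot,conf_level Bootstrap settings for the pooled statistic.
#' @param seed Integer master seed.
#' @param code A [genetic_code()].
#' @param internal_stops Passed to [read_gene_alignment()] when reading from
#'   disk.
#' @return An object of class `core_mk_run`: list with `results` (one
#'   `core_mk_result` per direction), `split`, `tree`, `qc`, `flags`,
#'   `errors`, `files`, `log`.
#' @export
run_core_mk_pipeline <- function(input, out_dir,
                                 min_overlap = 0.85, max_indel = 15,
                                 split = NULL,
                                 congruency = TRUE,
                                 exclude_incongruent = TRUE,
                                 exclude_recombinants = FALSE,
                                 phi = TRUE, phi_window = 100,
                                 phi_permutations = 1000, phi_alpha = 0.05,
                                 n_boot = 10000, conf_level = 0.95,
                                 seed = 1,
                                 code = genetic_code(11),
                                 internal_stops = c("error", "mask")) {
  internal_stops <- match.arg(internal_stops)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(stage, fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }

  # --- read ---------------------------------------------------------------
  read_errors <- list()
  if (is.character(input)) {
    if (!dir.exists(input)) {
      coremk_abort(sprintf("input directory '%s' does not exist", input), "input_error")
    }
    paths <- sort(list.files(input,
      pattern = "\\.(fa|fasta|fna|ffn)$",
      full.names = TRUE
    ))
    if (length(paths) == 0L) {
      coremk_abort(sprintf("no FASTA files found in '%s'", input), "input_error")
    }
    genes <- list()
    for (p in paths) {
      aln <- tryCatch(
        read_gene_alignment(p, internal_stops = internal_stops, code = code),
        coremk_error = function(e) e
      )
      if (inherits(aln, "error")) {
        id <- sub("\\.[A-Za-z0-9]+$", "", basename(p))
        read_errors[[id]] <- tibble(gene_id = id, stage = "read", error = conditionMessage(aln))
        say("read", "gene '%s' skipped: %s", id, conditionMessage(aln))
      } else {
        genes[[gene_id(aln)]] <- aln
      }
    }
  } else {
    genes <- input
    names(genes) <- vapply(genes, gene_id, character(1L))
  }
  if (length(genes) == 0L) {
    coremk_abort("no readable gene alignments in input", "input_error")
  }
  say("read", "%d gene alignments", length(genes))

  # --- trim + qc ----------------------------------------------------------
  qc <- qc_genes(genes, min_overlap = min_overlap, max_indel = max_indel)
  readr::write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"))
  if (length(qc$rejected) > 0L) {
    lq_dir <- file.path(out_dir, "low_quality")
    dir.create(lq_dir, showWarnings = FALSE)
    for (g in qc$rejected) {
      write_gene_alignment(g, file.path(lq_dir, paste0(gene_id(g), ".fasta")))
    }
  }
  say(
    "qc", "%d of %d genes passed (min_overlap=%g, max_indel=%d)",
    length(qc$alignments), length(genes), min_overlap, max_indel
  )
  if (length(qc$alignments) == 0L) {
    coremk_abort("no gene passed alignment QC", "qc_error")
  }

  # --- concatenate + tree -------------------------------------------------
  concatemer <- concatenate_alignments(qc$alignments)
  write_gene_alignment(concatemer, file.path(out_dir, "concatemer.fasta"))
  tree <- upgma(jc69_distance(concatemer))
  write_newick(tree, file.path(out_dir, "concatemer.nwk"))
  say("tree", "concatemer of %d nt; UPGMA tree over %d genomes", n_sites(concatemer), nrow(concatemer))

  # --- outgroup designation -----------------------------------------------
  if (is.null(split)) {
    split <- first_split(tree)
    say(
      "split", "first split: {%s} | {%s}",
      paste(split$clade_a, collapse = ","), paste(split$clade_b, collapse = ",")
    )
  } else if (!inherits(split, "taxon_split")) {
    coremk_abort("split must be a taxon_split", "input_error")
  }

  # --- per-gene congruency ------------------------------------------------
  flags <- tibble(gene_id = names(qc$alignments))
  if (congruency) {
    congr <- vapply(qc$alignments, function(aln) {
      tryCatch(
        is_congruent(upgma(jc69_distance(aln)), split),
        coremk_error = function(e) NA
      )
    }, logical(1L))
    flags$congruent <- unname(congr)
    say(
      "congruency", "%d congruent, %d incongruent, %d undetermined",
      sum(congr, na.rm = TRUE), sum(!congr, na.rm = TRUE), sum(is.na(congr))
    )
  }

  # --- PHI recombination test ----------------------------------------------
  if (phi) {
    phi_rows <- vector("list", length(qc$alignments))
    for (i in seq_along(qc$alignments)) {
      phi_rows[[i]] <- phi_test(qc$alignments[[i]],
        n_permutations = phi_permutations, window = phi_window,
        seed = seed + 10000L + i
      )
    }
    phi_tab <- bind_rows(phi_rows)
    flags$phi_p <- phi_tab$p_value[match(flags$gene_id, phi_tab$gene_id)]
    say(
      "phi", "%d of %d genes flagged at alpha=%g",
      sum(!is.na(flags$phi_p) & flags$phi_p <= phi_alpha), nrow(flags), phi_alpha
    )
  }

  # --- MK per direction ---------------------------------------------------
  clades <- list(clade_a = split$clade_a, clade_b = split$clade_b)
  results <- list()
  files <- c(
    qc_report = file.path(out_dir, "qc_report.tsv"),
    concatemer = file.path(out_dir, "concatemer.fasta"),
    tree = file.path(out_dir, "concatemer.nwk")
  )
  dir_i <- 0L
  for (nm in names(clades)) {
    ing <- clades[[nm]]
    outg <- setdiff(unlist(clades), ing)
    dir_i <- dir_i + 1L
    if (length(ing) < 2L) {
      say("mk", "direction ingroup=%s skipped: fewer than 2 strains", nm)
      next
    }
    label <- paste0("ingroup_", nm)
    res <- mk_core_genome(qc$alignments,
      ingroup = ing, outgroup = outg, code = code,
      gene_flags = flags,
      exclude_incongruent = exclude_incongruent,
      exclude_recombinants = exclude_recombinants,
      phi_alpha = phi_alpha,
      n_boot = n_boot, conf_level = conf_level,
      seed = seed + 20000L + dir_i,
      direction_label = label
    )
    results[[label]] <- res
    f_sum <- file.path(out_dir, paste0("summary_", label, ".tsv"))
    readr::write_tsv(res$per_gene, f_sum)
    f_agg <- file.path(out_dir, paste0("aggregate_", label, ".tsv"))
    readr::write_tsv(glance(res), f_agg)
    f_sfs <- file.path(out_dir, paste0("sfs_", label, ".tsv"))
    if (!is.null(res$sfs)) {
      readr::write_tsv(
        tibble(
          frequency_class = seq_along(res$sfs$unfolded),
          count = res$sfs$unfolded
        ),
        f_sfs
      )
    }
    files[paste0("summary_", label)] <- f_sum
    files[paste0("aggregate_", label)] <- f_agg
    files[paste0("sfs_", label)] <- f_sfs
    say(
      "mk", "%s: NI_TG=%.4f [%.4f, %.4f], %d genes weighted",
      label, res$ni_tg, res$ci_low, res$ci_high, res$n_genes_included
    )
  }
  if (length(results) == 0L) {
    coremk_abort("no direction had at least 2 ingroup strains", "direction_error")
  }

  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  files["log"] <- file.path(out_dir, "pipeline.log")

  structure(
    list(
      results = results,
      split = split,
      tree = tree,
      qc = qc$report,
      flags = flags,
      errors = bind_rows(read_errors),
      files = files,
      log = log_lines
    ),
    class = "core_mk_run"
  )
}

#' @export
print.core_mk_run <- function(x, ...) {
  cat(sprintf(
    "<core-genome MK pipeline run: %d genes in QC report, %d direction(s)>\n",
    nrow(x$qc), length(x$results)
  ))
  for (r in x$results) print(r)
  invisible(x)
}
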