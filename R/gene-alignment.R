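# Codon alignments of single-copy orthologs: construction, validation, FASTA
# round-trips, back-translation and concatenation.

ALIGNMENT_CHARS <- c(
  "A", "C", "G", "T", "-",
  "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V"
)

#' In-frame codon alignment of one ortholog
#'
#' A `gene_alignment` holds the equal-length, in-frame nucleotide sequences of
#' one single-copy ortholog, one sequence per genome. Sequence IDs are exact
#' genome labels. Ambiguity characters (N and other IUPAC codes) are retained
#' but every downstream counting function masks any codon containing one.
#'
#' @param sequences Named character vector of aligned nucleotide strings over
#'   `A,C,G,T,-` (IUPAC ambiguity codes tolerated). Names are genome labels.
#' @param gene_id Identifier for the ortholog.
#' @param internal_stops `"error"` (default) aborts when a sequence contains
#'   an in-frame internal stop codon; `"mask"` replaces such codons with
#'   `"---"`. A stop in the final codon position is always allowed.
#' @param code Genetic code used to identify stop codons.
#' @return An object of class `gene_alignment`: a character matrix of single
#'   characters (rows = genomes, columns = alignment positions) with
#'   attributes `gene_id` and `masked_stops`.
#' @examples
#' aln <- gene_alignment(c(g1 = "ATGAAA", g2 = "ATGAAG"), gene_id = "dnaA")
#' n_codons(aln)
#' @export
gene_alignment <- function(sequences, gene_id = "gene",
                           internal_stops = c("error", "mask"),
                           code = genetic_code(11)) {
  internal_stops <- match.arg(internal_stops)
  if (length(sequences) < 2L) {
    coremk_abort("an alignment needs at least 2 sequences", "input_error")
  }
  labs <- names(sequences)
  if (is.null(labs) || anyNA(labs) || any(labs == "")) {
    coremk_abort("sequences must be named by genome label", "input_error")
  }
  if (anyDuplicated(labs)) {
    coremk_abort(
      sprintf(
        "duplicate genome labels: %s",
        paste(unique(labs[duplicated(labs)]), collapse = ", ")
      ),
      "input_error"
    )
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    coremk_abort(
      sprintf(
        "sequences have unequal lengths (%s)",
        paste(sort(unique(lens)), collapse = ", ")
      ),
      "alignment_error"
    )
  }
  if (lens[1L] %% 3L != 0L) {
    coremk_abort(
      sprintf("alignment length %d is not divisible by 3", lens[1L]),
      "frame_error"
    )
  }
  if (lens[1L] == 0L) {
    coremk_abort("alignment has zero length", "alignment_error")
  }
  mat <- matrix(
    unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
    nrow = length(sequences), byrow = TRUE
  )
  rownames(mat) <- labs
  bad <- setdiff(unique(as.vector(mat)), ALIGNMENT_CHARS)
  if (length(bad) > 0L) {
    coremk_abort(
      sprintf("invalid characters in alignment: %s", paste(bad, collapse = " ")),
      "input_error"
    )
  }
  aln <- new_gene_alignment(mat, gene_id)
  handle_internal_stops(aln, internal_stops, code)
}

new_gene_alignment <- function(mat, gene_id, masked_stops = 0L) {
  structure(mat,
    gene_id = as.character(gene_id), masked_stops = masked_stops,
    class = c("gene_alignment", "matrix", "array")
  )
}

handle_internal_stops <- function(aln, internal_stops, code) {
  cod <- codon_strings(unclass_aln(aln))
  nc <- ncol(cod)
  if (nc > 1L) {
    internal <- cod[, -nc, drop = FALSE]
    is_stop <- matrix(internal %in% stop_codons(code), nrow = nrow(internal))
    if (any(is_stop)) {
      if (internal_stops == "error") {
        hit <- which(is_stop, arr.ind = TRUE)[1L, ]
        coremk_abort(
          sprintf(
            "internal stop codon in '%s' at codon %d (use internal_stops = \"mask\" to mask)",
            rownames(aln)[hit[1L]], hit[2L]
          ),
          "stop_error"
        )
      }
      mat <- unclass_aln(aln)
      idx <- which(is_stop, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        jj <- (idx[r, 2L] - 1L) * 3L + 1:3
        mat[idx[r, 1L], jj] <- "-"
      }
      return(new_gene_alignment(mat, gene_id(aln), masked_stops = nrow(idx)))
    }
  }
  aln
}

unclass_aln <- function(x) {
  attr(x, "gene_id") <- NULL
  attr(x, "masked_stops") <- NULL
  class(x) <- NULL
  x
}

#' Alignment accessors
#'
#' @param x A [gene_alignment()].
#' @return `gene_id()` the ortholog identifier; `alignment_labels()` the
#'   genome labels; `n_sites()` the alignment length in nucleotides;
#'   `n_codons()` the length in codons; `alignment_strings()` the sequences
#'   as a named character vector.
#' @export
gene_id <- function(x) attr(x, "gene_id")

#' @rdname gene_id
#' @export
alignment_labels <- function(x) rownames(x)

#' @rdname gene_id
#' @export
n_sites <- function(x) ncol(x)

#' @rdname gene_id
#' @export
n_codons <- function(x) ncol(x) %/% 3L

#' @rdname gene_id
#' @export
alignment_strings <- function(x) {
  apply(unclass_aln(x), 1L, paste, collapse = "")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf(
    "<gene_alignment '%s': %d sequences x %d nt (%d codons)>\n",
    gene_id(x), nrow(x), ncol(x), n_codons(x)
  ))
  invisible(x)
}

#' Read a per-gene codon alignment from FASTA
#'
#' Reads a FASTA file of aligned, in-frame coding sequences and validates it
#' as a [gene_alignment()]. The genome label is the first whitespace-delimited
#' token of each header line.
#'
#' @param path FASTA file path.
#' @param gene_id Ortholog identifier; defaults to the file name without
#'   extension.
#' @inheritParams gene_alignment
#' @return A [gene_alignment()].
#' @export
read_gene_alignment <- function(path, gene_id = NULL,
                                internal_stops = c("error", "mask"),
                                code = genetic_code(11)) {
  seqs <- read_fasta(path)
  if (length(seqs) < 2L) {
    coremk_abort(
      sprintf("'%s' contains fewer than 2 sequences", path),
      "input_error"
    )
  }
  gene_id <- gene_id %||% sub("\\.[A-Za-z0-9]+$", "", basename(path))
  gene_alignment(seqs, gene_id = gene_id, internal_stops = internal_stops, code = code)
}

#' Read and write FASTA as named character vectors
#'
#' Thin wrappers around `Biostrings` for reading and a deterministic
#' plain-text writer (one sequence line per record, so that
#' read-write-read round-trips are byte-identical).
#'
#' @param path File path.
#' @param x Named character vector of sequences.
#' @return `read_fasta()` a named character vector; `write_fasta()` the path,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    coremk_abort(sprintf("file not found: '%s'", path), "input_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      coremk_abort(sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e)), "input_error")
    }
  )
  labs <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(labs)) {
    coremk_abort(
      sprintf("duplicate sequence IDs in '%s'", path),
      "input_error"
    )
  }
  setNames(as.character(set), labs)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  con <- file(path, open = "wb") # binary: identical bytes on any platform
  on.exit(close(con))
  writeLines(paste0(">", names(x), "\n", x), con, sep = "\n")
  invisible(path)
}

#' Write a gene alignment to FASTA
#'
#' @param alignment A [gene_alignment()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gene_alignment <- function(alignment, path) {
  write_fasta(alignment_strings(alignment), path)
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Projects an amino-acid alignment onto the corresponding unaligned CDS: each
#' amino-acid column becomes one codon column and each gap becomes `"---"`.
#' Every protein sequence (gaps removed) must equal the translation of its
#' CDS; a trailing stop codon on the CDS is ignored.
#'
#' @param protein_alignment Named character vector of aligned amino-acid
#'   sequences (gaps as `-`), names = genome labels.
#' @param cds Named character vector of unaligned coding sequences covering
#'   the same labels.
#' @param gene_id Ortholog identifier for the result.
#' @param code Genetic code used for translation.
#' @return A [gene_alignment()] of codon-aligned nucleotide sequences.
#' @examples
#' back_translate(c(a = "M-K", b = "MEK"),
#'   cds = c(a = "ATGAAA", b = "ATGGAAAAG")
#' )
#' @export
back_translate <- function(protein_alignment, cds, gene_id = "gene",
                           code = genetic_code(11)) {
  if (is.null(names(protein_alignment)) || is.null(names(cds))) {
    coremk_abort("protein and CDS sequences must be named", "input_error")
  }
  if (!setequal(names(protein_alignment), names(cds))) {
    coremk_abort("protein and CDS label sets differ", "input_error")
  }
  protein_alignment <- toupper(protein_alignment)
  cds <- toupper(cds)
  out <- vapply(names(protein_alignment), function(lab) {
    prot <- strsplit(protein_alignment[[lab]], "", fixed = TRUE)[[1L]]
    dna <- cds[[lab]]
    if (nchar(dna) %% 3L != 0L) {
      coremk_abort(
        sprintf("CDS of '%s' has length not divisible by 3", lab),
        "frame_error"
      )
    }
    codons <- substring(dna, seq(1L, nchar(dna), 3L), seq(3L, nchar(dna), 3L))
    n_cod <- length(codons)
    # drop a trailing stop codon if present
    if (n_cod > 0L && codons[n_cod] %in% stop_codons(code)) {
      codons <- codons[-n_cod]
    }
    aa_cds <- translate_codons(codons, code)
    aa_prot <- prot[prot != "-"]
    if (length(aa_prot) != length(aa_cds) || !all(aa_prot == aa_cds)) {
      coremk_abort(
        sprintf("protein of '%s' does not match the translation of its CDS", lab),
        "consistency_error"
      )
    }
    row <- rep("---", length(prot))
    row[prot != "-"] <- codons
    paste(row, collapse = "")
  }, character(1L))
  gene_alignment(out, gene_id = gene_id, code = code)
}

#' Concatenate gene alignments into a per-genome concatemer
#'
#' Joins the alignments of all orthologs for every genome, in sorted
#' `gene_id` order so the result does not depend on the input list order.
#' All alignments must cover the identical set of genome labels.
#'
#' @param alignments List of [gene_alignment()] objects.
#' @param gene_id Identifier for the concatemer (default `"concatemer"`).
#' @return A [gene_alignment()] whose length is the sum of gene lengths, rows
#'   ordered by genome label.
#' @export
concatenate_alignments <- function(alignments, gene_id = "concatemer") {
  if (length(alignments) == 0L) {
    coremk_abort("no alignments to concatenate", "input_error")
  }
  ids <- vapply(alignments, function(a) gene_id(a), character(1L))
  if (anyDuplicated(ids)) {
    coremk_abort("duplicate gene_ids in concatenation input", "input_error")
  }
  alignments <- alignments[order(ids)]
  labs <- sort(alignment_labels(alignments[[1L]]))
  mats <- lapply(alignments, function(a) {
    if (!setequal(alignment_labels(a), labs)) {
      coremk_abort(
        sprintf("gene '%s' has a different genome label set", gene_id(a)),
        "input_error"
      )
    }
    unclass_aln(a)[labs, , drop = FALSE]
  })
  new_gene_alignment(do.call(cbind, mats), gene_id)
}

#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] and [ape::write.tree()].
#'
#' @param tree An [ape::phylo] tree.
#' @param path File path.
#' @return `read_newick()` a `phylo`; `write_newick()` the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
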