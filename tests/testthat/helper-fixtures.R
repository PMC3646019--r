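# Fixture builders shared across test files. Everything is generated in
# code; no data files are used.

# (helpers load alphabetically; the oracle helper defines this too)
if (!exists("oracle_code_map")) {
  oracle_code_map <- as.list(Biostrings::getGeneticCode("11"))
}

make_aln <- function(..., gene_id = "g") {
  gene_alignment(c(...), gene_id = gene_id)
}

SENSE11 <- names(oracle_code_map)[unlist(oracle_code_map) != "*"]

random_sense_cds <- function(n_codons) {
  paste(sample(SENSE11, n_codons, replace = TRUE), collapse = "")
}

# A random codon alignment (no gaps) built from a shared ancestral CDS with
# sprinkled substitutions that never create stop codons.
random_alignment <- function(n_seq = 4, n_codons = 30, n_mut = 10,
                             labels = sprintf("s%02d", seq_len(n_seq))) {
  anc <- strsplit(random_sense_cds(n_codons), "")[[1]]
  seqs <- matrix(anc, n_seq, length(anc), byrow = TRUE)
  tries <- 0
  placed <- 0
  while (placed < n_mut && tries < 50 * n_mut) {
    tries <- tries + 1
    p <- sample.int(length(anc), 1)
    s <- sample.int(n_seq, 1)
    new <- sample(setdiff(c("A", "C", "G", "T"), seqs[s, p]), 1)
    cand <- seqs[s, ]
    cand[p] <- new
    ci <- (p - 1) %/% 3
    codon <- paste(cand[ci * 3 + 1:3], collapse = "")
    if (identical(oracle_code_map[[codon]], "*")) next
    seqs[s, p] <- new
    placed <- placed + 1
  }
  gene_alignment(setNames(apply(seqs, 1, paste, collapse = ""), labels))
}

# Alignment whose polymorphic sites are all consistent with one genealogy:
# each mutation's carrier set is a clade of a single random coalescent tree,
# so every site pair is compatible (homoplasy-free evolution).
tree_consistent_alignment <- function(n_seq = 8, n_codons = 80, n_mut = 30) {
  tr <- ape::rcoal(n_seq, tip.label = sprintf("s%02d", seq_len(n_seq)))
  clades <- ape::prop.part(tr)
  clade_sets <- lapply(clades, function(idx) tr$tip.label[idx])
  # add tip "clades" (singletons) as well
  clade_sets <- c(clade_sets, as.list(tr$tip.label))
  clade_sets <- Filter(function(s) length(s) < n_seq, clade_sets)

  anc <- strsplit(random_sense_cds(n_codons), "")[[1]]
  seqs <- matrix(anc, n_seq, length(anc), byrow = TRUE)
  rownames(seqs) <- sprintf("s%02d", seq_len(n_seq))
  pos_pool <- sample.int(length(anc))
  used_codons <- integer(0) # one mutation per codon: no combined stop risk
  placed <- 0
  i <- 1
  while (placed < n_mut && i <= length(pos_pool)) {
    p <- pos_pool[i]
    i <- i + 1
    ci <- (p - 1) %/% 3
    if (ci %in% used_codons) next
    carriers <- clade_sets[[sample.int(length(clade_sets), 1)]]
    new <- sample(setdiff(c("A", "C", "G", "T"), anc[p]), 1)
    cand <- anc
    cand[p] <- new
    codon <- paste(cand[ci * 3 + 1:3], collapse = "")
    if (identical(oracle_code_map[[codon]], "*")) next
    seqs[carriers, p] <- new
    used_codons <- c(used_codons, ci)
    placed <- placed + 1
  }
  gene_alignment(setNames(apply(seqs, 1, paste, collapse = ""), rownames(seqs)))
}

# Mosaic alignment: the 5' half of the gene carries clade markers of one
# topology, the 3' half of a conflicting topology — a forced half-gene
# recombinant with strong, clean signal.
two_tree_mosaic_alignment <- function(n_codons = 100, sites_per_half = 12) {
  labs <- sprintf("s%d", 1:8)
  top_a <- list(c(1, 2), c(3, 4), c(5, 6), c(7, 8), 1:4, 5:8)
  top_b <- list(c(1, 5), c(2, 6), c(3, 7), c(4, 8), c(1, 2, 5, 6), c(3, 4, 7, 8))
  len <- 3 * n_codons
  anc <- strsplit(random_sense_cds(n_codons), "")[[1]]
  seqs <- matrix(anc, 8, len, byrow = TRUE)
  used_codons <- integer(0)
  place <- function(seqs, tops, positions) {
    for (p in positions) {
      ci <- (p - 1) %/% 3
      if (ci %in% used_codons) next
      carriers <- tops[[sample.int(length(tops), 1)]]
      new <- sample(setdiff(c("A", "C", "G", "T"), anc[p]), 1)
      cand <- anc
      cand[p] <- new
      if (identical(oracle_code_map[[paste(cand[ci * 3 + 1:3], collapse = "")]], "*")) next
      seqs[carriers, p] <- new
      used_codons <<- c(used_codons, ci)
    }
    seqs
  }
  half <- (len %/% 2) - ((len %/% 2) %% 3) # codon boundary
  seqs <- place(seqs, top_a, sample(seq_len(half), sites_per_half))
  seqs <- place(seqs, top_b, sample(seq(half + 1, len), sites_per_half))
  gene_alignment(setNames(apply(seqs, 1, paste, collapse = ""), labs))
}

write_temp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}
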