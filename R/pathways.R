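# Codon-pair substitution classification by shortest stop-free mutational
# pathways. For a pair of sense codons differing at m positions, every
# ordering of the m single-nucleotide steps is a shortest pathway; orderings
# whose intermediate codons are stops are discarded and the synonymous /
# non-synonymous step counts are averaged over the remainder. If every
# ordering passes through a stop (rare), the average is taken over all
# orderings instead.

.coremk_cache <- new.env(parent = emptyenv())

perm_rows <- function(m) {
  if (m == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- perm_rows(m - 1L)
  out <- matrix(0L, 0L, m)
  for (k in seq_len(m)) {
    rest <- setdiff(seq_len(m), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), m - 1L)))
  }
  unname(out)
}

pathway_pair <- function(a_chars, b_chars, map) {
  pos <- which(a_chars != b_chars)
  m <- length(pos)
  if (m == 0L) {
    return(c(syn = 0, nonsyn = 0))
  }
  perms <- perm_rows(m)
  syn_counts <- numeric(nrow(perms))
  nonsyn_counts <- numeric(nrow(perms))
  valid <- logical(nrow(perms))
  for (r in seq_len(nrow(perms))) {
    cur <- a_chars
    s <- 0
    ns <- 0
    ok <- TRUE
    for (stepk in seq_len(m)) {
      p <- pos[perms[r, stepk]]
      nxt <- cur
      nxt[p] <- b_chars[p]
      aa1 <- map[[paste(cur, collapse = "")]]
      aa2 <- map[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && stepk < m) ok <- FALSE # stop as intermediate codon
      if (aa1 == aa2) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    syn_counts[r] <- s
    nonsyn_counts[r] <- ns
    valid[r] <- ok
  }
  use <- if (any(valid)) valid else rep(TRUE, nrow(perms))
  c(syn = mean(syn_counts[use]), nonsyn = mean(nonsyn_counts[use]))
}

# 64x64 lookup matrices of pathway-averaged synonymous / non-synonymous
# counts, cached per genetic-code table.
pathway_tables <- function(code) {
  key <- paste0("pathways_", code$table_id)
  hit <- .coremk_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  codons <- names(code$map)
  chars <- strsplit(codons, "", fixed = TRUE)
  k <- length(codons)
  syn <- matrix(0, k, k, dimnames = list(codons, codons))
  nonsyn <- syn
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      pc <- pathway_pair(chars[[i]], chars[[j]], code$map)
      syn[i, j] <- pc[["syn"]]
      nonsyn[i, j] <- pc[["nonsyn"]]
    }
  }
  out <- list(syn = syn, nonsyn = nonsyn)
  .coremk_cache[[key]] <- out
  out
}

#' Pathway-averaged substitution counts between two codons
#'
#' Classifies the nucleotide differences between two sense codons into
#' synonymous and non-synonymous changes, averaging over all shortest
#' mutational pathways that avoid stop codons.
#'
#' @param from,to Three-letter DNA codons.
#' @param code A [genetic_code()] object.
#' @return Named numeric vector `c(syn = , nonsyn = )`; the two entries sum
#'   to the number of differing positions.
#' @examples
#' codon_path_counts("AAA", "AGG") # K -> R via AGA or AAG
#' @export
codon_path_counts <- function(from, to, code = genetic_code(11)) {
  stopifnot(nchar(from) == 3L, nchar(to) == 3L)
  tabs <- pathway_tables(code)
  if (!(from %in% rownames(tabs$syn)) || !(to %in% rownames(tabs$syn))) {
    coremk_abort("codons must be unambiguous DNA triplets", "input_error")
  }
  c(syn = tabs$syn[from, to], nonsyn = tabs$nonsyn[from, to])
}
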