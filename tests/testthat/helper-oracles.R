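# Independent oracles used to cross-check the implementation. These
# deliberately share no code with the package internals: translation goes
# straight through Biostrings tables, permutations are generated by a
# different recursion, and sums are written term by term.

oracle_code_map <- as.list(Biostrings::getGeneticCode("11"))

# All orderings of a vector, as a list (independent of the package's
# permutation matrix builder).
oracle_orderings <- function(v) {
  if (length(v) <= 1L) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_orderings(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# Pathway-averaged syn/nonsyn counts between two sense codons: enumerate
# every ordering of the differing positions, walk the mutational path,
# discard paths whose intermediate codons are stops (fall back to all paths
# when every ordering is blocked), and average the per-step classifications.
oracle_path_counts <- function(a, b, map = oracle_code_map) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  pos <- which(av != bv)
  if (length(pos) == 0L) {
    return(c(syn = 0, nonsyn = 0))
  }
  paths <- list()
  for (ord in oracle_orderings(pos)) {
    cur <- av
    steps <- character(0)
    blocked <- FALSE
    for (k in seq_along(ord)) {
      nxt <- cur
      nxt[ord[k]] <- bv[ord[k]]
      aa_cur <- map[[paste(cur, collapse = "")]]
      aa_nxt <- map[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" && k < length(ord)) blocked <- TRUE
      steps <- c(steps, if (aa_cur == aa_nxt) "s" else "n")
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- list(steps = steps, blocked = blocked)
  }
  open <- Filter(function(p) !p$blocked, paths)
  if (length(open) == 0L) open <- paths
  syn <- mean(vapply(open, function(p) sum(p$steps == "s"), numeric(1)))
  nonsyn <- mean(vapply(open, function(p) sum(p$steps == "n"), numeric(1)))
  c(syn = syn, nonsyn = nonsyn)
}

# MK cell counts for a single codon column, by explicit enumeration:
# polymorphism from the most frequent ingroup codon (lexicographic ties) to
# each other observed codon; divergence only when the ingroup is
# monomorphic, against the strict-majority outgroup codon.
oracle_single_codon_mk <- function(in_codons, out_codons, map = oracle_code_map) {
  sense <- names(map)[unlist(map) != "*"]
  if (!all(c(in_codons, out_codons) %in% sense)) {
    return(NULL)
  }
  counts <- sort(table(in_codons), decreasing = TRUE)
  top <- names(counts)[counts == max(counts)]
  major <- sort(top)[1]
  rep_tab <- table(out_codons)
  rep_c <- names(rep_tab)[rep_tab > length(out_codons) / 2]
  if (length(rep_c) == 0L) {
    return(NULL) # no strict-majority outgroup codon: column skipped
  }
  p <- c(syn = 0, nonsyn = 0)
  d <- c(syn = 0, nonsyn = 0)
  distinct <- unique(in_codons)
  if (length(distinct) > 1L) {
    for (cdn in setdiff(distinct, major)) {
      p <- p + oracle_path_counts(major, cdn, map)
    }
  } else if (distinct != rep_c) {
    d <- oracle_path_counts(distinct, rep_c, map)
  }
  list(p_s = p[["syn"]], p_n = p[["nonsyn"]], d_s = d[["syn"]], d_n = d[["nonsyn"]])
}

# Term-by-term weighted Neutrality Index (pooled), written as an explicit
# loop over genes.
oracle_ni_tg <- function(p_n, p_s, d_n, d_s) {
  num <- 0
  den <- 0
  for (i in seq_along(p_n)) {
    w <- p_s[i] + d_s[i]
    if (w > 0) {
      num <- num + d_s[i] * p_n[i] / w
      den <- den + p_s[i] * d_n[i] / w
    }
  }
  num / den
}

# Brute-force JC69 distances by per-pair column scan.
oracle_jc69 <- function(seqs) {
  labs <- names(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- chars[[i]]
      y <- chars[[j]]
      use <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
      p <- sum(x[use] != y[use]) / sum(use)
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

# Two-sided Fisher exact p for a 2x2 table via hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Chi-squared (no continuity correction) p for a 2x2 table.
oracle_chisq_2x2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# Mean pairwise incompatibility over in-window informative-site pairs,
# recomputed by a direct double loop with a four-gamete/partition check via
# igraph-free cycle counting on an adjacency list.
oracle_pair_incompat <- function(x, y) {
  keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[keep]
  y <- y[keep]
  combos <- unique(data.frame(x = x, y = y))
  vs <- c(paste0("L", unique(x)), paste0("R", unique(y)))
  adj <- setNames(vector("list", length(vs)), vs)
  for (r in seq_len(nrow(combos))) {
    a <- paste0("L", combos$x[r])
    b <- paste0("R", combos$y[r])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(0)
  ncomp <- 0
  for (v in vs) {
    if (v %in% seen) next
    ncomp <- ncomp + 1
    queue <- v
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      if (cur %in% seen) next
      seen <- c(seen, cur)
      queue <- c(queue, setdiff(adj[[cur]], seen))
    }
  }
  nrow(combos) - length(vs) + ncomp
}
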