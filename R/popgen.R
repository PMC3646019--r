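# Ingroup population-genetic summaries: segregating sites, nucleotide
# diversity, Watterson's theta, and the site-frequency spectrum.

ingroup_matrix <- function(alignment, ingroup) {
  labs <- alignment_labels(alignment)
  ingroup <- ingroup %||% labs
  miss <- setdiff(ingroup, labs)
  if (length(miss) > 0L) {
    coremk_abort(
      sprintf("labels not in alignment: %s", paste(miss, collapse = ", ")),
      "input_error"
    )
  }
  if (length(ingroup) < 2L) {
    coremk_abort("need at least 2 ingroup sequences", "input_error")
  }
  unclass_aln(alignment)[ingroup, , drop = FALSE]
}

#' Segregating sites
#'
#' Counts nucleotide columns carrying two or more distinct bases among the
#' ingroup. Columns containing a gap or ambiguity character in any ingroup
#' sequence are skipped. A triallelic column counts as one segregating site.
#'
#' @param alignment A [gene_alignment()].
#' @param ingroup Genome labels to use (default: all sequences).
#' @return Integer `S`, with attributes `sites_used` (number of clean
#'   columns) and `positions` (alignment positions of the segregating
#'   columns).
#' @export
segregating_sites <- function(alignment, ingroup = NULL) {
  m <- ingroup_matrix(alignment, ingroup)
  ok <- colSums(!matrix(is_acgt(m), nrow = nrow(m))) == 0L
  seg <- ok & colSums(m != matrix(m[1L, ], nrow(m), ncol(m), byrow = TRUE)) > 0L
  structure(sum(seg),
    sites_used = sum(ok),
    positions = which(seg)
  )
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise difference proportion over all sequence pairs of the
#' ingroup. Each pair is compared over the columns where both sequences
#' carry an unambiguous base, so the per-site scale is robust to gaps.
#'
#' @inheritParams segregating_sites
#' @return Per-site nucleotide diversity (numeric scalar).
#' @export
nucleotide_diversity <- function(alignment, ingroup = NULL) {
  m <- ingroup_matrix(alignment, ingroup)
  n <- nrow(m)
  ok <- matrix(is_acgt(m), nrow = n)
  total <- 0
  npair <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc > 0L) {
        total <- total + sum(m[i, comp] != m[j, comp]) / nc
      }
      npair <- npair + 1L
    }
  }
  total / npair
}

#' Watterson's theta
#'
#' `theta_w = S / (a_n * L)` with `a_n = sum(1 / (1:(n-1)))`, the per-site
#' population mutation rate estimated from the number of segregating sites.
#'
#' @param s Number of segregating sites.
#' @param n Number of sequences (`n >= 2`).
#' @param l Number of sites surveyed (`l >= 1`).
#' @return Per-site theta (numeric scalar).
#' @examples
#' watterson_theta(5, 4, 100)
#' @export
watterson_theta <- function(s, n, l) {
  if (n < 2L) coremk_abort("watterson_theta needs n >= 2", "input_error")
  if (l < 1L) coremk_abort("watterson_theta needs l >= 1", "input_error")
  a_n <- sum(1 / seq_len(n - 1L))
  s / (a_n * l)
}

#' Per-gene diversity summary
#'
#' @inheritParams segregating_sites
#' @return One-row tibble: `n_sequences`, `sites_used`, `s`, `pi`,
#'   `theta_w` (both per usable site).
#' @export
diversity_stats <- function(alignment, ingroup = NULL) {
  m <- ingroup_matrix(alignment, ingroup)
  s <- segregating_sites(alignment, ingroup = ingroup %||% alignment_labels(alignment))
  sites_used <- attr(s, "sites_used")
  tibble(
    n_sequences = nrow(m),
    sites_used = sites_used,
    s = as.integer(s),
    pi = nucleotide_diversity(alignment, ingroup = ingroup %||% alignment_labels(alignment)),
    theta_w = if (sites_used > 0L) {
      watterson_theta(as.integer(s), nrow(m), sites_used)
    } else {
      NA_real_
    }
  )
}

#' Site-frequency spectrum
#'
#' Tabulates derived-allele counts over the biallelic ingroup columns (clean
#' of gaps and ambiguity codes). Sites are polarized by the outgroup
#' representative base (single outgroup sequence, or strict-majority
#' consensus): when the outgroup carries one of the two ingroup alleles the
#' other allele is taken as derived and the site enters the unfolded
#' spectrum; otherwise the site is unpolarizable and enters only the folded
#' (minor-allele) spectrum, which is tabulated over all biallelic sites.
#' Polarized sites are additionally split into synonymous and non-synonymous
#' spectra when the substitution can be classified on the ingroup consensus
#' codon background.
#'
#' @param alignment A [gene_alignment()].
#' @param ingroup Genome labels forming the population sample.
#' @param outgroup Genome labels used for polarization, or `NULL` for a
#'   folded-only spectrum.
#' @param code A [genetic_code()] used for the synonymous split.
#' @return An object of class `coremk_sfs`: list with `n` (sample size),
#'   `unfolded` (counts indexed 1..n-1), `folded` (counts indexed
#'   1..floor(n/2)), `syn` and `nonsyn` (unfolded split spectra),
#'   `biallelic_sites` and `polarizable_sites`.
#' @export
site_frequency_spectrum <- function(alignment, ingroup = NULL, outgroup = NULL,
                                    code = genetic_code(11)) {
  m <- ingroup_matrix(alignment, ingroup)
  n <- nrow(m)
  out_m <- NULL
  if (!is.null(outgroup)) {
    labs <- alignment_labels(alignment)
    miss <- setdiff(outgroup, labs)
    if (length(miss) > 0L) {
      coremk_abort(
        sprintf("labels not in alignment: %s", paste(miss, collapse = ", ")),
        "input_error"
      )
    }
    out_m <- unclass_aln(alignment)[outgroup, , drop = FALSE]
  }

  unfolded <- numeric(n - 1L)
  folded <- numeric(max(n %/% 2L, 1L))
  syn <- numeric(n - 1L)
  nonsyn <- numeric(n - 1L)
  biallelic <- 0L
  polarizable <- 0L

  ok <- colSums(!matrix(is_acgt(m), nrow = n)) == 0L
  seg <- which(ok & colSums(m != matrix(m[1L, ], n, ncol(m), byrow = TRUE)) > 0L)
  for (p in seg) {
    col <- m[, p]
    alleles <- sort(unique(col))
    if (length(alleles) != 2L) next # triallelic+: S and pi only
    biallelic <- biallelic + 1L
    k1 <- sum(col == alleles[1L])
    folded_k <- min(k1, n - k1)
    folded[folded_k] <- folded[folded_k] + 1

    if (is.null(out_m)) next
    out_col <- out_m[, p]
    out_col <- out_col[is_acgt(out_col)]
    anc <- if (length(out_col) > 0L) strict_majority(out_col) else NA_character_
    if (is.na(anc) || !(anc %in% alleles)) next # unpolarizable
    derived <- setdiff(alleles, anc)
    k <- sum(col == derived)
    polarizable <- polarizable + 1L
    unfolded[k] <- unfolded[k] + 1

    cls <- classify_site(m, p, alleles, anc, derived, code)
    if (identical(cls, "syn")) syn[k] <- syn[k] + 1
    if (identical(cls, "nonsyn")) nonsyn[k] <- nonsyn[k] + 1
  }

  structure(
    list(
      n = n, unfolded = unfolded, folded = folded,
      syn = syn, nonsyn = nonsyn,
      biallelic_sites = biallelic, polarizable_sites = polarizable
    ),
    class = "coremk_sfs"
  )
}

# Synonymous / non-synonymous classification of a biallelic nucleotide site
# on the ingroup consensus codon background; NA when the flanking codon
# positions are polymorphic, ambiguous or produce a stop codon.
classify_site <- function(m, p, alleles, anc, derived, code) {
  cidx <- (p - 1L) %/% 3L
  jj <- cidx * 3L + 1:3
  off <- p - cidx * 3L
  background <- m[, jj, drop = FALSE]
  flank <- background[, -off, drop = FALSE]
  if (any(!is_acgt(flank)) ||
    any(flank != matrix(flank[1L, ], nrow(flank), ncol(flank), byrow = TRUE))) {
    return(NA_character_)
  }
  anc_cod <- background[1L, ]
  anc_cod[off] <- anc
  der_cod <- anc_cod
  der_cod[off] <- derived
  a1 <- translate_codons(paste(anc_cod, collapse = ""), code)
  a2 <- translate_codons(paste(der_cod, collapse = ""), code)
  if (a1 %in% c("*", "X") || a2 %in% c("*", "X")) {
    return(NA_character_)
  }
  if (a1 == a2) "syn" else "nonsyn"
}

#' @export
print.coremk_sfs <- function(x, ...) {
  cat(sprintf(
    "<site-frequency spectrum: n = %d, %d biallelic sites (%d polarized)>\n",
    x$n, x$biallelic_sites, x$polarizable_sites
  ))
  cat(" unfolded:", paste(x$unfolded, collapse = " "), "\n")
  cat(" folded:  ", paste(x$folded, collapse = " "), "\n")
  invisible(x)
}

#' @export
as_tibble.coremk_sfs <- function(x, ...) {
  tibble(
    frequency_class = seq_len(x$n - 1L),
    unfolded = x$unfolded,
    syn = x$syn,
    nonsyn = x$nonsyn,
    folded = c(x$folded, rep(NA_real_, x$n - 1L - length(x$folded)))
  )
}
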