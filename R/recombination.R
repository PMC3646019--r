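# Pairwise homoplasy index (PHI): a permutation test for intragenic
# recombination. Recombination lets nearby site pairs stay compatible while
# distant pairs accumulate incompatibility, so a windowed mean incompatibility
# that is low relative to site-order permutations signals recombination.

# Parsimony-informative columns: at least two states each carried by at
# least two sequences (non-ACGT characters are treated as missing).
informative_columns <- function(mat) {
  which(apply(mat, 2L, function(col) {
    col <- col[is_acgt(col)]
    if (length(col) < 4L) {
      return(FALSE)
    }
    tab <- table(col)
    sum(tab >= 2L) >= 2L
  }))
}

#' Refined incompatibility score of two characters
#'
#' The minimum number of extra state changes, beyond the parsimony minimum
#' for each character alone, needed to fit both characters on a single tree.
#' Computed via the partition-intersection graph: vertices are the observed
#' states of each character, edges the jointly observed state pairs; the
#' score is the graph's cycle rank `|E| - |V| + c`. It is 0 exactly when the
#' two characters are compatible (for binary characters, when at most three
#' of the four gametes occur).
#'
#' @param site_i,site_j Character vectors of per-sequence states (same
#'   length); non-ACGT entries are treated as missing and the corresponding
#'   sequences dropped pairwise.
#' @return Non-negative integer score.
#' @examples
#' pairwise_incompatibility(c("A", "A", "G", "G"), c("C", "T", "C", "T"))
#' @export
pairwise_incompatibility <- function(site_i, site_j) {
  if (length(site_i) != length(site_j)) {
    coremk_abort("site columns must have equal length", "input_error")
  }
  keep <- is_acgt(site_i) & is_acgt(site_j)
  x <- site_i[keep]
  y <- site_j[keep]
  if (length(x) == 0L) {
    return(0L)
  }
  edges <- unique(paste(x, y))
  vx <- unique(x)
  vy <- unique(y)
  n_v <- length(vx) + length(vy)
  # connected components by union-find over the small state graph
  parent <- seq_len(n_v)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  ex <- match(substr(edges, 1L, 1L), vx)
  ey <- match(substr(edges, 3L, 3L), vy) + length(vx)
  for (e in seq_along(edges)) {
    ra <- find(ex[e])
    rb <- find(ey[e])
    if (ra != rb) parent[ra] <- rb
  }
  n_comp <- length(unique(vapply(seq_len(n_v), find, integer(1L))))
  as.integer(length(edges) - n_v + n_comp)
}

phi_profile <- function(alignment, window) {
  mat <- unclass_aln(alignment)
  pos <- informative_columns(mat)
  k <- length(pos)
  if (k < 2L) {
    return(list(positions = pos, A = NULL, ii = integer(0), jj = integer(0)))
  }
  A <- matrix(0L, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      A[i, j] <- A[j, i] <- pairwise_incompatibility(mat[, pos[i]], mat[, pos[j]])
    }
  }
  pr <- which(
    outer(pos, pos, function(a, b) abs(a - b)) <= window &
      upper.tri(A),
    arr.ind = TRUE
  )
  list(positions = pos, A = A, ii = pr[, 1L], jj = pr[, 2L])
}

#' Windowed pairwise homoplasy statistic
#'
#' Mean [pairwise_incompatibility()] over all pairs of parsimony-informative
#' sites at most `window` nucleotides apart.
#'
#' @param alignment A [gene_alignment()].
#' @param window Maximum pair distance in nucleotides (default 100).
#' @return The statistic, or `NA` when fewer than two informative sites (or
#'   no pair within the window) exist; the number of informative sites is
#'   attached as attribute `informative_sites`.
#' @export
phi_statistic <- function(alignment, window = 100) {
  prof <- phi_profile(alignment, window)
  k <- length(prof$positions)
  obs <- if (k < 2L || length(prof$ii) == 0L) {
    NA_real_
  } else {
    mean(prof$A[cbind(prof$ii, prof$jj)])
  }
  structure(obs, informative_sites = k)
}

#' PHI permutation test for recombination
#'
#' Compares the observed windowed homoplasy statistic with its distribution
#' under random permutations of the order of informative sites. Permuting
#' destroys the physical clustering of compatible sites, so under
#' recombination the observed statistic is low relative to the permuted
#' ones: `p = (1 + #\{permuted <= observed\}) / (n_permutations + 1)`.
#'
#' @inheritParams phi_statistic
#' @param n_permutations Number of permutations (default 1000; must be
#'   positive).
#' @param seed Integer seed, or `NULL` for the current RNG state.
#' @param gene_id Identifier copied into the result (defaults to the
#'   alignment's).
#' @return One-row tibble: `gene_id`, `informative_sites`, `phi_observed`,
#'   `p_value`, `n_permutations`. `phi_observed` and `p_value` are `NA` when
#'   the statistic is undefined (such genes pass the recombination filter by
#'   default).
#' @export
phi_test <- function(alignment, n_permutations = 1000, window = 100,
                     seed = NULL, gene_id = NULL) {
  if (n_permutations < 1L) {
    coremk_abort("n_permutations must be a positive integer", "input_error")
  }
  gene_id <- gene_id %||% gene_id(alignment)
  prof <- phi_profile(alignment, window)
  k <- length(prof$positions)
  if (k < 2L || length(prof$ii) == 0L) {
    return(tibble(
      gene_id = gene_id, informative_sites = k,
      phi_observed = NA_real_, p_value = NA_real_,
      n_permutations = as.integer(n_permutations)
    ))
  }
  obs <- mean(prof$A[cbind(prof$ii, prof$jj)])
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      pi_b <- sample.int(k)
      mean(prof$A[cbind(pi_b[prof$ii], pi_b[prof$jj])])
    }, numeric(1L))
  })
  p <- (1 + sum(perm_stats <= obs + 1e-12)) / (n_permutations + 1)
  tibble(
    gene_id = gene_id, informative_sites = k,
    phi_observed = obs, p_value = p,
    n_permutations = as.integer(n_permutations)
  )
}
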