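# Distances, UPGMA trees, outgroup designation from the first split, and
# per-gene congruency filtering.

#' Jukes-Cantor (JC69) distance matrix
#'
#' Pairwise JC69 distances over the columns where both sequences carry an
#' unambiguous base (pairwise deletion of gapped or ambiguous positions):
#' `d = -3/4 * log(1 - 4p/3)` with `p` the mismatch proportion.
#'
#' @param alignment A [gene_alignment()].
#' @return A symmetric numeric matrix with genome labels as dimnames.
#' @section Errors: A saturated pair (`p >= 0.75`) or a pair with no
#'   comparable column aborts with class `coremk_distance_error`.
#' @export
jc69_distance <- function(alignment) {
  mat <- unclass_aln(alignment)
  n <- nrow(mat)
  labs <- rownames(mat)
  ok <- matrix(is_acgt(mat), nrow = n)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        coremk_abort(
          sprintf("no comparable columns between '%s' and '%s'", labs[i], labs[j]),
          "distance_error"
        )
      }
      p <- sum(mat[i, comp] != mat[j, comp]) / nc
      if (p >= 0.75) {
        coremk_abort(
          sprintf(
            "saturated pair '%s'/'%s' (mismatch proportion %.3f >= 0.75)",
            labs[i], labs[j], p
          ),
          "distance_error"
        )
      }
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering. Each merge places the new node at
#' half the merge distance, so the tree is rooted, binary and ultrametric.
#' Tied merges are resolved deterministically: among all pairs at the minimum
#' distance, the pair whose sorted cluster keys (the lexicographically
#' smallest leaf label within each cluster) come first is merged.
#'
#' @param d Symmetric distance matrix with labelled rows/columns, or a
#'   [stats::dist] object.
#' @return A rooted ultrametric [ape::phylo] tree.
#' @examples
#' d <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' upgma(d)
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  labs <- rownames(m)
  if (is.null(labs) || is.null(colnames(m)) || !identical(labs, colnames(m))) {
    coremk_abort("distance matrix must have matching row/column labels", "input_error")
  }
  n <- nrow(m)
  if (n < 2L) {
    coremk_abort("need at least 2 labels to build a tree", "input_error")
  }
  if (anyDuplicated(labs)) {
    coremk_abort("duplicate labels in distance matrix", "input_error")
  }
  if (any(!is.finite(m)) || any(m < 0) || any(abs(diag(m)) > 1e-12) ||
    any(abs(m - t(m)) > 1e-9)) {
    coremk_abort("distance matrix must be finite, non-negative and symmetric with zero diagonal", "input_error")
  }

  newick <- labs
  height <- rep(0, n)
  size <- rep(1L, n)
  key <- labs
  active <- rep(TRUE, n)
  D <- m
  fmt <- function(x) sprintf("%.15g", max(x, 0))

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    dmin <- Inf
    for (a in idx) {
      for (b in idx) {
        if (a < b && D[a, b] < dmin) dmin <- D[a, b]
      }
    }
    # candidate pairs at the minimum (within numerical noise); deterministic pick
    best <- NULL
    best_key <- NULL
    for (a in idx) {
      for (b in idx) {
        if (a < b && D[a, b] <= dmin + 1e-12) {
          k <- sort(c(key[a], key[b]))
          if (is.null(best) ||
            k[1L] < best_key[1L] ||
            (k[1L] == best_key[1L] && k[2L] < best_key[2L])) {
            best <- c(a, b)
            best_key <- k
          }
        }
      }
    }
    i <- best[1L]
    j <- best[2L]
    h <- dmin / 2
    newick[i] <- paste0(
      "(", newick[i], ":", fmt(h - height[i]),
      ",", newick[j], ":", fmt(h - height[j]), ")"
    )
    # average-linkage update into slot i
    for (k2 in idx) {
      if (k2 != i && k2 != j) {
        D[i, k2] <- D[k2, i] <-
          (size[i] * D[i, k2] + size[j] * D[j, k2]) / (size[i] + size[j])
      }
    }
    height[i] <- h
    size[i] <- size[i] + size[j]
    key[i] <- min(key[i], key[j])
    active[j] <- FALSE
  }
  ape::read.tree(text = paste0(newick[which(active)], ";"))
}

#' Bipartition at the root of a tree
#'
#' Returns the two leaf-label sets induced by the root's two children — the
#' "first split" used for automatic ingroup/outgroup designation.
#'
#' @param tree A rooted binary [ape::phylo] tree.
#' @return A `taxon_split`: list with sorted character vectors `clade_a` and
#'   `clade_b`; `clade_a` is the clade containing the lexicographically
#'   smallest label.
#' @export
first_split <- function(tree) {
  if (!inherits(tree, "phylo")) {
    coremk_abort("tree must be an ape 'phylo' object", "input_error")
  }
  ntip <- length(tree$tip.label)
  if (ntip < 2L) {
    coremk_abort("tree must have at least 2 leaves", "input_error")
  }
  root <- ntip + 1L
  children <- tree$edge[tree$edge[, 1L] == root, 2L]
  if (length(children) != 2L) {
    coremk_abort("tree root is not binary; cannot take its first split", "input_error")
  }
  tips_under <- function(node) {
    if (node <= ntip) {
      return(tree$tip.label[node])
    }
    stack <- node
    tips <- character(0)
    while (length(stack) > 0L) {
      cur <- stack[1L]
      stack <- stack[-1L]
      kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
      tips <- c(tips, tree$tip.label[kids[kids <= ntip]])
      stack <- c(stack, kids[kids > ntip])
    }
    tips
  }
  taxon_split(tips_under(children[1L]), tips_under(children[2L]))
}

#' Construct a taxon split
#'
#' An unordered bipartition of genome labels into two disjoint non-empty
#' clades, as produced by [first_split()] or supplied explicitly.
#'
#' @param clade_a,clade_b Character vectors of genome labels.
#' @return A `taxon_split` object. The clade containing the lexicographically
#'   smallest label is stored as `clade_a`.
#' @export
taxon_split <- function(clade_a, clade_b) {
  clade_a <- sort(unique(as.character(clade_a)))
  clade_b <- sort(unique(as.character(clade_b)))
  if (length(clade_a) == 0L || length(clade_b) == 0L) {
    coremk_abort("both clades of a split must be non-empty", "input_error")
  }
  if (length(intersect(clade_a, clade_b)) > 0L) {
    coremk_abort("split clades must be disjoint", "input_error")
  }
  if (clade_b[1L] < clade_a[1L]) {
    tmp <- clade_a
    clade_a <- clade_b
    clade_b <- tmp
  }
  structure(list(clade_a = clade_a, clade_b = clade_b), class = "taxon_split")
}

#' @export
print.taxon_split <- function(x, ...) {
  cat(sprintf(
    "<taxon split: {%s} | {%s}>\n",
    paste(x$clade_a, collapse = ","), paste(x$clade_b, collapse = ",")
  ))
  invisible(x)
}

#' Is a gene tree congruent with a reference split?
#'
#' A gene tree is congruent when its own first split equals the reference
#' split as an unordered pair of label sets. Used to flag orthologs whose
#' history disagrees with the concatemer tree (e.g. inter-taxon
#' recombinants).
#'
#' @param gene_tree A rooted binary [ape::phylo] tree.
#' @param reference_split A [taxon_split()].
#' @return Logical scalar.
#' @export
is_congruent <- function(gene_tree, reference_split) {
  if (!inherits(reference_split, "taxon_split")) {
    coremk_abort("reference_split must be a taxon_split", "input_error")
  }
  all_ref <- c(reference_split$clade_a, reference_split$clade_b)
  if (!setequal(gene_tree$tip.label, all_ref)) {
    coremk_abort("gene tree and reference split cover different label sets", "input_error")
  }
  gs <- first_split(gene_tree)
  (identical(gs$clade_a, reference_split$clade_a) &&
    identical(gs$clade_b, reference_split$clade_b))
}
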