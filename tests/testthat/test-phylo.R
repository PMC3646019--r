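test_that("JC69 distances match the closed form and an independent scan", {
  set.seed(11)
  s <- random_sense_cds(400)
  aln <- gene_alignment(c(a = s, b = s))
  expect_equal(jc69_distance(aln)["a", "b"], 0)

  # p = 0.1 over 1000 sites -> d = -0.75 * log(1 - 0.4/3)
  chars <- strsplit(paste(rep("ACA", 334), collapse = ""), "")[[1]][1:1002]
  x <- paste(chars, collapse = "")
  y_chars <- chars
  flip <- seq(2, by = 10, length.out = round(0.1 * 1002))
  y_chars[flip] <- ifelse(y_chars[flip] == "C", "G", "C")
  y <- paste(y_chars, collapse = "")
  p_true <- mean(strsplit(x, "")[[1]] != y_chars)
  aln2 <- gene_alignment(c(a = x, b = y))
  expect_equal(
    jc69_distance(aln2)["a", "b"],
    -0.75 * log(1 - 4 * p_true / 3),
    tolerance = 1e-12
  )

  # saturation guard
  sat_y <- paste(ifelse(strsplit(x, "")[[1]] == "C", "G", "C"), collapse = "")
  expect_error(
    jc69_distance(gene_alignment(c(a = x, b = sat_y))),
    class = "coremk_distance_error"
  )

  # random fixtures vs per-pair column-scan oracle, with gaps
  for (rep in 1:10) {
    aln3 <- random_alignment(n_seq = 5, n_codons = 60, n_mut = 25)
    m <- unclass(aln3)
    m[2, 10:18] <- "-"
    seqs <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
    aln3 <- gene_alignment(seqs)
    expect_equal(jc69_distance(aln3), oracle_jc69(seqs), tolerance = 1e-12)
  }
})

test_that("JC69 agrees with ape's implementation under pairwise deletion", {
  set.seed(31)
  aln <- random_alignment(n_seq = 6, n_codons = 80, n_mut = 40)
  d_pkg <- jc69_distance(aln)
  bin <- ape::as.DNAbin(strsplit(alignment_strings(aln), ""))
  d_ape <- as.matrix(ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE))
  expect_equal(d_pkg[rownames(d_ape), colnames(d_ape)], d_ape, tolerance = 1e-10)
})

test_that("UPGMA recovers hand-built and random ultrametric trees exactly", {
  # two leaves
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(unname(t2$edge.length), c(0.1, 0.1))

  # hand-drawn ultrametric 4-taxon tree: ((a:1,b:1):2,(c:2,d:2):1)
  labs <- c("a", "b", "c", "d")
  d4 <- matrix(6, 4, 4, dimnames = list(labs, labs))
  diag(d4) <- 0
  d4["a", "b"] <- d4["b", "a"] <- 2
  d4["c", "d"] <- d4["d", "c"] <- 4
  t4 <- upgma(d4)
  coph <- ape::cophenetic.phylo(t4)[labs, labs]
  expect_equal(coph, d4, tolerance = 1e-9)
  sp <- first_split(t4)
  expect_equal(sp$clade_a, c("a", "b"))
  expect_equal(sp$clade_b, c("c", "d"))

  # random coalescent (ultrametric) trees: exact recovery of the cophenetic
  # matrix, and ultrametricity of the output
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(3:16, 1)
    tr <- ape::rcoal(n, tip.label = sprintf("t%02d", 1:n))
    dm <- ape::cophenetic.phylo(tr)
    rec <- upgma(dm)
    coph2 <- ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)]
    expect_equal(coph2, dm, tolerance = 1e-9)
    depths <- ape::node.depth.edgelength(rec)
    tip_depths <- depths[seq_len(n)]
    expect_lt(max(tip_depths) - min(tip_depths), 1e-9)
  }
})

test_that("UPGMA matches average-linkage hclust heights on tie-free matrices", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 8
    labs <- sprintf("x%d", 1:n)
    m <- matrix(0, n, n, dimnames = list(labs, labs))
    v <- runif(n * (n - 1) / 2, 0.1, 1)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    tr <- upgma(m)
    # the multiset of merge heights must agree (node height = merge dist / 2)
    depths <- ape::node.depth.edgelength(tr)
    root_age <- max(depths[1:n])
    node_ages <- root_age - depths[(n + 1):(2 * n - 1)]
    expect_equal(sort(node_ages) * 2, sort(hc$height), tolerance = 1e-9)
  }
})

test_that("tied merges resolve deterministically", {
  labs <- c("b", "a", "d", "c")
  m <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(m) <- 0 # every pair tied
  t1 <- ape::write.tree(upgma(m))
  for (i in 1:5) expect_identical(ape::write.tree(upgma(m)), t1)
  # lexicographically smallest pair (a, b) merges first
  sp <- first_split(upgma(m))
  expect_true("a" %in% c(sp$clade_a, sp$clade_b))
})

test_that("first_split returns the root bipartition", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  sp <- first_split(tr)
  expect_equal(sp$clade_a, c("A", "B"))
  expect_equal(sp$clade_b, c("C", "D"))

  tr2 <- ape::read.tree(text = "(A:2,(B:1,C:1):1);")
  sp2 <- first_split(tr2)
  expect_equal(sp2$clade_a, "A")
  expect_equal(sp2$clade_b, c("B", "C"))
})

test_that("congruency compares unordered first splits", {
  ref <- taxon_split(c("A", "B"), c("C", "D"))
  t_ok <- ape::read.tree(text = "((B:1,A:1):1,(D:1,C:1):1);")
  t_bad <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_true(is_congruent(t_ok, ref))
  expect_false(is_congruent(t_bad, ref))
  t_other <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(is_congruent(t_other, ref), class = "coremk_input_error")
})

test_that("the concatemer first split recovers the simulated taxon assignment", {
  cfg <- simulation_config(
    n_genes = 15, gene_length_codons = 120,
    n_ingroup = 4, n_outgroup = 3, seed = 404
  )
  sim <- simulate_core_genome(cfg)
  conc <- concatenate_alignments(sim$genes)
  sp <- first_split(upgma(jc69_distance(conc)))
  expect_equal(sp$clade_a, sort(sim$ingroup))
  expect_equal(sp$clade_b, sort(sim$outgroup))
})
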