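test_that("pathway classification matches the enumeration oracle over codon pairs", {
  code <- genetic_code(11)
  set.seed(13)
  sense <- sense_codons(code)
  pairs <- cbind(
    sample(sense, 300, replace = TRUE),
    sample(sense, 300, replace = TRUE)
  )
  for (r in seq_len(nrow(pairs))) {
    got <- codon_path_counts(pairs[r, 1], pairs[r, 2], code)
    want <- oracle_path_counts(pairs[r, 1], pairs[r, 2])
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    # steps conserve the nucleotide difference count
    nd <- sum(strsplit(pairs[r, 1], "")[[1]] != strsplit(pairs[r, 2], "")[[1]])
    expect_equal(sum(got), nd, tolerance = 1e-12)
  }
  # a multi-path pair with mixed classification: AAA (K) <-> AGG (R)
  expect_equal(unname(codon_path_counts("AAA", "AGG")), c(1, 1))
})

test_that("single-codon MK counting matches hand enumerations", {
  # segregating synonymous change: K/K polymorphism
  aln <- make_aln(i1 = "AAA", i2 = "AAA", i3 = "AAG", o1 = "AAA")
  cts <- count_mk(aln, c("i1", "i2", "i3"), "o1")
  expect_equal(
    cts[, c("p_n", "p_s", "d_n", "d_s")],
    tibble::tibble(p_n = 0, p_s = 1, d_n = 0, d_s = 0)
  )

  # fixed non-synonymous difference: K -> R
  aln2 <- make_aln(i1 = "AAA", i2 = "AAA", o1 = "AGA")
  cts2 <- count_mk(aln2, c("i1", "i2"), "o1")
  expect_equal(
    cts2[, c("p_n", "p_s", "d_n", "d_s")],
    tibble::tibble(p_n = 0, p_s = 0, d_n = 1, d_s = 0)
  )

  # identical codons: nothing to count
  aln3 <- make_aln(i1 = "ATG", i2 = "ATG", o1 = "ATG")
  cts3 <- count_mk(aln3, c("i1", "i2"), "o1")
  expect_equal(cts3$p_n + cts3$p_s + cts3$d_n + cts3$d_s, 0)

  # polymorphic codon never contributes to divergence, whatever the outgroup
  aln4 <- make_aln(i1 = "AAA", i2 = "AAG", o1 = "GGG")
  cts4 <- count_mk(aln4, c("i1", "i2"), "o1")
  expect_equal(cts4$d_n + cts4$d_s, 0)
  expect_equal(cts4$p_s, 1)

  # gapped codon in any counted sequence skips the column
  aln5 <- make_aln(i1 = "AAAATG", i2 = "AAAATG", o1 = "AGA---")
  cts5 <- count_mk(aln5, c("i1", "i2"), "o1")
  expect_equal(cts5$codons_used, 1L)
  expect_equal(cts5$d_n, 1)

  # no usable column at all
  aln6 <- make_aln(i1 = "---", i2 = "AAA", o1 = "AAA")
  expect_error(count_mk(aln6, c("i1", "i2"), "o1"), class = "coremk_count_error")
})

test_that("multi-strain outgroups use the strict-majority consensus codon", {
  # majority AGA among outgroup -> one nonsyn fixed difference
  aln <- make_aln(i1 = "AAA", i2 = "AAA", o1 = "AGA", o2 = "AGA", o3 = "AAA")
  cts <- count_mk(aln, c("i1", "i2"), c("o1", "o2", "o3"))
  expect_equal(cts$d_n, 1)
  # 1-1 outgroup: no strict majority, column skipped
  aln2 <- make_aln(i1 = "AAA", i2 = "AAA", o1 = "AGA", o2 = "AAA")
  expect_error(
    count_mk(aln2, c("i1", "i2"), c("o1", "o2")),
    class = "coremk_count_error"
  )
})

test_that("random single-codon cases agree with the explicit pathway oracle", {
  code <- genetic_code(11)
  sense <- sense_codons(code)
  set.seed(2024)
  n_cases <- 2000
  for (k in seq_len(n_cases)) {
    n_in <- sample(2:6, 1)
    n_out <- sample(1:3, 1)
    # draw from a small codon pool to make polymorphism/divergence frequent
    pool <- sample(sense, 3)
    in_cod <- sample(pool, n_in, replace = TRUE)
    out_cod <- sample(pool, n_out, replace = TRUE)
    labs_in <- sprintf("i%d", seq_len(n_in))
    labs_out <- sprintf("o%d", seq_len(n_out))
    aln <- gene_alignment(setNames(c(in_cod, out_cod), c(labs_in, labs_out)))
    want <- oracle_single_codon_mk(in_cod, out_cod)
    if (is.null(want)) {
      expect_error(count_mk(aln, labs_in, labs_out), class = "coremk_count_error")
    } else {
      got <- count_mk(aln, labs_in, labs_out)
      expect_equal(got$p_n, want$p_n, tolerance = 1e-12)
      expect_equal(got$p_s, want$p_s, tolerance = 1e-12)
      expect_equal(got$d_n, want$d_n, tolerance = 1e-12)
      expect_equal(got$d_s, want$d_s, tolerance = 1e-12)
    }
  }
})

test_that("swapping ingroup and outgroup swaps which clade's polymorphism is counted", {
  # clade A polymorphic (AAA/AAA/AAG), clade B monomorphic GGG at codon 1;
  # codon 2 monomorphic on both sides and divergent
  aln <- make_aln(
    a1 = "AAAATG", a2 = "AAAATG", a3 = "AAGATG",
    b1 = "GGGACG", b2 = "GGGACG", b3 = "GGGACG"
  )
  a_in <- count_mk(aln, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  b_in <- count_mk(aln, c("b1", "b2", "b3"), c("a1", "a2", "a3"))
  # direction A: K/K polymorphism at codon 1; codon 1 not divergent (polymorphic)
  expect_equal(a_in$p_s, 1)
  expect_equal(a_in$p_n, 0)
  # direction B: no polymorphism; codon 1 now divergent GGG vs consensus AAA
  expect_equal(b_in$p_n + b_in$p_s, 0)
  expect_gt(b_in$d_n + b_in$d_s, a_in$d_n + a_in$d_s)
  # codon 2 (ATG vs ACG, M vs T) is a nonsyn fixed difference in both directions
  expect_gte(a_in$d_n, 1)
  expect_gte(b_in$d_n, 1)
})

test_that("NI and DoS match exact arithmetic and the undefined-case contract", {
  counts <- data.frame(p_n = 2, p_s = 42, d_n = 7, d_s = 17)
  expect_equal(neutrality_index(counts), (2 * 17) / (42 * 7), tolerance = 1e-15)
  expect_equal(direction_of_selection(counts), 7 / 24 - 2 / 44, tolerance = 1e-15)
  expect_equal(neutrality_index(data.frame(p_n = 1, p_s = 1, d_n = 1, d_s = 1)), 1)
  expect_equal(direction_of_selection(data.frame(p_n = 1, p_s = 1, d_n = 1, d_s = 1)), 0)
  expect_true(is.na(neutrality_index(data.frame(p_n = 3, p_s = 0, d_n = 2, d_s = 5))))
  expect_true(is.na(direction_of_selection(data.frame(p_n = 0, p_s = 0, d_n = 3, d_s = 5))))

  # random tables vs cross-product arithmetic
  set.seed(3)
  tabs <- data.frame(
    p_n = sample(0:40, 200, TRUE), p_s = sample(0:40, 200, TRUE),
    d_n = sample(0:40, 200, TRUE), d_s = sample(0:40, 200, TRUE)
  )
  ni <- neutrality_index(tabs)
  dos <- direction_of_selection(tabs)
  for (i in seq_len(nrow(tabs))) {
    r <- tabs[i, ]
    if (r$d_n == 0 || r$p_s == 0) {
      expect_true(is.na(ni[i]))
    } else {
      expect_equal(ni[i], (r$p_n * r$d_s) / (r$p_s * r$d_n), tolerance = 1e-12)
    }
    if ((r$p_n + r$p_s) == 0 || (r$d_n + r$d_s) == 0) {
      expect_true(is.na(dos[i]))
    } else {
      expect_equal(dos[i], r$d_n / (r$d_n + r$d_s) - r$p_n / (r$p_n + r$p_s),
        tolerance = 1e-12
      )
    }
  }
})

test_that("the significance test picks chi-squared or Fisher correctly", {
  # identical ratios, large counts: chi-squared with statistic 0
  res <- mk_significance(data.frame(p_n = 10, p_s = 10, d_n = 10, d_s = 10))
  expect_equal(res$test_used, "chisq")
  expect_equal(res$p_value, 1.0)

  # the worked table: small expected cells force Fisher; p below 0.05
  res2 <- mk_significance(data.frame(p_n = 2, p_s = 42, d_n = 7, d_s = 17))
  expect_equal(res2$test_used, "fisher")
  expect_lt(res2$p_value, 0.05)
  tab <- matrix(c(2, 42, 7, 17), 2, byrow = TRUE)
  expect_equal(res2$p_value, oracle_fisher_2x2(tab), tolerance = 1e-9)

  # large balanced-margin table: chi-squared, checked against direct formula
  res3 <- mk_significance(data.frame(p_n = 12, p_s = 30, d_n = 25, d_s = 21))
  expect_equal(res3$test_used, "chisq")
  tab3 <- matrix(c(12, 30, 25, 21), 2, byrow = TRUE)
  expect_equal(res3$p_value, oracle_chisq_2x2(tab3), tolerance = 1e-12)

  # all-zero table is undefined
  res4 <- mk_significance(data.frame(p_n = 0, p_s = 0, d_n = 0, d_s = 0))
  expect_true(is.na(res4$p_value))
  expect_true(is.na(res4$test_used))

  # fractional counts are rounded for the table
  res5 <- mk_significance(data.frame(p_n = 1.6, p_s = 2.4, d_n = 3.2, d_s = 0.4))
  tab5 <- matrix(c(2, 2, 3, 0), 2, byrow = TRUE)
  expect_equal(res5$p_value, oracle_fisher_2x2(tab5), tolerance = 1e-9)
})

test_that("NI_TG pools genes per the weighted formula with sane CIs", {
  # single gene: weights cancel, NI_TG == NI
  one <- data.frame(p_n = 2, p_s = 42, d_n = 7, d_s = 17)
  res <- ni_tg(one, n_boot = 0)
  expect_equal(res$ni_tg, neutrality_index(one), tolerance = 1e-12)

  # k copies of the same gene leave the value unchanged
  for (k in c(2, 7)) {
    rep_tab <- one[rep(1, k), ]
    expect_equal(ni_tg(rep_tab, n_boot = 0)$ni_tg, res$ni_tg, tolerance = 1e-12)
  }

  # random 20-gene sets vs the term-by-term oracle
  set.seed(8)
  for (r in 1:20) {
    tabs <- data.frame(
      p_n = sample(0:30, 20, TRUE), p_s = sample(1:30, 20, TRUE),
      d_n = sample(1:30, 20, TRUE), d_s = sample(0:30, 20, TRUE)
    )
    expect_equal(
      ni_tg(tabs, n_boot = 0)$ni_tg,
      oracle_ni_tg(tabs$p_n, tabs$p_s, tabs$d_n, tabs$d_s),
      tolerance = 1e-12
    )
  }

  # genes with p_s + d_s == 0 are skipped, not fatal
  tabs2 <- data.frame(
    p_n = c(2, 5), p_s = c(42, 0), d_n = c(7, 3), d_s = c(17, 0)
  )
  res2 <- ni_tg(tabs2, n_boot = 0)
  expect_equal(res2$n_genes_included, 1L)
  expect_equal(res2$ni_tg, res$ni_tg, tolerance = 1e-12)

  # all-zero denominator aborts
  expect_error(
    ni_tg(data.frame(p_n = 1, p_s = 0, d_n = 0, d_s = 3), n_boot = 0),
    class = "coremk_aggregate_error"
  )

  # bootstrap CI brackets the point estimate and is seed-reproducible
  set.seed(77)
  tabs3 <- data.frame(
    p_n = sample(0:20, 40, TRUE), p_s = sample(1:20, 40, TRUE),
    d_n = sample(1:20, 40, TRUE), d_s = sample(0:20, 40, TRUE)
  )
  r1 <- ni_tg(tabs3, n_boot = 2000, seed = 5)
  r2 <- ni_tg(tabs3, n_boot = 2000, seed = 5)
  expect_lte(r1$ci_low, r1$ni_tg)
  expect_gte(r1$ci_high, r1$ni_tg)
  expect_equal(r1$ci_low, r2$ci_low)
  expect_equal(r1$ci_high, r2$ci_high)
})

test_that("tidy and glance expose the per-gene table and pooled summary", {
  counts <- data.frame(
    gene_id = c("g1", "g2"),
    p_n = c(2, 1), p_s = c(42, 10), d_n = c(7, 2), d_s = c(17, 4)
  )
  res <- ni_tg(counts, n_boot = 100, seed = 1, direction_label = "demo")
  td <- tidy(res)
  gl <- glance(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2L)
  expect_equal(gl$direction_label, "demo")
  expect_equal(gl$n_genes_included, 2L)
  expect_s3_class(autoplot(ni_tg(add_mk_statistics(counts), n_boot = 50, seed = 2)), "ggplot")
})
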