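test_that("the simulator is seed-deterministic down to the FASTA bytes", {
  cfg <- simulation_config(n_genes = 5, gene_length_codons = 60, seed = 12)
  s1 <- simulate_core_genome(cfg)
  s2 <- simulate_core_genome(cfg)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile()
  f2 <- tempfile()
  write_gene_alignment(s1$genes[[1]], f1)
  write_gene_alignment(s2$genes[[1]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  # and a different seed changes the output
  s3 <- simulate_core_genome(simulation_config(
    n_genes = 5,
    gene_length_codons = 60, seed = 13
  ))
  expect_false(identical(
    alignment_strings(s1$genes[[1]]),
    alignment_strings(s3$genes[[1]])
  ))
})

test_that("zero divergence yields no fixed differences and undefined NI everywhere", {
  # single outgroup strain: with no divergence the outgroup IS the ancestor
  # (a multi-strain outgroup could still show consensus-frequency variants)
  cfg <- simulation_config(
    n_genes = 10, gene_length_codons = 100,
    divergence_subs_per_site = 0, polymorphism_theta = 0.01,
    n_outgroup = 1, seed = 3
  )
  sim <- simulate_core_genome(cfg)
  expect_true(all(sim$truth$d_n_true + sim$truth$d_s_true == 0))
  counts <- dplyr::bind_rows(lapply(sim$genes, function(g) {
    count_mk(g, sim$ingroup, sim$outgroup)
  }))
  expect_true(all(counts$d_n + counts$d_s == 0))
  expect_true(all(is.na(neutrality_index(counts))))
})

test_that("the generator never emits internal stop codons", {
  cfg <- simulation_config(
    n_genes = 8, gene_length_codons = 80,
    divergence_subs_per_site = 0.2, polymorphism_theta = 0.03,
    omega_divergence = 1, omega_polymorphism = 1, seed = 23
  )
  sim <- simulate_core_genome(cfg)
  stops <- stop_codons(genetic_code(11))
  for (g in sim$genes) {
    cod <- matrix(
      substring(
        alignment_strings(g),
        rep(seq(1, n_sites(g), 3), each = nrow(g)),
        rep(seq(3, n_sites(g), 3), each = nrow(g))
      ),
      nrow = nrow(g)
    )
    expect_false(any(cod %in% stops))
  }
})

test_that("accepted mutation counts scale linearly with the configured rates", {
  rates <- c(0.02, 0.04, 0.08)
  mean_d <- vapply(rates, function(r) {
    sim <- simulate_core_genome(simulation_config(
      n_genes = 40, gene_length_codons = 150,
      divergence_subs_per_site = r, polymorphism_theta = 0.005,
      seed = 1000 + round(1e4 * r)
    ))
    mean(sim$truth$d_n_true + sim$truth$d_s_true)
  }, numeric(1))
  len <- 450
  fit <- stats::lm(mean_d ~ rates)
  slope <- unname(stats::coef(fit)[2])
  expect_lt(abs(slope / len - 1), 0.1)
})

test_that("equal purifying constraint exposes the documented pathway-counting bias", {
  # Equal-weight averaging over shortest stop-free pathways (the standard
  # codon-counting convention) overestimates the non-synonymous share of
  # multi-step fixed differences when non-synonymous steps are suppressed:
  # the realized histories are synonymous-biased, but every pathway gets the
  # same weight. With omega = 0.2 on both timescales and 0.05 subs/site this
  # shows up as a small positive mean DoS; it vanishes at omega = 1 (see the
  # neutral recovery test). This characterizes the limitation so it cannot
  # regress silently.
  doses <- vapply(1:3, function(r) {
    sim <- simulate_core_genome(simulation_config(
      n_genes = 100, gene_length_codons = 300,
      omega_divergence = 0.2, omega_polymorphism = 0.2,
      seed = 1300 + r
    ))
    counts <- dplyr::bind_rows(lapply(sim$genes, function(g) {
      count_mk(g, sim$ingroup, sim$outgroup)
    }))
    mean(direction_of_selection(counts), na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(doses), 0)
  expect_lt(mean(doses), 0.06)
})

test_that("configuration is validated", {
  expect_error(simulation_config(n_genes = 0), class = "coremk_config_error")
  expect_error(simulation_config(gene_length_codons = 1), class = "coremk_config_error")
  expect_error(simulation_config(omega_divergence = 1.5), class = "coremk_config_error")
  expect_error(simulation_config(recombinant_fraction = -0.1), class = "coremk_config_error")
  expect_error(simulate_core_genome(list()), class = "coremk_config_error")
})

test_that("truth-versus-estimate recovery is tight in an easy regime", {
  cfg <- simulation_config(
    n_genes = 40, gene_length_codons = 200,
    divergence_subs_per_site = 0.02, polymorphism_theta = 0.004,
    n_ingroup = 5, n_outgroup = 2, seed = 31
  )
  sim <- simulate_core_genome(cfg)
  counts <- dplyr::bind_rows(lapply(sim$genes, function(g) {
    count_mk(g, sim$ingroup, sim$outgroup)
  }))
  rec <- truth_vs_estimate(sim$truth, counts)
  expect_gt(rec$cor_d, 0.9)
  expect_lt(rec$rel_err_d, 0.1)
})

test_that("inter-taxon recombinants are flagged by the congruency filter", {
  cfg <- simulation_config(
    n_genes = 30, gene_length_codons = 200,
    divergence_subs_per_site = 0.12, polymorphism_theta = 0.005,
    recombinant_fraction = 0.2, seed = 47
  )
  sim <- simulate_core_genome(cfg)
  ref <- taxon_split(sim$ingroup, sim$outgroup)
  congr <- vapply(sim$genes, function(g) {
    tryCatch(
      is_congruent(upgma(jc69_distance(g)), ref),
      coremk_error = function(e) NA
    )
  }, logical(1))
  flags <- tibble::tibble(gene_id = names(congr), congruent = unname(congr))
  rec <- truth_vs_estimate(sim$truth, dplyr::inner_join(
    dplyr::bind_rows(lapply(sim$genes, function(g) {
      count_mk(g, sim$ingroup, sim$outgroup)
    })),
    flags,
    by = "gene_id"
  ))
  expect_gt(rec$tp / (rec$tp + rec$fn), 0.5)
  # non-recombinant genes mostly stay congruent
  expect_lt(rec$fp / max(rec$fp + rec$tn, 1), 0.2)
})
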