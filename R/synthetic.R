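# Forward simulator of core-genome ortholog sets with known divergence,
# polymorphism, selection regimes and recombination, so every pipeline stage
# can be validated against recorded ground truth without external data.

#' Simulation configuration
#'
#' Parameters of the core-genome simulator. Selection is modelled as
#' acceptance/rejection of proposed non-synonymous changes: synonymous
#' proposals are always accepted, non-synonymous ones with probability
#' `omega_divergence` (on the outgroup lineage) or `omega_polymorphism`
#' (segregating within a clade). Equal omegas give an MK-neutral regime;
#' `omega_divergence > omega_polymorphism` mimics adaptive divergence.
#'
#' @param n_genes Number of ortholog genes.
#' @param gene_length_codons Gene length in codons.
#' @param n_ingroup,n_outgroup Strains per clade (`n_ingroup >= 2`,
#'   `n_outgroup >= 1`).
#' @param divergence_subs_per_site Accepted substitutions per nucleotide
#'   site on the outgroup lineage.
#' @param polymorphism_theta Per-site Watterson theta of the segregating
#'   variation injected into each clade.
#' @param omega_divergence,omega_polymorphism Acceptance probabilities for
#'   non-synonymous proposals, in `[0, 1]`.
#' @param recombinant_fraction Fraction of genes carrying a recombinant
#'   block: under the star genealogy one ingroup strain receives a
#'   contiguous 3' block from the outgroup lineage; under the clustered
#'   genealogy one strain of each ingroup subclade swaps tails.
#' @param transition_bias Relative rate of transitions over each
#'   transversion in the proposal kernel (default 2).
#' @param genealogy `"star"` (default; independent strains, analytic truth)
#'   or `"clustered"` (the ingroup additionally carries a two-level
#'   structure, for stressing tree stages).
#' @param seed Integer seed fixing the full output.
#' @param code_table Genetic code table id (default 11).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200, gene_length_codons = 300,
                              n_ingroup = 6, n_outgroup = 3,
                              divergence_subs_per_site = 0.05,
                              polymorphism_theta = 0.01,
                              omega_divergence = 0.2,
                              omega_polymorphism = 0.2,
                              recombinant_fraction = 0,
                              transition_bias = 2,
                              genealogy = c("star", "clustered"),
                              seed = 1, code_table = 11) {
  genealogy <- match.arg(genealogy)
  bad <- function(msg) coremk_abort(msg, "config_error")
  if (n_genes < 1) bad("n_genes must be >= 1")
  if (gene_length_codons < 2) bad("gene_length_codons must be >= 2")
  if (n_ingroup < 2) bad("n_ingroup must be >= 2")
  if (n_outgroup < 1) bad("n_outgroup must be >= 1")
  if (divergence_subs_per_site < 0) bad("divergence_subs_per_site must be >= 0")
  if (polymorphism_theta < 0) bad("polymorphism_theta must be >= 0")
  if (omega_divergence < 0 || omega_divergence > 1) bad("omega_divergence must be in [0, 1]")
  if (omega_polymorphism < 0 || omega_polymorphism > 1) bad("omega_polymorphism must be in [0, 1]")
  if (recombinant_fraction < 0 || recombinant_fraction > 1) bad("recombinant_fraction must be in [0, 1]")
  if (transition_bias <= 0) bad("transition_bias must be > 0")
  structure(
    list(
      n_genes = as.integer(n_genes),
      gene_length_codons = as.integer(gene_length_codons),
      n_ingroup = as.integer(n_ingroup),
      n_outgroup = as.integer(n_outgroup),
      divergence_subs_per_site = divergence_subs_per_site,
      polymorphism_theta = polymorphism_theta,
      omega_divergence = omega_divergence,
      omega_polymorphism = omega_polymorphism,
      recombinant_fraction = recombinant_fraction,
      transition_bias = transition_bias,
      genealogy = genealogy,
      seed = as.integer(seed),
      code_table = code_table
    ),
    class = "simulation_config"
  )
}

# The simulator works on integer-coded bases (A=1, C=2, G=3, T=4) with
# codon identity aa_int[((a-1)*4 + (b-1))*4 + c], where aa_int encodes the
# amino acid as an integer and 0 marks a stop codon. This keeps the
# per-proposal cost to a handful of integer operations.

SIM_BASES <- c("A", "C", "G", "T")
SIM_TRANSITION <- c(3L, 4L, 1L, 2L) # A<->G, C<->T
SIM_TRANSVERSIONS <- matrix(
  c(
    2L, 4L, # A -> C, T
    1L, 3L, # C -> A, G
    2L, 4L, # G -> C, T
    1L, 3L # T -> A, G
  ),
  nrow = 4L, byrow = TRUE
)

# Integer amino-acid code per codon id (0 = stop), from a genetic_code map.
sim_aa_table <- function(code) {
  ids <- expand.grid(c3 = 1:4, c2 = 1:4, c1 = 1:4) # varies c3 fastest
  codons <- paste0(
    SIM_BASES[ids$c1], SIM_BASES[ids$c2], SIM_BASES[ids$c3]
  )
  aa <- code$map[codons]
  out <- match(aa, c(unique(aa[aa != "*"])))
  out[aa == "*"] <- 0L
  out
}

codon_id <- function(a, b, cc) ((a - 1L) * 4L + (b - 1L)) * 4L + cc

propose_base_int <- function(old, p_ts) {
  u <- runif(1L)
  if (u < p_ts) {
    SIM_TRANSITION[old]
  } else if (u < p_ts + (1 - p_ts) / 2) {
    SIM_TRANSVERSIONS[old, 1L]
  } else {
    SIM_TRANSVERSIONS[old, 2L]
  }
}

# Apply `n_target` accepted substitutions to an integer-coded sequence.
# Returns the evolved vector plus the accepted syn/nonsyn counts.
evolve_lineage <- function(s, n_target, omega, bias, aa_tab) {
  n_syn <- 0L
  n_nonsyn <- 0L
  p_ts <- bias / (bias + 2)
  if (n_target > 0L) {
    len <- length(s)
    accepted <- 0L
    guard <- 0L
    guard_max <- 1000L * (n_target + 10L)
    while (accepted < n_target && guard < guard_max) {
      guard <- guard + 1L
      p <- sample.int(len, 1L)
      new <- propose_base_int(s[p], p_ts)
      ci0 <- ((p - 1L) %/% 3L) * 3L
      off <- p - ci0
      cod <- s[ci0 + 1:3]
      aa_old <- aa_tab[codon_id(cod[1L], cod[2L], cod[3L])]
      cod[off] <- new
      aa_new <- aa_tab[codon_id(cod[1L], cod[2L], cod[3L])]
      if (aa_new == 0L) next # stop codon
      syn <- aa_old == aa_new
      if (syn || runif(1L) < omega) {
        s[p] <- new
        accepted <- accepted + 1L
        if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      }
    }
  }
  list(chars = s, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

# Inject `n_target` accepted segregating mutations into an integer-coded
# clade matrix (rows = strains). Derived-allele counts follow the neutral
# 1/k law on a star genealogy; positions are distinct. Acceptance is judged
# on the ancestral codon context.
inject_polymorphism <- function(strains, anc, n_target, omega, bias, aa_tab) {
  n <- nrow(strains)
  len <- length(anc)
  n_syn <- 0L
  n_nonsyn <- 0L
  p_ts <- bias / (bias + 2)
  if (n_target > 0L && n >= 2L) {
    order_pos <- sample.int(len)
    next_pos <- 1L
    accepted <- 0L
    k_prob <- (1 / seq_len(n - 1L))
    while (accepted < n_target && next_pos <= len) {
      p <- order_pos[next_pos]
      next_pos <- next_pos + 1L
      new <- propose_base_int(anc[p], p_ts)
      ci0 <- ((p - 1L) %/% 3L) * 3L
      off <- p - ci0
      cod <- anc[ci0 + 1:3]
      aa_old <- aa_tab[codon_id(cod[1L], cod[2L], cod[3L])]
      cod[off] <- new
      aa_new <- aa_tab[codon_id(cod[1L], cod[2L], cod[3L])]
      if (aa_new == 0L) next
      syn <- aa_old == aa_new
      if (!syn && runif(1L) >= omega) next
      k <- sample.int(n - 1L, 1L, prob = k_prob)
      carriers <- sample.int(n, k)
      # carriers may already differ from the ancestor in this codon (earlier
      # mutation, cluster history): never let the combination form a stop
      cc <- strains[carriers, ci0 + 1:3, drop = FALSE]
      cc[, off] <- new
      if (any(aa_tab[codon_id(cc[, 1L], cc[, 2L], cc[, 3L])] == 0L)) next
      strains[carriers, p] <- new
      accepted <- accepted + 1L
      if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(strains = strains, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

#' Simulate a core genome of ortholog alignments with known truth
#'
#' Generates `n_genes` gap-free codon alignments over an ingroup clade (`A*`
#' labels) and an outgroup clade (`B*` labels). Per gene: a random ancestral
#' CDS without internal stops is evolved along the outgroup lineage
#' (Poisson-distributed accepted substitutions at
#' `divergence_subs_per_site`), then each clade receives theta-scaled
#' segregating mutations at distinct sites. In recombinant genes one random
#' ingroup strain has a contiguous 3'-block (breakpoint in the middle third)
#' replaced by the outgroup lineage sequence. The same seed reproduces the
#' output byte for byte.
#'
#' @param config A [simulation_config()].
#' @return A list with
#'   \describe{
#'     \item{genes}{named list of [gene_alignment()] objects}
#'     \item{truth}{tibble of per-gene true counts: `d_n_true`, `d_s_true`,
#'       `p_n_true`, `p_s_true` (ingroup), `p_n_out_true`, `p_s_out_true`,
#'       `recombinant`, `recombinant_strain`, `breakpoint_codon`}
#'     \item{ingroup, outgroup}{genome label vectors}
#'     \item{split}{the generating [taxon_split()]}
#'     \item{config}{the configuration used}
#'   }
#' @export
simulate_core_genome <- function(config) {
  if (!inherits(config, "simulation_config")) {
    coremk_abort("config must come from simulation_config()", "config_error")
  }
  code <- genetic_code(config$code_table)
  aa_tab <- sim_aa_table(code)
  sense_ids <- which(aa_tab != 0L)
  decode_id <- function(ids) {
    rbind(
      (ids - 1L) %/% 16L + 1L,
      ((ids - 1L) %/% 4L) %% 4L + 1L,
      (ids - 1L) %% 4L + 1L
    )
  }
  lc <- config$gene_length_codons
  len <- 3L * lc
  n_in <- config$n_ingroup
  n_out <- config$n_outgroup
  in_labs <- sprintf("A%02d", seq_len(n_in))
  out_labs <- sprintf("B%02d", seq_len(n_out))
  a_in <- sum(1 / seq_len(max(n_in - 1L, 1L)))
  a_out <- if (n_out >= 2L) sum(1 / seq_len(n_out - 1L)) else 0

  with_seed(config$seed, {
    n_rec <- round(config$recombinant_fraction * config$n_genes)
    rec_genes <- if (n_rec > 0L) sample.int(config$n_genes, n_rec) else integer(0)

    genes <- vector("list", config$n_genes)
    truth <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      anc <- as.vector(decode_id(sample(sense_ids, lc, replace = TRUE)))
      div <- evolve_lineage(
        anc, rpois(1L, config$divergence_subs_per_site * len),
        config$omega_divergence, config$transition_bias, aa_tab
      )
      out_anc <- div$chars

      in_strains <- matrix(anc, n_in, len, byrow = TRUE)
      cluster_anc <- NULL
      cl_syn <- 0L
      cl_nonsyn <- 0L
      if (config$genealogy == "clustered" && n_in >= 4L) {
        # two ingroup subclades, each with its own shared substitution
        # history (markers segregate at subclade frequency)
        half1 <- seq_len(n_in %/% 2L)
        half2 <- setdiff(seq_len(n_in), half1)
        cl_rate <- 0.25 * config$divergence_subs_per_site * len
        sh1 <- evolve_lineage(
          anc, rpois(1L, cl_rate),
          config$omega_polymorphism, config$transition_bias, aa_tab
        )
        sh2 <- evolve_lineage(
          anc, rpois(1L, cl_rate),
          config$omega_polymorphism, config$transition_bias, aa_tab
        )
        in_strains[half1, ] <- matrix(sh1$chars, length(half1), len, byrow = TRUE)
        in_strains[half2, ] <- matrix(sh2$chars, length(half2), len, byrow = TRUE)
        cluster_anc <- sh1$chars # donor haplotype for recombinants
        cl_syn <- sh1$n_syn + sh2$n_syn
        cl_nonsyn <- sh1$n_nonsyn + sh2$n_nonsyn
      }
      poly_in <- inject_polymorphism(
        in_strains, anc,
        rpois(1L, config$polymorphism_theta * a_in * len),
        config$omega_polymorphism, config$transition_bias, aa_tab
      )
      in_strains <- poly_in$strains

      out_strains <- matrix(out_anc, n_out, len, byrow = TRUE)
      p_out <- list(n_syn = 0L, n_nonsyn = 0L)
      if (n_out >= 2L) {
        poly_out <- inject_polymorphism(
          out_strains, out_anc,
          rpois(1L, config$polymorphism_theta * a_out * len),
          config$omega_polymorphism, config$transition_bias, aa_tab
        )
        out_strains <- poly_out$strains
        p_out <- poly_out
      }

      # Recombinants exchange a contiguous 3' block (50-75% of the gene)
      # between lineage histories. Under the star genealogy one ingroup
      # strain receives the block from the outgroup lineage (an inter-taxon
      # recombinant, the target of the tree congruency filter); under the
      # clustered genealogy one strain of each ingroup subclade swaps tails,
      # so the two gene halves support conflicting ingroup topologies — the
      # mosaic pattern the PHI test detects.
      rec_strain <- NA_character_
      bp <- NA_integer_
      if (g %in% rec_genes) {
        pick1 <- function(v) v[sample.int(length(v), 1L)]
        bp <- pick1(seq(max(2L, floor(lc / 4)), max(2L, floor(lc / 2))))
        jj <- ((bp - 1L) * 3L + 1L):len
        if (!is.null(cluster_anc)) {
          s1 <- pick1(seq_len(n_in %/% 2L))
          s2 <- pick1((n_in %/% 2L + 1L):n_in)
          tail1 <- in_strains[s1, jj]
          in_strains[s1, jj] <- in_strains[s2, jj]
          in_strains[s2, jj] <- tail1
          rec_strain <- paste(in_labs[c(s1, s2)], collapse = ",")
        } else {
          s <- sample.int(n_in, 1L)
          in_strains[s, jj] <- out_anc[jj]
          rec_strain <- in_labs[s]
        }
      }

      to_string <- function(row) paste(SIM_BASES[row], collapse = "")
      seqs <- c(
        setNames(apply(in_strains, 1L, to_string), in_labs),
        setNames(apply(out_strains, 1L, to_string), out_labs)
      )
      id <- sprintf("gene%04d", g)
      genes[[g]] <- gene_alignment(seqs, gene_id = id, code = code)
      truth[[g]] <- tibble(
        gene_id = id,
        d_n_true = div$n_nonsyn, d_s_true = div$n_syn,
        p_n_true = poly_in$n_nonsyn + cl_nonsyn,
        p_s_true = poly_in$n_syn + cl_syn,
        p_n_out_true = p_out$n_nonsyn, p_s_out_true = p_out$n_syn,
        recombinant = g %in% rec_genes,
        recombinant_strain = rec_strain,
        breakpoint_codon = bp
      )
    }
    names(genes) <- vapply(genes, gene_id, character(1L))
    list(
      genes = genes,
      truth = bind_rows(truth),
      ingroup = in_labs,
      outgroup = out_labs,
      split = taxon_split(in_labs, out_labs),
      config = config
    )
  })
}

#' Compare simulator truth with pipeline estimates
#'
#' Joins the simulator's per-gene truth record with a per-gene result table
#' and summarizes how well counts and recombinant flags were recovered.
#'
#' @param truth Truth tibble from [simulate_core_genome()].
#' @param per_gene Per-gene table containing `gene_id`, `p_n`, `p_s`, `d_n`,
#'   `d_s` and optionally `congruent` and/or `phi_p`.
#' @param alpha Significance level used to call a PHI flag (default 0.05).
#' @return One-row tibble: correlations `cor_d`, `cor_p`, mean relative
#'   errors `rel_err_d`, `rel_err_p`, and the recombinant-detection
#'   confusion counts `tp`, `fp`, `fn`, `tn` (NA when no flags present).
#' @export
truth_vs_estimate <- function(truth, per_gene, alpha = 0.05) {
  joined <- dplyr::inner_join(truth, per_gene, by = "gene_id")
  if (nrow(joined) == 0L) {
    coremk_abort("truth and per_gene share no gene_ids", "input_error")
  }
  d_true <- joined$d_n_true + joined$d_s_true
  d_est <- joined$d_n + joined$d_s
  p_true <- joined$p_n_true + joined$p_s_true
  p_est <- joined$p_n + joined$p_s
  flagged <- rep(NA, nrow(joined))
  if ("congruent" %in% names(joined) || "phi_p" %in% names(joined)) {
    congr <- if ("congruent" %in% names(joined)) joined$congruent else TRUE
    phi_p <- if ("phi_p" %in% names(joined)) joined$phi_p else NA_real_
    flagged <- (!is.na(congr) & !congr) | (!is.na(phi_p) & phi_p <= alpha)
  }
  tibble(
    n_genes = nrow(joined),
    cor_d = suppressWarnings(cor(d_true, d_est)),
    cor_p = suppressWarnings(cor(p_true, p_est)),
    rel_err_d = mean(abs(d_est - d_true) / pmax(d_true, 1)),
    rel_err_p = mean(abs(p_est - p_true) / pmax(p_true, 1)),
    tp = sum(flagged & joined$recombinant, na.rm = TRUE),
    fp = sum(flagged & !joined$recombinant, na.rm = TRUE),
    fn = sum(!flagged & joined$recombinant, na.rm = TRUE),
    tn = sum(!flagged & !joined$recombinant, na.rm = TRUE)
  )
}
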