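# coremk

Genome-wide McDonald-Kreitman (MK) tests of adaptive divergence for
prokaryote core genomes.

## The problem

Closely related bacterial strains share a core genome of single-copy
orthologs (SICOs). Comparing, for each ortholog, the synonymous and
non-synonymous changes that *segregate within* a set of strains against
those *fixed between* the strains and an outgroup quantifies how much of the
divergence was driven by selection. Doing this across every core gene —
rather than for one or two loci — is the point of this package: it takes a
directory of per-gene codon alignments and returns per-gene and
genome-wide selection statistics, for microbial population genomicists who
have ortholog alignments and want a reproducible, scriptable MK analysis.

## The statistics

For each gene, polymorphisms (`P_N`, `P_S`) and fixed differences
(`D_N`, `D_S`) are counted codon by codon, resolving multi-step codon
differences by averaging over all shortest stop-free mutational pathways.
From the 2×2 table:

* **Neutrality Index** — `NI = (P_N/P_S) / (D_N/D_S)`; 1 under neutrality,
  < 1 with excess non-synonymous divergence (positive selection); undefined
  when `D_N = 0` or `P_S = 0`.
* **Direction of Selection** — `DoS = D_N/(D_N+D_S) − P_N/(P_N+P_S)`;
  0 under neutrality, positive under adaptive divergence; defined for far
  more genes than NI.
* **Weighted Neutrality Index** (Tarone-Greenland / Mantel-Haenszel style)
  for the whole core genome:

  `NI_TG = Σᵢ[D_Sᵢ·P_Nᵢ/(P_Sᵢ+D_Sᵢ)] / Σᵢ[P_Sᵢ·D_Nᵢ/(P_Sᵢ+D_Sᵢ)]`

  with a seeded bootstrap-over-genes 95% CI.

Per-gene significance is a chi-squared test on the 2×2 table (Fisher's exact
test when expected cells are small), with BH q-values across genes.

Around the statistics sits the full workflow: alignment trimming and QC,
per-genome concatenation, a UPGMA tree with automatic outgroup designation
from its first split (the MK test runs in both directions when both clades
have ≥ 2 strains), a per-gene tree congruency filter against inter-taxon
recombinants, the PHI permutation test for intragenic recombination,
site-frequency spectra and nucleotide diversity (π, θ_W), and a seeded
forward simulator that generates core genomes with known selection regimes
for validation. See the methods vignette
(`vignettes/core-genome-mk.Rmd`) for the model details and design choices.

## A worked example

```r
library(coremk)
library(dplyr)

sim <- simulate_core_genome(simulation_config(
  n_genes = 40, gene_length_codons = 200, seed = 42
))
counts <- bind_rows(lapply(sim$genes, function(g) {
  count_mk(g, sim$ingroup, sim$outgroup)
}))
res <- ni_tg(add_mk_statistics(counts), n_boot = 2000, seed = 1)
res
#> <core-genome MK result>
#>   NI_TG = 1.0557, 95% CI [0.8665, 1.2911]
#>   40 of 40 genes weighted, 2000 bootstrap resamples

head(tidy(res)[, c("gene_id", "p_n", "p_s", "d_n", "d_s", "ni", "dos", "p_value")], 4)
#> # A tibble: 4 × 8
#>   gene_id    p_n   p_s   d_n   d_s    ni      dos p_value
#>   <chr>    <dbl> <dbl> <dbl> <dbl> <dbl>    <dbl>   <dbl>
#> 1 gene0001     5     8   9    15   1.04  -0.00962   1
#> 2 gene0002     6    13   8    19   1.10  -0.0195    0.887
#> 3 gene0003     6     7  10    23   1.97  -0.159     0.328
#> 4 gene0004     6    17   7.5  16.5 0.776  0.0516    0.587
```

The simulation is MK-neutral (equal non-synonymous acceptance for
polymorphism and divergence), and the pooled result behaves accordingly:
`NI_TG ≈ 1` with a CI that covers 1, and per-gene DoS values scattered
around 0. Fractional counts (e.g. `d_n = 7.5`) arise from pathway averaging
over multi-step codon differences.

The complete pipeline over a directory of FASTA alignments — QC, tree,
filters, both test directions, all output tables — is one call:

```r
run <- run_core_mk_pipeline("alignments/", "results/", seed = 1)
glance(run$results$ingroup_clade_a)
autoplot(run$results$ingroup_clade_a)
```

or, from a shell, via the thin CLI in `exec/`:

```sh
Rscript exec/coremk simulate --out genes/ --n-genes 200 --seed 1
Rscript exec/coremk run --in genes/ --out results/ --seed 1
```

Per direction, `results/` contains `summary_<direction>.tsv` (one row per
gene: counts, NI, DoS, test used, p/q-values, S, π, θ_W, SFS, filter
flags), `aggregate_<direction>.tsv` (NI_TG with CI), `sfs_<direction>.tsv`,
plus the concatemer FASTA, the UPGMA tree in Newick, the QC report and a
stage-prefixed log.

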