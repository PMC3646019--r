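---
title: "Core-genome McDonald-Kreitman analysis with coremk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-genome McDonald-Kreitman analysis with coremk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremk)
library(dplyr)
```

## The model

The McDonald-Kreitman (MK) test contrasts two ratios of coding-sequence
change. Within a population, mutations segregate as polymorphisms; between a
population and an outgroup, mutations have fixed as divergence. Under
neutrality the non-synonymous fraction of both classes is governed by the
same constraint, so

$$\frac{P_N}{P_S} \approx \frac{D_N}{D_S}.$$

Departures indicate selection: an excess of non-synonymous divergence
(positive selection) or an excess of non-synonymous polymorphism (segregating
slightly deleterious variants). `coremk` applies this logic gene by gene over
the single-copy orthologs (SICOs) shared by a group of prokaryote genomes —
the core genome — and then pools the genes.

Three summary statistics are computed:

* the **Neutrality Index**, $NI = (P_N/P_S)/(D_N/D_S)$, undefined whenever
  $D_N = 0$ or $P_S = 0$ (a ratio of ratios; when $D_S = 0$ with $D_N > 0$
  and $P_S > 0$ the cross-product form $P_N D_S / P_S D_N$ yields 0);
* the **Direction of Selection**,
  $DoS = \frac{D_N}{D_N + D_S} - \frac{P_N}{P_N + P_S}$, defined for every
  gene with at least one polymorphism and one fixed difference, zero under
  neutrality and positive under adaptive divergence;
* the pooled **weighted Neutrality Index**
  $$NI_{TG} = \frac{\sum_i D_{S,i}\,P_{N,i}/(P_{S,i}+D_{S,i})}
                   {\sum_i P_{S,i}\,D_{N,i}/(P_{S,i}+D_{S,i})},$$
  a Mantel-Haenszel-style combination of the per-gene 2×2 tables that is
  robust to across-gene heterogeneity and usable even when most individual
  genes have undefined NI.

Per-gene significance uses the 2×2 table $[[P_N, P_S], [D_N, D_S]]$ with a
chi-squared test without continuity correction, replaced by Fisher's exact
test whenever an expected cell falls below 5 (counts are rounded to integers
for the table only). Benjamini-Hochberg q-values are reported across genes
alongside the raw p-values, which remain primary.

### Counting $P$ and $D$

Counting walks codon columns of each in-frame alignment:

* a codon column is **used** only when every counted sequence carries a
  gap-free, unambiguous, non-stop codon (codons containing `N` or other
  IUPAC codes are masked); internal stop codons are an input error by
  default and can be masked instead;
* a column **segregating within the ingroup** contributes only to
  polymorphism — never to divergence, whatever the outgroup carries.
  Changes are counted from the most frequent ingroup codon (ties broken
  lexicographically) to each other observed codon;
* at **ingroup-monomorphic** columns, differences from the outgroup
  representative count as divergence. A multi-strain outgroup is
  represented by its strict-majority consensus codon; columns without a
  majority are skipped;
* **multi-nucleotide codon differences** are averaged over all shortest
  mutational pathways that avoid stop codons, so counts can be fractional
  (they are kept fractional for NI/DoS/$NI_{TG}$ and rounded only for the
  contingency test). In the rare case where every ordering passes through a
  stop, the average is over all orderings.

This direct pathway-counting approach replaces likelihood-based codon models:
the package's contract is the aggregate MK statistics, not reproduction of
any particular codon-model estimator's per-gene values.

The 95% confidence interval for $NI_{TG}$ is a seeded nonparametric
bootstrap over genes (percentile method, 10,000 resamples by default).
An analytic variance-based interval is deliberately not offered: the
variance estimator would have to be transcribed from its original source,
and guessing it would be worse than omitting it.

## Pipeline stages and their parameters

`run_core_mk_pipeline()` chains the stages; each is also exported on its own.

**Trimming and QC** (`trim_alignment()`, `evaluate_qc()`): leading/trailing
codon columns containing any gap are removed; genes then pass QC when the
overlap fraction (share of codon columns with no gap in any sequence) is at
least `min_overlap` (default 0.85) and the longest run of gap-containing
codon columns is at most `max_indel` (default 15 codons). Gap runs are
measured in codon columns to preserve frame semantics. The two defaults are
package choices — the QC parameters are user-defined by design — and both
are fully configurable.

**Outgroup designation** (`jc69_distance()`, `upgma()`, `first_split()`):
orthologs are concatenated per genome (in sorted gene-id order, so the
concatemer is independent of input order) and a UPGMA tree is built from
JC69 distances. JC69 was chosen over richer substitution models for its
closed form, which makes the distance stage exactly testable; gapped or
ambiguous positions are deleted pairwise so short genes stay usable, and a
mismatch proportion at or beyond 0.75 (outside the JC69 domain) is an error.
UPGMA ties are broken deterministically by merging the pair whose sorted
cluster keys are lexicographically smallest. The bipartition at the root —
the first split — defines the two candidate taxa; the MK test runs once in
each direction with at least two ingroup strains, mirroring the
dual-direction output appropriate for multi-strain outgroups. No convention
designates one side "the" outgroup when both are multi-strain, so both
tables are produced and labelled.

**Congruency filter** (`is_congruent()`): a per-gene UPGMA tree whose first
split disagrees with the concatemer split marks the gene as a candidate
inter-taxon recombinant. Only the root bipartition is compared — stricter
whole-topology matching would reject genes for shallow rearrangements that
do not affect the ingroup/outgroup contrast. Incongruent genes are excluded
from $NI_{TG}$ by default (the filter exists precisely because such genes
violate the MK test's outgroup assumption); exclusion is configurable.

**PHI recombination test** (`phi_test()`): for parsimony-informative site
pairs, the refined incompatibility score is the cycle rank of the
partition-intersection graph (0 iff the pair fits on one tree). The statistic
is the mean score over pairs at most `window` (default 100 nt) apart;
recombination leaves nearby pairs compatible while distant pairs conflict,
so a low observed value relative to site-order permutations signals
recombination, with $p = (1 + \#\{\text{perm} \le \text{obs}\})/(n+1)$
(default 1,000 seeded permutations). Genes with fewer than two informative
sites have an undefined statistic and pass the filter (logged). PHI-flagged
genes are flagged only by default — exclusion from the pooled statistic is
opt-in (`exclude_recombinants`), since the congruency filter already covers
the variant of recombination that breaks the MK contrast.

**Diversity** (`diversity_stats()`, `site_frequency_spectrum()`): per
ingroup and gene, segregating sites $S$, nucleotide diversity $\pi$ (mean
pairwise difference per comparable site) and Watterson's
$\theta_W = S/(a_n L)$ are reported per usable site, for cross-gene
comparability. The site-frequency spectrum is tabulated both unfolded
(polarized by the outgroup representative base; unpolarizable sites fall
back to the folded spectrum only) and folded, since either convention may be
wanted downstream; triallelic sites count in $S$ and $\pi$ but are excluded
from the spectrum, which requires biallelic polarization. Synonymous and
non-synonymous split spectra are emitted for polarized sites classifiable on
the ingroup consensus codon background.

## The simulator: what it emulates, and what it does not

`simulate_core_genome()` generates gap-free codon alignments for an ingroup
clade and an outgroup clade from random stop-free ancestral CDS. Its
defaults are the study conditions used throughout the package's validation:
200 genes of 300 codons, 6 ingroup and 3 outgroup strains, 0.05 accepted
substitutions/site on the outgroup lineage, per-site polymorphism
$\theta = 0.01$, and a 2:1 transition bias — values typical of
closely-related bacterial strain collections with a congeneric outgroup.

Selection is modelled as acceptance/rejection: synonymous proposals are
always accepted, non-synonymous ones with probability `omega_divergence` on
the divergence lineage and `omega_polymorphism` within clades (default 0.2
each — equal acceptance is the MK-neutral regime; a 5:1 ratio mimics
adaptive divergence). Mutations that would create a stop codon, including in
combination with earlier mutations in the same codon of a carrier, are
rejected, so the generator never emits internal stops. Targets for accepted
substitution numbers are Poisson draws, so realized rates scale linearly
with the configured ones.

Ingroup polymorphism uses a star-genealogy frequency model: each accepted
mutation gets a distinct site and a derived-allele count drawn from the
neutral $1/k$ law, assigned to random strains. This keeps per-gene truth
analytic, but joint site patterns are not constrained to a single genealogy
— which is deliberate for testing PHI's calibration (incompatibility then
has no positional structure, so PHI p-values should be uniform). The
`"clustered"` genealogy adds two ingroup subclades with shared marker
histories at one quarter of the divergence rate.

Recombinant genes (controlled by `recombinant_fraction`) exchange a
contiguous 3' block covering 50-75% of the gene between lineage histories.
Under the star genealogy one ingroup strain receives the block from the
outgroup lineage — the inter-taxon recombinant that relocates the strain in
the gene tree and is caught by the congruency filter, while remaining
invisible to PHI (a single-strain transfer only creates nested, hence
compatible, bipartitions). Under the clustered genealogy one strain of each
subclade swaps tails, so the two gene halves support conflicting ingroup
topologies — the mosaic pattern PHI detects. The block-size range was chosen
so that inter-taxon recombinants genuinely move the strain across the gene
tree's first split.

What the simulator does **not** emulate: coalescent genealogies with
realistic linkage, indel evolution (gaps are introduced only synthetically
for QC tests), rate variation across sites and genes, codon-usage bias, and
back-mutation-rich saturation. Passing recovery tests on these simulations
therefore demonstrates correctness of the counting and pooling machinery
under controlled conditions, not robustness to every feature of real data.

## Numerical choices

* Undefined statistics are `NA` values, never errors; error conditions are
  classed (`coremk_*_error`) so pipelines can log and skip per gene.
* UPGMA treats distances within `1e-12` of the minimum as tied and resolves
  ties lexicographically; output trees are ultrametric to `1e-9`.
* The bootstrap discards resamples with a zero denominator sum (reported via
  `n_boot_finite`); the percentile interval uses the default quantile type.
* All randomness (simulation, permutations, bootstrap) flows from explicit
  seeds; the pipeline derives per-gene and per-direction substreams from its
  master seed by fixed offsets, so identical inputs and seed reproduce every
  output file byte for byte.
* Validation problem sizes were chosen desk-scale: recovery runs use
  200-gene core genomes over 50 replicates; the counting engine is checked
  against an exhaustive pathway-enumeration oracle on 20,000 random
  single-codon cases; tree recovery on 500 random ultrametric trees of up
  to 16 taxa.

## A worked example

```{r example}
sim <- simulate_core_genome(simulation_config(
  n_genes = 40, gene_length_codons = 200, seed = 42
))
counts <- bind_rows(lapply(sim$genes, function(g) {
  count_mk(g, sim$ingroup, sim$outgroup)
}))
res <- ni_tg(add_mk_statistics(counts), n_boot = 2000, seed = 1)
glance(res)
head(tidy(res))
```

The full pipeline, including QC, tree building, both filters and both test
directions, is one call:

```{r pipeline, eval = FALSE}
run <- run_core_mk_pipeline(sim$genes, "results/", seed = 1)
run$results$ingroup_clade_a
autoplot(run$results$ingroup_clade_a)
```

## Known limitations

* Equal-weight pathway averaging — the standard convention for multi-step
  codon differences — overestimates the non-synonymous share of divergence
  when purifying selection is strong: the histories actually realized are
  synonymous-biased, but every stop-free pathway receives the same weight.
  In the package's own characterization runs (equal acceptance probability
  0.2 on both timescales, 0.05 substitutions/site) this appears as a small
  positive mean DoS, bounded below 0.06; it vanishes when all mutations are
  accepted. Likelihood-based codon models correct for this at the cost of a
  model fit per gene; interpret small positive genome-wide DoS values with
  the divergence level and constraint strength in mind.
* Divergence is counted against a consensus outgroup representative;
  segregating outgroup variants above consensus frequency therefore appear
  as fixed differences, as in any consensus-outgroup MK implementation.
* Codons that are both polymorphic and divergent contribute only to
  polymorphism; this standard bookkeeping slightly undercounts divergence
  at high divergence levels.
* JC69 distances saturate at mismatch proportions near 0.75; very distant
  outgroups will fail the distance stage rather than return unreliable
  trees.
* The PHI permutation test needs several informative sites to be
  informative itself; short or low-diversity genes return `NA` and pass the
  filter.
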