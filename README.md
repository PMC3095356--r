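# allelemine

Characterization of plant resistance-gene allelic series from germplasm
screens, in R.

Many plant disease-resistance genes — the motivating case is the wheat
powdery-mildew resistance gene *Pm3*, a CC–NBS–LRR gene — occur as large
allelic series: a susceptible ancestral consensus plus near-identical
(>97%) alleles that differ by sparse SNPs and by *polymorphic sequence
blocks*, clusters of substitutions copied in from donor alleles or from
diverged paralogs by gene conversion/recombination. Projects that mine
gene banks for new alleles combine a screening funnel over accessions
with sequence-level characterization of whatever is cloned. `allelemine`
implements that computational pipeline:

* **Screening funnel** — stage predicates over an accession table
  (resistant/intermediate phenotype → haplotype STS marker →
  known-allele exclusion → fully-resistant candidates → sequence
  obtained), per-country summaries, and in-silico PCR for marker assays
  (`stage_filters()`, `summarize_funnel()`, `insilico_pcr()`).
* **Alignment & consensus** — a near-identity-specialised global aligner
  (affine-gap Needleman–Wunsch merged center-star, with exact-anchor
  partitioning) and a majority-rule consensus that becomes the 1-based
  coordinate reference (`align_near_identical()`, `build_consensus()`).
* **Variant calling** — consensus-relative SNPs and left-aligned indels
  with coding-effect classification on the consensus codon background,
  pseudogene flagging by net reading-frame shift or boundary-spanning
  deletion, TSV and minimal VCF output (`call_all_variants()`,
  `flag_pseudogene()`).
* **Blocks & chimeras** — greedy segmentation of each allele's
  polymorphisms into blocks vs isolated SNPs (defaults: ≥3 sites within
  250 bp), donor attribution by shared non-consensus bases, chimera
  reports, and ploidy-group block profiles (`segment_blocks()`,
  `match_block()`, `chimera_report()`, `ploidy_block_profile()`).
* **Diversity statistics** — per-domain (CC / NBS / interspacer / LRR)
  and per-ploidy-group polymorphic-site counts, nucleotide diversity π
  (mean pairwise difference with pairwise deletion), synonymous and
  non-synonymous substitution counts with pathway averaging for
  multi-hit codons, and the count-ratio Ka/Ks with the floor-to-2-decimal
  printing convention (`summarize_diversity()`, `substitution_ratio()`).
* **Simulator** — allelic series, paralog pools and accession panels
  with complete ground truth (`sim_config()`, `simulate_allele_series()`,
  `simulate_accession_panel()`), so every stage is testable offline.

## The statistics at the core

For a group of aligned coding sequences and a region *R*:

* π = (1 / C(n,2)) Σ_{i<j} d_ij, where d_ij is the proportion of
  differing sites among sites where both sequences carry an unambiguous
  base;
* Ka and Ks count distinct segregating changes (site, minority base)
  relative to the group consensus, classified through the genetic code;
  codons with several segregating sites are averaged over substitution
  orders (Nei–Gojobori-style pathway averaging), fractional tallies
  rounded half-up;
* the reported ratio is Ka/Ks of the raw counts, truncated to two
  decimals, `-` when Ks = 0; a site-normalized pN/pS
  (`site_normalized_ratio()`) is the labelled alternative.

## Worked example

```r
library(allelemine)

cfg <- sim_config(n_alleles = c(hexaploid = 6L, tetraploid = 4L),
                  n_paralogs = 2L)
ref <- simulate_reference(cfg, seed = 7)
paralogs <- dplyr::bind_rows(lapply(1:2, function(i)
  simulate_paralog(ref$sequence, cfg, paste0("paralog_", i))))
sim <- simulate_allele_series(ref, paralogs, cfg, seed = 8)
panel <- simulate_accession_panel(margins = pm3_screen_margins())

bundle <- run_pipeline(sim$sequences, gene_model = ref$model,
                       accessions = panel, out_dir = "reports")

bundle$funnel[bundle$funnel$origin == "Total", ]
#> # A tibble: 1 × 7
#>   origin stage1 stage2 stage3 stage4 stage5 stage6
#>   <chr>   <int>  <int>  <int>  <int>  <int>  <int>
#> 1 Total     733    154    109     81     51     41
```

The totals read: 733 accessions screened, 154 resistant or intermediately
resistant to at least one mildew isolate, 109 carrying the haplotype
marker, 81 without any known resistance allele, 51 fully resistant
candidates, 41 with a coding sequence obtained. `bundle$diversity` holds
the per-domain statistics (aligned sites, polymorphic sites, π, Ka, Ks,
ratio) for each ploidy group, and `bundle$chimera_reports` names, for
every allele with blocks, the donors sharing each block's non-consensus
bases. All outputs are also written under `reports/` as deterministic
TSV/VCF/JSON.

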