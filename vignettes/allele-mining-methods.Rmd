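---
title: "Methods: characterizing a resistance-gene allelic series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a resistance-gene allelic series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelemine)
```

## The problem

Allele mining searches germplasm collections for novel variants of a gene
of known sequence. The motivating system is the wheat powdery-mildew
resistance gene *Pm3*, a CC–NBS–LRR gene on chromosome 1A that occurs as a
large allelic series: a susceptible ancestral consensus (*Pm3CS*) plus
resistance alleles that differ from it by a handful of SNPs and/or by
*polymorphic sequence blocks* — clusters of nearby polymorphisms that
arise when a stretch of a donor allele or of a diverged paralog is copied
into the gene by gene conversion or recombination. `allelemine` implements
the computational side of such a project end to end:

1. a **screening funnel** over accessions (phenotype → haplotype marker →
   known-allele exclusion → candidate selection → sequencing outcome),
2. **consensus-relative variant calling** on a multiple alignment of
   near-identical alleles,
3. **block segmentation and donor attribution** (chimera reports),
4. **domain-partitioned diversity statistics** (polymorphic sites, π,
   Ka/Ks counts per CC, NBS, interspacer and LRR region),
5. a **ground-truth simulator** so that every stage can be validated
   without any sequence download.

## Gene model and coordinates

All coordinates are 1-based with inclusive intervals, numbered on the
ungapped consensus. The default gene model is a two-exon gene whose
4242 bp coding sequence is interrupted by a 200 bp intron (genomic span
4442 bp). The exact split of the CDS across the two exons is
configuration (default: 2500 bp in exon 1); only the totals are fixed by
the gene. The domain map tiles the CDS contiguously with the published
domain lengths — CC 474, NBS 1062, interspacer 198, LRR 2508 bp
(474 + 1062 + 198 + 2508 = 4242). Individual LRR repeat boundaries are
not published; `default_domain_map(lrr_split = TRUE)` cuts the LRR region
into 28 approximately equal slices and flags them `approximate`, and
users can supply exact boundaries as configuration.

## Alignment and consensus

Allelic series members are expected to be >97% identical, so the aligner
is deliberately specialised rather than a general MSA tool. Each sequence
is aligned to a backbone by global Needleman–Wunsch with affine gaps
(defaults match = 1, mismatch = −2, gap open = −8, gap extend = −1; the
dynamic program is Biostrings' C implementation) and the pairwise results
are merged center-star style, insertions opening shared gap columns. Two
shortcuts keep this fast without changing results in the regime the tool
targets: exact 64-mer anchors partition long pairs so only divergent
segments enter the dynamic program, and equal-length segments within
moderate divergence (≤20% mismatch) are paired on the diagonal, because a
gap pair (cost 8 + 1 per base, twice) can never beat the ≤3-point gain
per avoided mismatch at these identity levels. For sequences under
500 bp the full dynamic program is always used, and the test suite checks
its scores against an independent Gotoh implementation.

The consensus is the per-column majority base over the allele rows
(paralogs excluded); base ties are broken lexicographically (A < C < G <
T) and reported, a column where gaps outnumber every base gets a gap
consensus and is excluded from reference numbering. The pipeline runs
**two passes**: a first alignment only to estimate the consensus, then a
re-alignment of every sequence against the ungapped consensus. This
matters: if the first-pass backbone happens to carry a divergent
conversion tract, its locally optimal gap placement would otherwise leak
into every row and create artifact indel pairs in other alleles'
variant calls.

## Variant calling and coding effects

Variants are called per allele against the consensus row: one SNP per
mismatching column, one record per maximal gap run. `N` produces no call.
Indels are left-aligned against the consensus, and an equal-length,
immediately adjacent deletion + insertion pair is re-expressed as the run
of substitutions it actually is (another alignment-artifact guard).

A SNP's coding effect is evaluated on the consensus codon background:
the alternative base is substituted into the consensus codon, the other
two positions staying at consensus state, and the translations compared.
When one allele carries two SNPs in the same codon each record still gets
this per-record effect; the joint, order-averaged treatment lives in the
diversity module. Indels inside the CDS are `frame_preserving_indel` when
their CDS overlap is a multiple of three, else `frame_disrupting`.

An allele is flagged as a **pseudogene** when its indels leave a net
reading-frame shift over the CDS, or when a deletion spans an exon/intron
boundary (after which exons can no longer be assigned). Using the *net*
shift rather than "any frame-disrupting record" is deliberate: a
compensating pair that restores the frame downstream leaves a full-length
reading frame, and it also makes the flag robust to residual alignment
ambiguity inside highly divergent tracts. Frame-disrupted alleles carry
no valid gene model and are excluded from all coding statistics.

## Blocks and donor attribution

Polymorphic sites of one allele are clustered greedily left to right: a
site joins the current cluster when it is within `max_gap` (default
250 bp) of the previous site; clusters with at least `min_sites`
(default 3) become blocks, the rest are isolated SNPs. The parameters are
configuration, not biology — published block figures show blocks of
roughly 8–43 sites that these defaults reproduce — and segmentation is a
partition: every site lands in exactly one block or the isolated list.

A block is scored against every candidate donor by counting member sites
at which the donor carries the allele's non-consensus base at the
homologous column ("shared" means the identical base, not mere
co-polymorphism). Sites where the donor has a gap are excluded from both
counts. Classification: `identical` (all comparable sites shared),
`partial` (share ≥ 40%, configurable), else `unique`; ties are broken by
donor id and all tied donors are listed. A window-query variant
(`window_shared_sites()`) answers the same question for an explicit
coordinate interval, since published "x out of y sites" counts are
sometimes windows rather than segmented blocks. `ploidy_block_profile()`
groups identical block footprints (position set + alternative bases)
across alleles and flags footprints confined to one ploidy group, the
pattern reported for tetraploid-specific LRR blocks.

## Diversity statistics

For each ploidy group (and the union) and each region (whole CDS plus
the four domains):

* **Polymorphic sites**: columns with ≥2 distinct non-N bases, columns
  containing any gap excluded entirely (complete deletion).
* **π**: the average over all unordered pairs of (differing sites /
  compared sites), comparing only columns where both members carry an
  unambiguous base (pairwise deletion). Note a consequence of this
  standard estimator: duplicating a panel of *n* sequences rescales π by
  exactly 2(*n*−1)/(2*n*−1), because the copies contribute zero-distance
  pairs; π never increases under duplication. The tests assert this exact
  identity rather than literal invariance.
* **Ka/Ks counts**: one segregating change per distinct (site, minority
  base) relative to the *group* consensus. A codon with several
  segregating sites is handled by equal-weight pathway averaging over
  substitution orders (and over base combinations when a site segregates
  for more than one minority base); fractional tallies are rounded
  half-up at the end. A step to or from a stop codon counts as
  non-synonymous; unlike some tools we do not discard stop-crossing
  paths, which on >97%-identical coding alleles are vanishingly rare.
* **Ratio**: the reported "Ka/Ks" is the plain ratio of the two counts,
  not normalized per synonymous/non-synonymous site — that convention is
  what reproduces the published cells (252/103 → 2.44, 221/66 → 3.34). A
  site-normalized Nei–Gojobori pN/pS with optional Jukes–Cantor
  correction is available as the explicitly labelled alternative
  `site_normalized_ratio()`.
* **Formatting**: printed values are truncated (floored) to two decimals
  (2.375 prints 2.37), matching the published convention; rounding is
  available as an option. Sites-per-100-bp is reported with both the
  ungapped reference length and the gapped column count as denominators,
  because the published table mixes the two and never states which is
  used; only cells consistent with the ungapped convention are used as
  checks.

## The screening funnel

Stage predicates, applied cumulatively: (2) resistant **or**
intermediately resistant (R/IR) to ≥1 isolate of the panel; (3) haplotype
STS marker present; (4) no known resistance allele detected; (5)
candidate = fully resistant (R, not merely IR) to ≥1 isolate — the two
different phenotype rules at stages 2 and 5 are both stated project
rules, encoded as distinct predicates; (6) coding sequence obtained
(sequencing failure is an input field, not predicted). Marker genotyping
can be done in silico: `insilico_pcr()` finds the forward primer and the
reverse-complemented reverse primer downstream with a configurable
mismatch budget and checks the amplicon length against the expected size
(default tolerance ±50 bp) — the shipped examples use synthetic primers
with the diagnostic 946 bp geometry, as the real primer sequences are
published elsewhere.

## The simulator

`sim_config()` defaults encode the study conditions: a 4442 bp gene
(4242 bp CDS, 200 bp intron), 31 hexaploid + 23 tetraploid alleles (the
size of the modelled series), paralogs at 83.4–88.3% identity, alleles
≥97% identical to the reference, indels in multiples of 3 bp, a rare
(p = 0.05, matching ~2 pseudogenes in 54 sequences) 302 bp deletion
spanning the exon-1/intron boundary, SNP counts Poisson with mean 6, a
0.72 non-synonymous fraction (reproducing the combined Ka:Ks count ratio
of ~2.6 in expectation), and geometric conversion-tract lengths with
mean 300 bp — the tract-length distribution is not published; geometric
with this mean spans the reported range from tens of bp to multi-LRR
blocks, and paralog-derived tracts are capped (at 0.025·L/divergence,
~670 bp) so no allele violates the 97% identity floor. Random tract and
SNP placement keeps every column's count of non-ancestral carriers below
half the panel, so the majority consensus remains the ancestral state by
construction (an explicitly configured shared tract is exempt from this
constraint but still counted). Conversion tracts are contiguous donor copies; deliberate overwriting of tract sites by
later SNPs, and a shared tract given to a configurable number of members
of one ploidy group, reproduce the "partially shared" and
"ploidy-specific" block patterns. Phenotypes in simulated accession
panels are bookkeeping flags consistent with the funnel margins, not a
model of infection biology.

Ground truth records every SNP, tract, and indel; `build_allele_sequence()`
replays the truth through the same construction path, so
truth-vs-sequence round trips are exact by design and the tests verify
calling, attribution and flagging against it.

What the simulator does **not** emulate: sequencing error, heterozygous
or paralog-collapsed assemblies, intron polymorphism (SNPs are placed in
the CDS only), mosaic tracts, coalescent structure, or selection. Passing
recovery tests therefore demonstrate correctness of the pipeline's logic
on clean near-identical series, not robustness to noisy assemblies.

## Problem sizes and numerical choices

The recovery checks run 50 seeded replicates of an 8-allele panel with
one paralog donor at full gene length, with tract and SNP settings as
above; the oracle checks use 100 random small alignments for π, all
two-change codons exhaustively, and random pairs ≤200 bp against the full
dynamic program. These sizes give the properties room to fail while
keeping the default test run quick. Other conventions: consensus ties
A<C<G<T (deterministic and visible); indel left-alignment; ratio and
per-100bp formatters floor by default; undefined ratios (Ks = 0) render
as `"-"`; all outputs are plain TSV/JSON/FASTA/VCF written
deterministically, so identical configurations produce byte-identical
files.

## Known limitations

* Gap placement inside highly divergent conversion tracts is not
  guaranteed to match any particular external aligner base-for-base; the
  per-record effect labels inside such tracts can differ even when the
  net interpretation (block, donor, frame) is stable.
* Exact reproduction of the published substitution counts from real
  sequences would require the original sequence set (and the original
  tool's undocumented multi-hit convention) and is out of scope at desk
  scale; the package instead proves its arithmetic against the printed
  cells and its counting against exhaustive oracles.
* The funnel operates on per-accession fields; it does not model isolate
  virulence spectra, only records phenotypes against a panel.

## A worked example

```{r example, eval = FALSE}
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
bundle$funnel          # per-country screening-stage counts
bundle$diversity       # per-domain, per-group diversity statistics
bundle$chimera_reports # per-allele block/donor attribution
```
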