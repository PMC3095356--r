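#' Reference screening-funnel margins (733-accession Pm3 screen)
#'
#' Per-country stage counts of a large Pm3 allele-mining screen of 733
#' wheat gene-bank accessions from 20 countries: total accessions,
#' accessions resistant or intermediately resistant to at least one
#' powdery mildew isolate, accessions with the Pm3 haplotype marker,
#' accessions lacking the known Pm3a-Pm3g alleles, completely resistant
#' candidate accessions, and accessions with a Pm3 sequence obtained.
#' Used as exact margins for the accession-panel simulator and as the
#' fixture the funnel stage predicates must reproduce.
#'
#' @return A tibble with columns `origin`, `stage1` ... `stage6`.
#' @export
pm3_screen_margins <- function() {
  tibble::tribble(
    ~origin,       ~stage1, ~stage2, ~stage3, ~stage4, ~stage5, ~stage6,
    "India",            92L,     27L,     21L,     12L,      7L,      6L,
    "China",            90L,     15L,      8L,      6L,      2L,      2L,
    "Nepal",            78L,     33L,     33L,     25L,     20L,     19L,
    "Ethiopia",         63L,     10L,      8L,      8L,      4L,      3L,
    "Mexico",           57L,      5L,      3L,      3L,      1L,      1L,
    "USA",              53L,      7L,      5L,      5L,      2L,      0L,
    "France",           51L,      7L,      3L,      2L,      2L,      1L,
    "Japan",            51L,      1L,      0L,      0L,      0L,      0L,
    "Russia",           38L,      6L,      3L,      1L,      0L,      0L,
    "Argentina",        31L,     10L,      5L,      3L,      3L,      2L,
    "Iraq",             27L,      7L,      4L,      4L,      3L,      2L,
    "Canada",           25L,      6L,      5L,      5L,      3L,      2L,
    "Australia",        23L,      7L,      3L,      2L,      2L,      1L,
    "Tajikistan",       16L,      6L,      3L,      2L,      1L,      1L,
    "Kazakhastan",       9L,      2L,      1L,      0L,      0L,      0L,
    "Azerbaizan",        7L,      1L,      1L,      1L,      0L,      0L,
    "Sudan",             7L,      2L,      2L,      2L,      1L,      1L,
    "Switzerland",       7L,      1L,      0L,      0L,      0L,      0L,
    "Kyrgyztan",         6L,      0L,      0L,      0L,      0L,      0L,
    "Uzbekistan",        2L,      1L,      1L,      0L,      0L,      0L
  )
}

#' Known-allele detections among haplotype-positive accessions
#'
#' Counts of accessions in the reference screen found to carry one of
#' the known resistance alleles Pm3a-Pm3g (the drop between funnel
#' stages 3 and 4): Pm3c in 17 accessions, Pm3b in 6, Pm3f and Pm3e in 2
#' each, Pm3d in 1 - 28 carriers in total.
#'
#' @return A named integer vector.
#' @export
pm3_known_allele_counts <- function() {
  c(Pm3c = 17L, Pm3b = 6L, Pm3f = 2L, Pm3e = 2L, Pm3d = 1L)
}

#' Reference per-domain diversity statistics of the Pm3 allelic series
#'
#' Published per-region, per-ploidy-group diversity statistics for the
#' 54 non-pseudogene Pm3 coding sequences: aligned sites, polymorphic
#' sites, sites per 100 bp, nucleotide diversity, synonymous (Ks) and
#' non-synonymous (Ka) substitution counts and their raw-count ratio.
#' Shipped so that the package formatters ([substitution_ratio()],
#' [per_100bp()]) can be checked against the printed cells; cells whose
#' printed per-100bp value is inconsistent with the ungapped region
#' length (the source table mixes gapped and ungapped denominators) are
#' marked `per_100bp_checks = FALSE`.
#'
#' @return A tibble with one row per group x region.
#' @export
pm3_diversity_table <- function() {
  tibble::tribble(
    ~group,      ~region,       ~sites, ~poly, ~per_100bp, ~pi,     ~ks, ~ka, ~ratio, ~per_100bp_checks,
    "hexaploid", "CDS",          4242L,  299L,  7.03,      0.01008, 103L, 252L, 2.44,  FALSE,
    "hexaploid", "CC",            474L,    0L,  0.00,      0.00000,   0L,   0L,   NA,  TRUE,
    "hexaploid", "NBS",          1062L,   80L,  7.51,      0.00742,  37L,  47L, 1.27,  FALSE,
    "hexaploid", "Interspacer",   198L,   37L, 18.40,      0.0379,   12L,  28L, 2.33,  FALSE,
    "hexaploid", "LRR",          2508L,  182L,  7.25,      0.0109,   54L, 177L, 3.27,  TRUE,
    "tetraploid", "CDS",         4242L,  185L,  4.36,      0.01113,  43L, 147L, 3.41,  TRUE,
    "tetraploid", "CC",           474L,    3L,  0.63,      0.00086,   1L,   2L, 2.00,  TRUE,
    "tetraploid", "NBS",         1062L,    4L,  0.37,      0.00045,   1L,   3L, 3.00,  TRUE,
    "tetraploid", "Interspacer",  198L,   31L, 15.65,      0.02598,   9L,  22L, 2.44,  TRUE,
    "tetraploid", "LRR",         2508L,  147L,  5.86,      0.01643,  32L, 120L, 3.75,  TRUE,
    "combined",  "CDS",          4242L,  356L,  8.38,      0.01311, 121L, 311L, 2.57,  FALSE,
    "combined",  "CC",            474L,    3L,  0.63,      0.00038,   1L,   2L, 2.00,  TRUE,
    "combined",  "NBS",          1062L,   84L,  7.90,      0.00451,  38L,  50L, 1.31,  TRUE,
    "combined",  "Interspacer",   198L,   43L, 21.39,      0.03273,  16L,  38L, 2.37,  FALSE,
    "combined",  "LRR",          2508L,  226L,  9.02,      0.01761,  66L, 221L, 3.34,  FALSE
  )
}
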