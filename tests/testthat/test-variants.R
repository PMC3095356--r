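# small helper: consensus-referenced alignment from explicit gapped rows
cons_aln <- function(...) {
  rows <- c(...)
  new_allele_alignment(rows, ref_id = "consensus")
}

test_that("an allele identical to the consensus yields an empty table", {
  aln <- cons_aln(consensus = "ACGTACGT", a1 = "ACGTACGT")
  vt <- call_variants(aln, "a1")
  expect_equal(nrow(vt), 0L)
  expect_error(call_variants(aln, "nope"), "unknown allele")
})

test_that("SNPs, insertions and deletions are called in consensus coordinates", {
  #             12345 678
  aln <- cons_aln(consensus = "ACGTA-CGT",
                  a1        = "ACTTAGCG-")
  vt <- call_variants(aln, "a1")
  snp <- vt[vt$kind == "SNP", ]
  expect_equal(snp$ref_pos, 3L)
  expect_equal(snp$ref, "G"); expect_equal(snp$alt, "T")
  ins <- vt[vt$kind == "insertion", ]
  expect_equal(ins$ref_pos, 5L)      # anchored after position 5
  expect_equal(ins$alt, "G")
  del <- vt[vt$kind == "deletion", ]
  expect_equal(del$ref_pos, 8L)
  expect_equal(del$ref, "T")
})

test_that("N in the allele produces no call", {
  aln <- cons_aln(consensus = "ACGTACGT", a1 = "ACNTACGT")
  expect_equal(nrow(call_variants(aln, "a1")), 0L)
})

test_that("indels are left-aligned against the consensus", {
  # deletion of one A in a AAA homopolymer: leftmost representation
  aln <- cons_aln(consensus = "CAAAG", a1 = "CA-AG")
  del <- call_variants(aln, "a1")
  expect_equal(del$kind, "deletion")
  expect_equal(del$ref_pos, 2L)
})

test_that("adjacent equal-length deletion+insertion pairs collapse to SNPs", {
  aln <- cons_aln(consensus = "ACGT-ACGT", a1 = "ACG-CACGT")
  vt <- call_variants(aln, "a1")
  expect_equal(vt$kind, "SNP")
  expect_equal(vt$ref_pos, 4L)
  expect_equal(vt$alt, "C")
})

test_that("coding effects follow the genetic code on the consensus background", {
  tm <- tiny_model(6)
  # consensus codons TTT CTT
  cons <- "TTTCTT"
  r1 <- list(ref_pos = 3L, kind = "SNP", ref = "T", alt = "A")
  expect_equal(classify_effect(r1, tm$model, cons), "nonsynonymous") # Phe->Leu
  r2 <- list(ref_pos = 6L, kind = "SNP", ref = "T", alt = "A")
  expect_equal(classify_effect(r2, tm$model, cons), "synonymous")    # Leu->Leu
})

test_that("single-SNP effects match a full-translation brute-force oracle", {
  set.seed(46)
  for (rep in 1:25) {
    n_codons <- 10L
    tm <- tiny_model(3L * n_codons)
    cds <- paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                c("TAA", "TAG", "TGA")),
                        n_codons, replace = TRUE), collapse = "")
    pos <- sample(3L * n_codons, 1L)
    refb <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    got <- classify_effect(list(ref_pos = pos, kind = "SNP",
                                ref = refb, alt = alt), tm$model, cds)
    mutant <- cds
    substr(mutant, pos, pos) <- alt
    aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                                 no.init.codon = TRUE))
    aa_mut <- as.character(Biostrings::translate(
      Biostrings::DNAString(mutant), no.init.codon = TRUE))
    want <- if (aa_ref == aa_mut) "synonymous" else "nonsynonymous"
    expect_equal(got, want, info = paste("pos", pos))
  }
})

test_that("indel effects depend on length mod 3 and location", {
  gm <- default_gene_model()
  # 45 bp in-frame deletion inside the LRR-encoding region
  d45 <- list(ref_pos = 3000L, kind = "deletion",
              ref = strrep("A", 45), alt = "")
  expect_equal(classify_effect(d45, gm, NULL), "frame_preserving_indel")
  d1 <- list(ref_pos = 3000L, kind = "deletion", ref = "A", alt = "")
  expect_equal(classify_effect(d1, gm, NULL), "frame_disrupting")
  i3 <- list(ref_pos = 1800L, kind = "insertion", ref = "", alt = "TAG")
  expect_equal(classify_effect(i3, gm, NULL), "frame_preserving_indel")
  # intronic SNP
  s_int <- list(ref_pos = 2600L, kind = "SNP", ref = "A", alt = "G")
  expect_equal(classify_effect(s_int, gm, random_seq(4442)), "intronic")
})

test_that("pseudogene flagging: frame shifts and boundary-spanning deletions", {
  gm <- default_gene_model()
  snp_only <- tibble::tibble(allele_id = "a", ref_pos = c(10L, 400L),
                             kind = "SNP", ref = c("A", "C"),
                             alt = c("G", "T"))
  expect_false(flag_pseudogene(snp_only, gm)$pseudogene)

  # 302 bp deletion spanning the exon-1/intron junction
  del302 <- tibble::tibble(allele_id = "a", ref_pos = 2350L,
                           kind = "deletion", ref = strrep("A", 302),
                           alt = "")
  fp <- flag_pseudogene(del302, gm)
  expect_true(fp$pseudogene)
  expect_match(fp$reason, "boundary")

  # lone 1 bp deletion in the CDS: net frame shift
  del1 <- tibble::tibble(allele_id = "a", ref_pos = 100L, kind = "deletion",
                         ref = "A", alt = "")
  expect_true(flag_pseudogene(del1, gm)$pseudogene)

  # compensating 1 bp deletion + 1 bp insertion: frame restored
  comp <- dplyr::bind_rows(del1, tibble::tibble(
    allele_id = "a", ref_pos = 300L, kind = "insertion", ref = "", alt = "G"))
  expect_false(flag_pseudogene(comp, gm)$pseudogene)
})

test_that("variant round-trip: applying the table to the consensus rebuilds the allele", {
  set.seed(47)
  cfg <- sim_config(n_alleles = c(hexaploid = 4L, tetraploid = 2L),
                    n_paralogs = 1L, conversion_prob = 0.6,
                    paralog_donor_prob = 1)
  ref <- simulate_reference(cfg, seed = 470)
  par <- simulate_paralog(ref$sequence, cfg, "paralog_1", seed = 471)
  sim <- simulate_allele_series(ref, par, cfg, seed = 472)
  bundle <- run_pipeline(sim$sequences, gene_model = ref$model)
  for (id in names(sim$truth)) {
    rebuilt <- apply_variants(bundle$consensus,
                              bundle$variants[bundle$variants$allele_id == id, ])
    expect_identical(rebuilt, sim$sequences$bases[sim$sequences$id == id],
                     info = id)
  }
})

test_that("variant calling is invariant to row order", {
  set.seed(48)
  anc <- random_seq(300)
  a1 <- mutate_seq(anc, 3)$seq
  a2 <- mutate_seq(anc, 2)$seq
  aln1 <- new_allele_alignment(c(consensus = anc, a1 = a1, a2 = a2),
                               "consensus")
  aln2 <- new_allele_alignment(c(a2 = a2, consensus = anc, a1 = a1),
                               "consensus")
  expect_equal(call_variants(aln1, "a1"), call_variants(aln2, "a1"))
})

test_that("variant writers emit TSV and minimal VCF", {
  gm <- tiny_model(9)
  aln <- cons_aln(consensus = "ACGTTTCGA-", a1 = "AGGT-TCGAC")
  vt <- call_variants(aln, "a1")
  vt <- annotate_variants(vt, gm$model, gm$domain_map, "ACGTTTCGA")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants_tsv(vt, tsv)
  write_variants_vcf(vt, "ACGTTTCGA", vcf)
  expect_equal(nrow(utils::read.delim(tsv)), nrow(vt))
  lines <- readLines(vcf)
  expect_match(lines[1], "VCFv4.2", fixed = TRUE)
  expect_equal(sum(!startsWith(lines, "#")), nrow(vt))
})
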