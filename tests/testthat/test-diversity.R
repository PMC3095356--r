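test_that("pi matches the single-pair and three-sequence hand calculations", {
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 99), "G")
  aln <- panel_alignment(c(x = a, y = b))
  expect_equal(nucleotide_diversity(aln, c("x", "y")), 0.01)

  # three sequences of length 10 with pairwise differences 1, 1, 2
  s1 <- "AAAAAAAAAA"
  s2 <- "GAAAAAAAAA"
  s3 <- "AGAAAAAAAA"
  aln3 <- panel_alignment(c(s1 = s1, s2 = s2, s3 = s3))
  expect_equal(nucleotide_diversity(aln3, c("s1", "s2", "s3")),
               (1 + 2 + 1) / (3 * 10))

  expect_equal(nucleotide_diversity(panel_alignment(c(x = a, y = a)),
                                    c("x", "y")), 0)
  expect_error(nucleotide_diversity(aln, "x"), "at least 2")
})

test_that("pi equals the all-pairs brute-force oracle on random panels", {
  set.seed(52)
  for (rep in 1:20) {
    rows <- random_panel(sample(3:7, 1), sample(30:80, 1))
    aln <- panel_alignment(rows)
    expect_equal(nucleotide_diversity(aln, names(rows)), oracle_pi(rows),
                 tolerance = 1e-12)
  }
})

test_that("pi uses pairwise deletion over gap/N columns", {
  rows <- c(a = "AANA", b = "AGCA", c = "A-CA")
  aln <- panel_alignment(rows)
  # pairs: a-b compare cols 1,2,4 (1 diff); a-c cols 1,4 (0); b-c cols 1,3,4 (0)
  expect_equal(nucleotide_diversity(aln, names(rows)),
               (1 / 3 + 0 / 2 + 0 / 3) / 3)
})

test_that("polymorphic site counting uses complete deletion and region masks", {
  rows <- c(a = "AAAAAA", b = "AAAAAT", c = "AA-AGT")
  aln <- panel_alignment(rows)
  # col 3 has a gap (excluded); cols 5 and 6 segregate
  expect_equal(count_polymorphic_sites(aln, names(rows)), 2L)
  expect_equal(count_polymorphic_sites(aln, c("a", "a2" = "a")), 0L)
  expect_error(count_polymorphic_sites(aln, character(0)), "empty")
})

test_that("whole-CDS polymorphic count equals the sum over tiling domains", {
  set.seed(53)
  cfg <- sim_config(n_alleles = c(hexaploid = 5L, tetraploid = 4L),
                    n_paralogs = 0L, conversion_prob = 0, snp_mean = 10,
                    indel_prob = 0, pseudogene_prob = 0)
  ref <- simulate_reference(cfg, seed = 530)
  sim <- simulate_allele_series(ref, NULL, cfg, seed = 531)
  bundle <- run_pipeline(sim$sequences, gene_model = ref$model)
  dm <- default_domain_map()
  ids <- sim$sequences$id
  total <- count_polymorphic_sites(bundle$alignment, ids, ref$model, dm, "CDS")
  parts <- vapply(c("CC", "NBS", "Interspacer", "LRR"), function(r) {
    count_polymorphic_sites(bundle$alignment, ids, ref$model, dm, r)
  }, integer(1))
  expect_equal(total, sum(parts))
  # injected ground truth: distinct exonic SNP positions across the panel
  truth_sites <- length(unique(unlist(lapply(sim$truth,
                                             function(t) t$snps$pos))))
  expect_equal(total, truth_sites)
})

test_that("single segregating changes are classified by the genetic code", {
  tm <- tiny_model(3)
  aln <- panel_alignment(c(a = "TTT", b = "TTC"))   # Phe -> Phe
  subs <- count_substitutions(aln, c("a", "b"), tm$model, tm$domain_map,
                              region = "CDS")
  expect_equal(c(subs$ks_count, subs$ka_count), c(1L, 0L))

  aln2 <- panel_alignment(c(a = "TTT", b = "TTA"))  # Phe -> Leu
  subs2 <- count_substitutions(aln2, c("a", "b"), tm$model, tm$domain_map,
                               region = "CDS")
  expect_equal(c(subs2$ks_count, subs2$ka_count), c(0L, 1L))
})

test_that("two-change codons are pathway-averaged (exhaustive oracle)", {
  codons <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  set.seed(54)
  picks <- sample(codons, 12)
  for (cod in picks) {
    sites <- sample(1:3, 2)
    b1 <- substr(cod, sites[1], sites[1])
    b2 <- substr(cod, sites[2], sites[2])
    a1 <- sample(setdiff(c("A", "C", "G", "T"), b1), 1)
    a2 <- sample(setdiff(c("A", "C", "G", "T"), b2), 1)
    got <- allelemine:::classify_codon_changes(
      cod, tibble::tibble(offset = sites, alt = c(a1, a2)))
    want <- oracle_two_change(cod, sites[1], a1, sites[2], a2)
    expect_equal(unname(got["syn"]), unname(want["syn"]),
                 info = paste(cod, sites[1], a1, sites[2], a2))
  }
})

test_that("ratio and per-100bp formatters reproduce printed-cell conventions", {
  expect_equal(substitution_ratio(252, 103), 2.44)
  expect_equal(substitution_ratio(120, 32), 3.75)
  expect_equal(substitution_ratio(221, 66), 3.34)
  expect_equal(substitution_ratio(38, 16), 2.37)   # 2.375 floors, not rounds
  expect_true(is.na(substitution_ratio(0, 0)))
  expect_error(substitution_ratio(-1, 2), "non-negative")

  expect_equal(per_100bp(3, 474), 0.63)
  expect_equal(per_100bp(147, 2508), 5.86)
  expect_equal(per_100bp(0, 1000), 0)
  expect_error(per_100bp(1, 0), "positive")
})

test_that("diversity summary has one row per group x region with set-union counts", {
  set.seed(55)
  cfg <- sim_config(n_alleles = c(hexaploid = 4L, tetraploid = 3L),
                    n_paralogs = 0L, conversion_prob = 0, snp_mean = 8,
                    indel_prob = 0, pseudogene_prob = 0)
  ref <- simulate_reference(cfg, seed = 550)
  sim <- simulate_allele_series(ref, NULL, cfg, seed = 551)
  bundle <- run_pipeline(sim$sequences, gene_model = ref$model)
  d <- bundle$diversity
  expect_equal(nrow(d), 15L)
  expect_setequal(unique(d$group), c("hexaploid", "tetraploid", "combined"))
  # combined polymorphic count >= each per-group count (set union)
  for (reg in unique(d$region)) {
    sub <- d[d$region == reg, ]
    expect_gte(sub$polymorphic_sites[sub$group == "combined"],
               max(sub$polymorphic_sites[sub$group != "combined"]))
  }
  expect_equal(d$aligned_sites[d$region == "CDS"][1], 4242L)
})

test_that("duplicating a panel rescales pi by the exact pair-weight identity", {
  set.seed(56)
  rows <- random_panel(5, 60)
  aln <- panel_alignment(rows)
  pi1 <- nucleotide_diversity(aln, names(rows))
  dup <- c(rows, stats::setNames(rows, paste0(names(rows), "_copy")))
  pi2 <- nucleotide_diversity(panel_alignment(dup), names(dup))
  n <- length(rows)
  # under the unordered-pairs definition, duplication rescales pi by
  # exactly 2(n-1)/(2n-1): identical copies add zero-distance pairs
  expect_equal(pi2, pi1 * 2 * (n - 1) / (2 * n - 1), tolerance = 1e-12)
  expect_lte(pi2, pi1 + 1e-15)
})

test_that("site-normalized pN/pS is reported as a labelled alternative", {
  tm <- tiny_model(6)
  aln <- panel_alignment(c(a = "TTTCTT", b = "TTACTT"))
  r <- site_normalized_ratio(aln, c("a", "b"), tm$model, tm$domain_map,
                             jukes_cantor = FALSE)
  expect_gt(r$nonsyn_sites, r$syn_sites)
  expect_true(is.finite(r$pn))
})
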