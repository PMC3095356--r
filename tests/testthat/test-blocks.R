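snp_table <- function(allele_id, pos, alt = NULL, ref = NULL) {
  tibble::tibble(allele_id = allele_id, ref_pos = as.integer(pos),
                 kind = "SNP",
                 ref = if (is.null(ref)) "A" else ref,
                 alt = if (is.null(alt)) "G" else alt)
}

test_that("segmentation follows the greedy min_sites/max_gap rule", {
  # two sites 1000 bp apart: below min_sites, no blocks
  vt <- snp_table("a", c(100, 1100))
  seg <- segment_blocks(vt, "a")
  expect_equal(nrow(seg$blocks), 0L)
  expect_equal(nrow(seg$isolated), 2L)

  # hand-evaluated clustering: {100,150,220} cluster, 3000 isolated
  vt2 <- snp_table("a", c(100, 150, 220, 3000))
  seg2 <- segment_blocks(vt2, "a")
  expect_equal(nrow(seg2$blocks), 1L)
  expect_equal(seg2$blocks$start, 100L)
  expect_equal(seg2$blocks$end, 220L)
  expect_equal(seg2$blocks$n_sites, 3L)
  expect_equal(seg2$isolated$ref_pos, 3000L)
})

test_that("segmentation partitions every polymorphic site exactly once", {
  set.seed(49)
  for (rep in 1:10) {
    pos <- sort(sample(4000, sample(5:30, 1)))
    vt <- snp_table("a", pos)
    seg <- segment_blocks(vt, "a",
                          min_sites = sample(2:4, 1),
                          max_gap = sample(c(100, 250, 400), 1))
    in_blocks <- unlist(seg$blocks$positions)
    together <- sort(c(in_blocks, seg$isolated$ref_pos))
    expect_equal(together, pos)
  }
})

test_that("donor matching counts shared non-consensus bases and classifies", {
  anc <- strrep("A", 500)
  # allele: block of 4 alt bases; donors with varying sharing
  mk <- function(pos, base) {
    ch <- strsplit(anc, "")[[1]]; ch[pos] <- base; paste(ch, collapse = "")
  }
  pos <- c(100, 150, 200, 250)
  allele <- mk(pos, "G")
  d_full <- mk(pos, "G")                      # shares all 4
  d_half <- mk(pos[1:2], "G")                 # shares 2 of 4
  d_none <- anc                               # consensus-identical
  aln <- new_allele_alignment(
    c(consensus = anc, al = allele, d_full = d_full, d_half = d_half,
      d_none = d_none), "consensus")
  vt <- call_variants(aln, "al")
  seg <- segment_blocks(vt, "al")
  m <- match_block(seg$blocks[1, ], aln, vt)
  expect_equal(m$donor_id, c("d_full", "d_half", "d_none"))
  expect_equal(m$shared_sites, c(4L, 2L, 0L))
  expect_equal(m$total_sites, rep(4L, 3))
  expect_equal(m$classification, c("identical", "partial", "unique"))
  expect_error(match_block(seg$blocks[1, ], aln, vt, donor_ids = "ghost"),
               "missing")
})

test_that("a block always matches its own allele completely", {
  set.seed(50)
  anc <- random_seq(800)
  al <- mutate_seq(anc, 6)
  aln <- new_allele_alignment(c(consensus = anc, al = al$seq), "consensus")
  vt <- call_variants(aln, "al")
  seg <- segment_blocks(vt, "al", min_sites = 2L, max_gap = 800L)
  if (nrow(seg$blocks) > 0) {
    m <- match_block(seg$blocks[1, ], aln, vt, donor_ids = "al")
    expect_equal(m$shared_sites, m$total_sites)
  }
})

test_that("simulated conversion tract is segmented as one block and attributed", {
  set.seed(51)
  cfg <- sim_config(n_alleles = c(hexaploid = 3L, tetraploid = 2L),
                    n_paralogs = 1L, conversion_prob = 0, snp_mean = 0)
  ref <- simulate_reference(cfg, seed = 510)
  par <- simulate_paralog(ref$sequence, cfg, "paralog_1", seed = 511)
  sim <- simulate_allele_series(ref, par, cfg, seed = 512)
  # hand one allele a 400 bp tract from the paralog
  id <- "hex_allele_1"
  tr <- tibble::tibble(donor = "paralog_1", start = 2001L, end = 2400L)
  entry <- sim$truth[[id]]
  entry$tracts <- tr
  seqs <- sim$sequences
  seqs$bases[seqs$id == id] <-
    build_allele_sequence(ref$sequence, entry,
                          stats::setNames(par$bases, par$id))
  bundle <- run_pipeline(seqs, gene_model = ref$model)
  vt <- bundle$variants
  seg <- segment_blocks(vt, id)
  ov <- seg$blocks[seg$blocks$start <= 2400 & seg$blocks$end >= 2001, ]
  expect_equal(nrow(ov), 1L)
  m <- match_block(ov[1, ], bundle$alignment, vt)
  expect_equal(m$donor_id[1], "paralog_1")
  expect_equal(m$classification[1], "identical")
  # diagnostic sites: every tract variant is shared with the donor
  expect_equal(m$shared_sites[1], m$total_sites[1])
})

test_that("a tract overwritten by later private SNPs matches partially", {
  anc <- strrep("ACGT", 125)   # 500 bp
  ch_d <- strsplit(anc, "")[[1]]
  pos <- seq(100, 260, by = 20)          # 9 donor-diagnostic sites
  for (p in pos) ch_d[p] <- setdiff(c("A", "C", "G", "T"), ch_d[p])[1]
  donor <- paste(ch_d, collapse = "")
  ch_a <- ch_d
  for (p in pos[1:2]) ch_a[p] <- setdiff(c("A", "C", "G", "T"),
                                         c(ch_a[p],
                                           strsplit(anc, "")[[1]][p]))[1]
  allele <- paste(ch_a, collapse = "")   # 2 of 9 overwritten, still non-consensus
  aln <- new_allele_alignment(c(consensus = anc, al = allele, D = donor),
                              "consensus")
  vt <- call_variants(aln, "al")
  seg <- segment_blocks(vt, "al")
  m <- match_block(seg$blocks[1, ], aln, vt, donor_ids = "D")
  expect_equal(m$shared_sites, 7L)
  expect_equal(m$total_sites, 9L)
  expect_equal(m$classification, "partial")
})

test_that("chimera reports name donors and flag paralog-derived blocks", {
  rep0 <- chimera_report("a", empty_blocks <- segment_blocks(
    snp_table("a", c(10, 2000)), "a")$blocks, NULL)
  expect_equal(rep0$summary, "SNP-only allele")
  expect_equal(rep0$n_blocks, 0L)

  blocks <- tibble::tibble(allele_id = "a", block_id = "a.B1",
                           start = 100L, end = 300L, n_sites = 5L,
                           positions = list(c(100L, 150L, 200L, 250L, 300L)))
  matches <- tibble::tibble(block_id = "a.B1", allele_id = "a",
                            donor_id = c("z_donor", "a_donor"),
                            shared_sites = c(5L, 5L), total_sites = 5L,
                            classification = "identical")
  rep1 <- chimera_report("a", blocks, matches,
                         roles = c(z_donor = "paralog", a_donor = "allele"))
  # tie: both listed, donor-id order
  expect_equal(rep1$blocks[[1]]$best_donors, c("a_donor", "z_donor"))
  expect_true(rep1$blocks[[1]]$paralog_derived)
  expect_equal(rep1$summary, "chimeric allele")
})

test_that("window-query sharing counts sites inside coordinate bounds", {
  anc <- strrep("A", 400)
  mk <- function(pos) {
    ch <- strsplit(anc, "")[[1]]; ch[pos] <- "G"; paste(ch, collapse = "")
  }
  allele <- mk(c(50, 120, 140, 160, 350))
  donor <- mk(c(120, 160))
  aln <- new_allele_alignment(c(consensus = anc, al = allele, D = donor),
                              "consensus")
  vt <- call_variants(aln, "al")
  w <- window_shared_sites(aln, vt, "al", 100, 200, "D")
  expect_equal(w$total_sites, 3L)
  expect_equal(w$shared_sites, 2L)
  expect_equal(w$positions, c(120L, 160L))
})

test_that("ploidy profile flags group-specific footprints and shared carriers", {
  # group B footprint carried by 3 of group B only -> specific
  vt <- dplyr::bind_rows(
    snp_table("b1", c(100, 150, 200)),
    snp_table("b2", c(100, 150, 200)),
    snp_table("b3", c(100, 150, 200)),
    snp_table("a1", c(2000, 2100, 2180)))
  groups <- c(b1 = "tetraploid", b2 = "tetraploid", b3 = "tetraploid",
              a1 = "hexaploid")
  prof <- ploidy_block_profile(vt, groups)
  fp_b <- prof[prof$start == 100, ]
  expect_equal(fp_b$status, "group_specific")
  expect_equal(fp_b$n_tetraploid, 3L)
  expect_equal(fp_b$n_hexaploid, 0L)

  # one hexaploid allele also carries it -> shared
  vt2 <- dplyr::bind_rows(vt, snp_table("a2", c(100, 150, 200)))
  groups2 <- c(groups, a2 = "hexaploid")
  prof2 <- ploidy_block_profile(vt2, groups2)
  fp_b2 <- prof2[prof2$start == 100, ]
  expect_equal(fp_b2$status, "shared")
  expect_true("a2" %in% fp_b2$carriers[[1]])

  # no variants at all -> empty profile
  empty <- ploidy_block_profile(snp_table("x", integer(0)), c(x = "hexaploid"))
  expect_equal(nrow(empty), 0L)
})
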