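make_template <- function(fwd, rev, inner_len, flank = 40) {
  # template: flank + fwd + inner + revcomp(rev) + flank
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  paste0(random_seq(flank), fwd, random_seq(inner_len), rc, random_seq(flank))
}

test_that("in-silico PCR finds the expected amplicon geometry", {
  set.seed(57)
  fwd <- random_seq(20); rev <- random_seq(20)
  inner <- 946 - 40   # amplicon includes both primer sites
  tpl <- make_template(fwd, rev, inner)
  assay <- marker_assay("sts", fwd, rev, expected_length = 946)
  expect_equal(insilico_pcr(tpl, assay), 946L)

  # reverse site absent -> no product
  tpl2 <- paste0(random_seq(40), fwd, random_seq(900))
  expect_true(is.na(insilico_pcr(tpl2, assay)))

  # amplicon far from the expected size -> rejected
  tpl3 <- make_template(fwd, rev, 400)
  expect_true(is.na(insilico_pcr(tpl3, assay)))
  expect_false(is.na(insilico_pcr(tpl3, marker_assay("sts2", fwd, rev, 440))))
})

test_that("primer mismatch tolerance is respected", {
  set.seed(58)
  fwd <- random_seq(20); rev <- random_seq(20)
  fwd_mut <- fwd
  substr(fwd_mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(fwd, 10, 10))[1]
  tpl <- make_template(fwd_mut, rev, 906)
  a0 <- marker_assay("m0", fwd, rev, 946, max_mismatches = 0)
  a1 <- marker_assay("m1", fwd, rev, 946, max_mismatches = 1)
  expect_true(is.na(insilico_pcr(tpl, a0)))
  expect_equal(insilico_pcr(tpl, a1), 946L)
  expect_error(insilico_pcr(tpl, list(forward = "", reverse = rev)),
               "malformed")
})

acc_record <- function(id, pheno1, haplotype = "present", hits = "",
                       seqstat = "untested", origin = "X") {
  rec <- tibble::tibble(id = id, origin = origin)
  for (iso in default_isolate_panel()) rec[[iso]] <- "S"
  rec[[default_isolate_panel()[1]]] <- pheno1
  rec$haplotype_marker <- haplotype
  rec$known_allele_hits <- hits
  rec$sequence_status <- seqstat
  rec
}

test_that("stage predicates encode the selection chain", {
  recs <- dplyr::bind_rows(
    acc_record("ir_only", "IR"),                       # stage4 yes, no candidate
    acc_record("with_pm3c", "R", hits = "Pm3c"),       # stage3 yes, stage4 no
    acc_record("susceptible", "S"),                    # fails stage2
    acc_record("full", "R", seqstat = "obtained"))     # passes everything
  out <- stage_filters(recs)
  ir <- out[out$id == "ir_only", ]
  expect_true(ir$stage4); expect_false(ir$stage5)
  pc <- out[out$id == "with_pm3c", ]
  expect_true(pc$stage3); expect_false(pc$stage4)
  expect_false(out$stage2[out$id == "susceptible"])
  expect_true(out$stage6[out$id == "full"])
})

test_that("funnel summary reproduces exact margins and stays monotone", {
  margins <- pm3_screen_margins()
  panel <- simulate_accession_panel(margins = margins)
  rep <- summarize_funnel(stage_filters(panel))
  tot <- rep[rep$origin == "Total", ]
  expect_equal(unlist(tot[paste0("stage", 1:6)], use.names = FALSE),
               c(733L, 154L, 109L, 81L, 51L, 41L))
  # per-country rows all reproduced
  for (i in seq_len(nrow(margins))) {
    got <- rep[rep$origin == margins$origin[i], paste0("stage", 1:6)]
    expect_equal(unlist(got, use.names = FALSE),
                 unlist(margins[i, paste0("stage", 1:6)], use.names = FALSE),
                 info = margins$origin[i])
  }
  # monotone along the funnel, totals = column sums
  counts <- as.matrix(rep[, paste0("stage", 1:6)])
  expect_true(all(counts[, -1] <= counts[, -6]))
  expect_equal(counts[nrow(counts), ],
               colSums(counts[-nrow(counts), , drop = FALSE]))
})

test_that("random panels keep funnel monotonicity and recount exactly", {
  set.seed(59)
  panel <- simulate_accession_panel(n = 200L,
                                    countries = c("A", "B", "C"))
  out <- stage_filters(panel)
  rep <- summarize_funnel(out)
  counts <- as.matrix(rep[, paste0("stage", 1:6)])
  expect_true(all(counts[, -1] <= counts[, -6]))
  # independent recount of the flags
  for (s in 1:6) {
    expect_equal(rep[[paste0("stage", s)]][rep$origin == "Total"],
                 sum(out[[paste0("stage", s)]]))
  }
})

test_that("inconsistent margins are rejected", {
  bad <- tibble::tibble(origin = "X", stage1 = 10L, stage2 = 11L,
                        stage3 = 5L, stage4 = 4L, stage5 = 2L, stage6 = 1L)
  expect_error(simulate_accession_panel(margins = bad), "non-increasing")
})

test_that("sequenced candidates are classified against consensus and known variants", {
  set.seed(60)
  cons <- random_seq(300)
  known <- mutate_seq(cons, 3)$seq
  novel <- mutate_seq(cons, 2)$seq
  panel <- c(gojho = known)
  expect_equal(classify_sequenced(cons, cons, panel), "consensus_identical")
  expect_equal(classify_sequenced(known, cons, panel),
               "known_susceptible_variant")
  expect_equal(classify_sequenced(novel, cons, panel), "novel")
  # one site off a panel entry is novel, not a known variant
  near <- known
  substr(near, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(near, 7, 7))[1]
  expect_equal(classify_sequenced(near, cons, panel), "novel")
})

test_that("accession TSV round-trips", {
  panel <- simulate_accession_panel(n = 20L, seed = 61)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_accessions_tsv(panel, f)
  back <- read_accessions_tsv(f)
  expect_equal(nrow(back), 20L)
  expect_equal(back$id, panel$id)
  expect_equal(back$haplotype_marker, panel$haplotype_marker)
  expect_equal(back$sequence_status, panel$sequence_status)
})
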