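#' Simulation configuration for synthetic allelic series
#'
#' Defaults emulate the structure of the modelled allelic series: a
#' 4442 bp gene (4242 bp CDS split by a 200 bp intron), alleles within
#' 97% identity of the ancestral consensus carrying sparse SNPs and
#' donor-copied conversion tracts, occasional frame-preserving 3 bp
#' indels, rare frame-disrupting deletions producing pseudogenes, and a
#' paralog pool diverged by 11.7-16.6% (83.4-88.3% identity).
#'
#' @param cds_length,intron_length,exon1_length Gene geometry in bp.
#' @param n_alleles Named integer vector of alleles per ploidy group
#'   (default 31 hexaploid + 23 tetraploid, the size of the modelled
#'   series).
#' @param n_paralogs Number of diverged paralogs in the donor pool.
#' @param snp_mean Mean of the Poisson SNP count per allele.
#' @param nonsynonymous_fraction Probability that an injected coding SNP
#'   is non-synonymous (default 0.72, matching a ~2.6 Ka:Ks count
#'   ratio).
#' @param conversion_prob Probability that an allele carries a
#'   conversion tract.
#' @param tract_mean Mean tract length in bp (geometric distribution).
#' @param paralog_donor_prob Probability that a tract donor is a paralog
#'   rather than another allele.
#' @param indel_prob Probability of a frame-preserving 3 bp indel per
#'   allele.
#' @param pseudogene_prob Probability of a pseudogene-generating
#'   deletion per allele.
#' @param pseudogene_deletion_size Size of that deletion (default
#'   302 bp, spanning the exon-1/intron boundary).
#' @param paralog_divergence Mismatch-fraction band of the paralogs.
#' @param shared_tract Optional list(`group`, `n_carriers`, `start`,
#'   `end`, `donor`) injecting one identical tract into `n_carriers`
#'   members of one ploidy group (emulates a ploidy-specific block).
#' @return A `sim_config` list.
#' @export
sim_config <- function(cds_length = 4242L, intron_length = 200L,
                       exon1_length = 2500L,
                       n_alleles = c(hexaploid = 31L, tetraploid = 23L),
                       n_paralogs = 3L,
                       snp_mean = 6,
                       nonsynonymous_fraction = 0.72,
                       conversion_prob = 0.5,
                       tract_mean = 300,
                       paralog_donor_prob = 0.25,
                       indel_prob = 0.1,
                       pseudogene_prob = 0.05,
                       pseudogene_deletion_size = 302L,
                       paralog_divergence = c(0.117, 0.166),
                       shared_tract = NULL) {
  if (cds_length %% 3L != 0L) stop("CDS length must be divisible by 3")
  probs <- c(nonsynonymous_fraction, conversion_prob, paralog_donor_prob,
             indel_prob, pseudogene_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (paralog_divergence[1] <= 0 || paralog_divergence[2] >= 1 ||
      paralog_divergence[1] > paralog_divergence[2]) {
    stop("paralog divergence band must be within (0, 1)")
  }
  structure(as.list(environment()), class = "sim_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate the ancestral reference sequence and its gene model
#'
#' Generates a random coding sequence with no in-frame stop codons
#' (first codon ATG) and inserts an intron with canonical GT...AG ends
#' at the configured exon junction.
#'
#' @param config A `sim_config`.
#' @param seed Optional RNG seed.
#' @return A list with `sequence` (genomic string), `cds`, and `model`
#'   (a `gene_model`).
#' @export
simulate_reference <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codons <- setdiff(names(GENETIC_CODE_TABLE), STOP_CODONS)
  n_codons <- config$cds_length %/% 3L
  cds <- paste(c("ATG", sample(codons, n_codons - 1L, replace = TRUE)),
               collapse = "")
  intron <- paste0("GT",
                   paste(sample(c("A", "C", "G", "T"),
                                config$intron_length - 4L, replace = TRUE),
                         collapse = ""),
                   "AG")
  seqn <- paste0(substr(cds, 1L, config$exon1_length), intron,
                 substr(cds, config$exon1_length + 1L, config$cds_length))
  model <- default_gene_model(config$exon1_length, config$intron_length,
                              config$cds_length)
  list(sequence = seqn, cds = cds, model = model)
}

#' Simulate a diverged paralog
#'
#' Substitutes a fraction of positions (drawn uniformly from the
#' configured divergence band) of the reference with random different
#' bases; the resulting identity lies inside the band by construction.
#'
#' @param reference Reference genomic sequence string.
#' @param config A `sim_config`.
#' @param id Sequence id.
#' @param seed Optional RNG seed.
#' @return A one-row allele-set tibble (`role = "paralog"`).
#' @export
simulate_paralog <- function(reference, config = sim_config(),
                             id = "paralog_1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(reference)
  band <- config$paralog_divergence
  div <- stats::runif(1, band[1], band[2])
  n_mut <- round(div * L)
  pos <- sample.int(L, n_mut)
  chars <- strsplit(reference, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  tibble::tibble(id = id, role = "paralog", ploidy_group = "unknown",
                 origin = NA_character_, bases = paste(chars, collapse = ""))
}

# Build an allele sequence from the reference and its truth record.
# Events are applied in a fixed order: tracts (donor copy), SNPs,
# indels (descending position). Shared by the simulator and by
# round-trip validation, so truth replay is exact by construction.
#' Reconstruct a simulated allele from the reference and its truth entry
#' @param reference Reference genomic sequence string.
#' @param truth_entry One allele's entry of the `truth` list returned by
#'   [simulate_allele_series()].
#' @param donor_seqs Named character vector of donor sequences (alleles
#'   and paralogs, ungapped, reference coordinates).
#' @return The allele sequence string.
#' @export
build_allele_sequence <- function(reference, truth_entry, donor_seqs) {
  chars <- strsplit(reference, "")[[1]]
  tr <- truth_entry$tracts
  for (i in seq_len(nrow(tr))) {
    d <- strsplit(donor_seqs[[tr$donor[i]]], "")[[1]]
    idx <- tr$start[i]:tr$end[i]
    chars[idx] <- d[idx]
  }
  sn <- truth_entry$snps
  for (i in seq_len(nrow(sn))) chars[sn$pos[i]] <- sn$alt[i]
  s <- paste(chars, collapse = "")
  ind <- truth_entry$indels
  if (nrow(ind) > 0L) {
    ind <- ind[order(ind$pos, decreasing = TRUE), ]
    for (i in seq_len(nrow(ind))) {
      if (ind$kind[i] == "insertion") {
        s <- paste0(substr(s, 1L, ind$pos[i]), ind$seq[i],
                    substr(s, ind$pos[i] + 1L, nchar(s)))
      } else {
        s <- paste0(substr(s, 1L, ind$pos[i] - 1L),
                    substr(s, ind$pos[i] + ind$len[i], nchar(s)))
      }
    }
  }
  s
}

sample_coding_snp <- function(reference, model, cds, want_nonsyn, exclude) {
  for (try in 1:100) {
    cpos <- sample.int(model$cds_length, 1L)
    rpos <- cds_to_ref(cpos, model)
    if (rpos %in% exclude) next
    refbase <- substr(reference, rpos, rpos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refbase), 1L)
    ci <- codon_at(cpos)
    codon <- substr(cds, (ci$codon_index - 1L) * 3L + 1L, ci$codon_index * 3L)
    mutant <- codon
    substr(mutant, ci$offset, ci$offset) <- alt
    is_nonsyn <- translate_codon(mutant) != translate_codon(codon)
    if (is_nonsyn == want_nonsyn) {
      return(list(pos = rpos, ref = refbase, alt = alt,
                  effect = if (is_nonsyn) "nonsynonymous" else "synonymous"))
    }
  }
  NULL
}

#' Simulate an allelic series with known ground truth
#'
#' Each allele starts from the reference, optionally receives
#' donor-copied conversion tracts, then sparse coding SNPs (biased to
#' non-synonymous changes per the configured fraction), then optional
#' frame-preserving 3 bp indels, and with small probability a
#' frame-disrupting deletion spanning the exon-1/intron boundary
#' (pseudogene). Later SNPs never overlap tract intervals, so injected
#' SNP counts and tract footprints are independently recoverable.
#'
#' @param reference Output of [simulate_reference()].
#' @param paralogs Allele-set tibble of paralogs (possibly 0-row).
#' @param config A `sim_config`.
#' @param seed Optional RNG seed.
#' @return A list: `sequences` (allele-set tibble of alleles +
#'   paralogs), `truth` (per-allele list with `snps`, `tracts`,
#'   `indels` tibbles and `pseudogene` flag), `reference`, `config`.
#' @export
simulate_allele_series <- function(reference, paralogs = NULL,
                                   config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(paralogs)) {
    paralogs <- tibble::tibble(id = character(0), role = character(0),
                               ploidy_group = character(0),
                               origin = character(0), bases = character(0))
  }
  refseq <- reference$sequence
  model <- reference$model
  L <- nchar(refseq)
  groups <- rep(names(config$n_alleles), config$n_alleles)
  ids <- unlist(lapply(names(config$n_alleles), function(g) {
    paste0(substr(g, 1, 3), "_allele_",
           seq_len(config$n_alleles[[g]]))
  }))
  truth <- list()
  seqs <- character(length(ids))
  donor_seqs <- stats::setNames(paralogs$bases, paralogs$id)
  # running per-column count of alleles carrying a non-ancestral base
  # (tract spans and SNPs): random tracts and SNPs are placed so that no
  # column accumulates carriers in half or more of the panel, keeping the
  # majority consensus equal to the ancestral state by construction (an
  # explicitly configured shared_tract is exempt but still counted)
  n_total <- length(ids)
  cover <- integer(L)
  max_carriers <- max((ceiling(n_total / 2) - 1L), 1L)
  # donor alleles are drawn after their own simulation round; to keep the
  # ground truth replayable we draw allele donors only from paralogs and
  # previously simulated alleles
  shared <- config$shared_tract
  shared_assigned <- 0L
  for (k in seq_along(ids)) {
    id <- ids[k]
    tracts <- tibble::tibble(donor = character(0), start = integer(0),
                             end = integer(0))
    # ploidy-specific shared tract
    if (!is.null(shared) && groups[k] == shared$group &&
        shared_assigned < shared$n_carriers) {
      tracts <- dplyr::bind_rows(tracts, tibble::tibble(
        donor = shared$donor, start = as.integer(shared$start),
        end = as.integer(shared$end)))
      shared_assigned <- shared_assigned + 1L
      cover[shared$start:shared$end] <- cover[shared$start:shared$end] + 1L
    }
    if (stats::runif(1) < config$conversion_prob && length(donor_seqs) > 0L) {
      # cap so a paralog-derived tract cannot push the allele below the
      # 97% identity floor of the series
      max_tract <- floor(0.025 * L / config$paralog_divergence[2L])
      len <- min(stats::rgeom(1L, 1 / config$tract_mean) + 1L, max_tract)
      use_paralog <- stats::runif(1) < config$paralog_donor_prob
      pool <- if (use_paralog) paralogs$id else setdiff(names(donor_seqs),
                                                        paralogs$id)
      if (length(pool) == 0L) pool <- names(donor_seqs)
      donor <- sample(pool, 1L)
      for (try in 1:20) {
        start <- sample.int(L - len, 1L)
        span <- start:(start + len - 1L)
        if (max(cover[span]) + 1L > max_carriers) next
        cand <- tibble::tibble(donor = donor, start = as.integer(start),
                               end = as.integer(start + len - 1L))
        # avoid overlap with an already assigned tract of this allele
        if (nrow(tracts) == 0L ||
            all(cand$end < tracts$start | cand$start > tracts$end)) {
          tracts <- dplyr::bind_rows(tracts, cand)
          cover[span] <- cover[span] + 1L
        }
        break
      }
    }
    tract_pos <- unlist(lapply(seq_len(nrow(tracts)), function(i) {
      tracts$start[i]:tracts$end[i]
    }))
    # indels and the pseudogene deletion are placed before SNP sampling so
    # that no SNP falls inside a deleted span (ground truth stays fully
    # recoverable from the sequence)
    indels <- tibble::tibble(kind = character(0), pos = integer(0),
                             len = integer(0), seq = character(0))
    pseudogene <- FALSE
    if (stats::runif(1) < config$pseudogene_prob) {
      pseudogene <- TRUE
      size <- config$pseudogene_deletion_size
      start <- model$exons[1, "end"] - size %/% 2L
      indels <- dplyr::bind_rows(indels, tibble::tibble(
        kind = "deletion", pos = as.integer(start), len = as.integer(size),
        seq = substr(refseq, start, start + size - 1L)))
    } else if (stats::runif(1) < config$indel_prob) {
      # frame-preserving 3 bp event inside the CDS, clear of tracts
      cpos <- sample.int(model$cds_length - 3L, 1L)
      rpos <- cds_to_ref(cpos, model)
      if (!rpos %in% tract_pos) {
        if (stats::runif(1) < 0.5) {
          indels <- dplyr::bind_rows(indels, tibble::tibble(
            kind = "insertion", pos = as.integer(rpos), len = 3L,
            seq = paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                        collapse = "")))
        } else if (rpos + 2L <= model$exons[1, "end"] ||
                   rpos >= model$exons[2, "start"]) {
          indels <- dplyr::bind_rows(indels, tibble::tibble(
            kind = "deletion", pos = as.integer(rpos), len = 3L,
            seq = substr(refseq, rpos, rpos + 2L)))
        }
      }
    }
    deleted_pos <- unlist(lapply(which(indels$kind == "deletion"),
                                 function(i) {
                                   indels$pos[i]:(indels$pos[i] +
                                                    indels$len[i] - 1L)
                                 }))
    n_snp <- stats::rpois(1L, config$snp_mean)
    snps <- list()
    saturated <- which(cover >= max_carriers)
    taken <- c(tract_pos, deleted_pos, indels$pos, saturated)
    for (s in seq_len(n_snp)) {
      want_nonsyn <- stats::runif(1) < config$nonsynonymous_fraction
      snp <- sample_coding_snp(refseq, model, reference$cds, want_nonsyn,
                               taken)
      if (!is.null(snp)) {
        snps[[length(snps) + 1L]] <- tibble::as_tibble(snp)
        taken <- c(taken, snp$pos)
        cover[snp$pos] <- cover[snp$pos] + 1L
      }
    }
    snps <- if (length(snps)) dplyr::bind_rows(snps) else {
      tibble::tibble(pos = integer(0), ref = character(0),
                     alt = character(0), effect = character(0))
    }
    entry <- list(allele_id = id, ploidy_group = groups[k], snps = snps,
                  tracts = tracts, indels = indels, pseudogene = pseudogene)
    seqs[k] <- build_allele_sequence(refseq, entry, donor_seqs)
    truth[[id]] <- entry
    donor_seqs[[id]] <- build_allele_sequence(
      refseq, list(snps = snps, tracts = tracts,
                   indels = indels[0, ]), donor_seqs)   # pre-indel coordinates
  }
  sequences <- dplyr::bind_rows(
    tibble::tibble(id = ids, role = "allele", ploidy_group = groups,
                   origin = NA_character_, bases = seqs),
    paralogs)
  list(sequences = sequences, truth = truth, reference = reference,
       donor_seqs = donor_seqs, config = config)
}

#' Simulate an accession panel, optionally matching exact funnel margins
#'
#' In exact mode, per-country stage margins (non-increasing counts for
#' the six funnel stages) are converted into individual accession
#' records whose stage flags aggregate back to the requested margins:
#' records dropping at stage 2 are susceptible to all isolates, at
#' stage 3 lack the haplotype marker, at stage 4 carry a known
#' resistance allele (drawn from `known_allele_counts`), at stage 5 are
#' only intermediately resistant, at stage 6 failed sequencing. In
#' random mode, records pass each stage independently with the given
#' probabilities.
#'
#' @param margins Margins tibble (`origin`, `stage1` ... `stage6`), e.g.
#'   [pm3_screen_margins()]; `NULL` for random mode.
#' @param known_allele_counts Named integer vector distributing known
#'   alleles over the stage-3-to-4 drop (default
#'   [pm3_known_allele_counts()] scaled to the drop size).
#' @param n,countries,stage_probs Random mode: panel size, country pool,
#'   per-stage pass probabilities (stages 2-6).
#' @param isolates Isolate panel (phenotype column names).
#' @param seed Optional RNG seed.
#' @return An accession tibble suitable for [stage_filters()].
#' @export
simulate_accession_panel <- function(margins = NULL,
                                     known_allele_counts =
                                       pm3_known_allele_counts(),
                                     n = 100L,
                                     countries = c("CountryA", "CountryB"),
                                     stage_probs = c(0.2, 0.7, 0.75,
                                                     0.65, 0.8),
                                     isolates = default_isolate_panel(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(margins)) {
    origin <- sample(countries, n, replace = TRUE)
    pass <- matrix(TRUE, n, 6L)
    for (s in 2:6) {
      pass[, s] <- pass[, s - 1L] & stats::runif(n) < stage_probs[s - 1L]
    }
    recs <- make_accessions(origin, pass, known_allele_counts, isolates)
    return(recs)
  }
  needed <- paste0("stage", 1:6)
  if (!all(needed %in% names(margins))) {
    stop("margins must have columns origin, stage1..stage6")
  }
  m <- as.matrix(margins[, needed])
  if (any(m[, -1L] > m[, -6L])) {
    stop("inconsistent margins: stage counts must be non-increasing")
  }
  pass <- NULL; origin <- character(0)
  for (i in seq_len(nrow(margins))) {
    ni <- m[i, 1L]
    p <- matrix(FALSE, ni, 6L)
    for (s in 1:6) if (m[i, s] > 0L) p[seq_len(m[i, s]), s] <- TRUE
    pass <- rbind(pass, p)
    origin <- c(origin, rep(margins$origin[i], ni))
  }
  make_accessions(origin, pass, known_allele_counts, isolates)
}

make_accessions <- function(origin, pass, known_allele_counts, isolates) {
  n <- length(origin)
  recs <- tibble::tibble(id = sprintf("ACC%04d", seq_len(n)), origin = origin)
  for (iso in isolates) recs[[iso]] <- "S"
  # phenotype: stage2 requires R or IR; stage5 requires full R
  recs[[isolates[1L]]][pass[, 2L] & pass[, 5L]] <- "R"
  recs[[isolates[1L]]][pass[, 2L] & !pass[, 5L] & pass[, 4L]] <- "IR"
  # records failing stage 4 (known allele) or stage 3 were resistant too
  recs[[isolates[1L]]][pass[, 2L] & !pass[, 4L]] <- "R"
  recs$haplotype_marker <- ifelse(pass[, 3L], "present",
                                  ifelse(pass[, 2L], "absent", "untested"))
  hits <- rep("", n)
  dropped4 <- which(pass[, 3L] & !pass[, 4L])
  if (length(dropped4)) {
    pool <- rep(names(known_allele_counts), known_allele_counts)
    pool <- rep(pool, length.out = length(dropped4))
    hits[dropped4] <- pool
  }
  recs$known_allele_hits <- hits
  recs$sequence_status <- ifelse(pass[, 6L], "obtained",
                                 ifelse(pass[, 5L], "failed", "untested"))
  recs
}
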