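#' Run the full allele-characterization pipeline
#'
#' Orchestrates the stages in screening order: align the allele set,
#' build the consensus, call and annotate variants, flag pseudogenes,
#' segment polymorphic blocks and attribute donors, summarize diversity
#' per domain and ploidy group, and (when an accession table is given)
#' summarize the screening funnel. All outputs are deterministic given
#' the inputs.
#'
#' @param sequences Allele-set tibble (see [read_allele_fasta()]) or a
#'   path to a FASTA file.
#' @param gene_model A `gene_model` (default [default_gene_model()]).
#' @param domain_map Domain map tibble (default [default_domain_map()]).
#' @param accessions Optional accession tibble or TSV path.
#' @param out_dir Optional output directory; when given, the report
#'   bundle is written there (alignment FASTA, variants TSV + VCF,
#'   blocks TSV, chimera JSON, diversity TSV, funnel TSV, manifest
#'   JSON).
#' @param block_params List with `min_sites`, `max_gap`,
#'   `partial_threshold`.
#' @param align_params Alignment scoring parameters (see
#'   [align_near_identical()]).
#' @param isolates Isolate panel for the funnel stage.
#' @param with_diversity Compute the per-region diversity summary
#'   (default `TRUE`; variant/block-only runs can skip it).
#' @return A report bundle list: `alignment`, `consensus`, `variants`,
#'   `pseudogenes`, `blocks`, `matches`, `chimera_reports`,
#'   `diversity`, `funnel` (or `NULL`).
#' @export
run_pipeline <- function(sequences, gene_model = default_gene_model(),
                         domain_map = default_domain_map(),
                         accessions = NULL, out_dir = NULL,
                         block_params = list(min_sites = 3L, max_gap = 250L,
                                             partial_threshold = 0.4),
                         align_params = list(match = 1, mismatch = -2,
                                             gap_open = -8, gap_extend = -1),
                         isolates = default_isolate_panel(),
                         with_diversity = TRUE) {
  if (is.character(sequences) && length(sequences) == 1L) {
    sequences <- read_allele_fasta(sequences)
  }
  # two passes: consensus is estimated from a first-round alignment, then
  # every sequence is re-aligned against the ungapped consensus so that
  # coordinates and gap placement are consensus-anchored (a first-round
  # backbone carrying a divergent conversion tract would otherwise leak
  # its own gap artifacts into every row)
  aln1 <- align_near_identical(sequences, params = align_params)
  prof <- build_consensus(aln1, include_roles = "allele")
  consensus_seq <- gsub("-", "", prof$consensus, fixed = TRUE)
  seqs2 <- dplyr::bind_rows(
    tibble::tibble(id = "consensus", role = "reference",
                   ploidy_group = "unknown", origin = NA_character_,
                   bases = consensus_seq),
    sequences)
  caln <- align_near_identical(seqs2, params = align_params,
                               ref_id = "consensus")

  allele_ids <- sequences$id[sequences$role == "allele"]
  variants <- call_all_variants(caln, ids = allele_ids,
                                gene_model = gene_model,
                                domain_map = domain_map)
  pseudo <- tibble::tibble(
    allele_id = allele_ids,
    pseudogene = vapply(allele_ids, function(id) {
      flag_pseudogene(variants[variants$allele_id == id, ],
                      gene_model)$pseudogene
    }, logical(1)))

  roles <- stats::setNames(caln$meta$role, caln$meta$id)
  blocks <- list(); matches <- list(); reports <- list()
  for (id in allele_ids) {
    seg <- segment_blocks(variants, id, block_params$min_sites,
                          block_params$max_gap)
    blocks[[id]] <- seg$blocks
    bm <- lapply(seq_len(nrow(seg$blocks)), function(i) {
      match_block(seg$blocks[i, ], caln, variants,
                  partial_threshold = block_params$partial_threshold)
    })
    matches[[id]] <- if (length(bm)) dplyr::bind_rows(bm) else NULL
    reports[[id]] <- chimera_report(id, seg$blocks,
                                    matches[[id]], roles = roles)
  }
  blocks <- dplyr::bind_rows(blocks)
  matches <- dplyr::bind_rows(matches)

  ok_ids <- pseudo$allele_id[!pseudo$pseudogene]
  groups <- stats::setNames(sequences$ploidy_group[match(ok_ids, sequences$id)],
                            ok_ids)
  groups <- groups[groups %in% c("hexaploid", "tetraploid")]
  diversity <- if (with_diversity && length(groups) >= 2L) {
    summarize_diversity(caln, gene_model, domain_map, groups)
  } else {
    NULL
  }

  funnel <- NULL
  if (!is.null(accessions)) {
    if (is.character(accessions)) accessions <- read_accessions_tsv(accessions)
    funnel <- summarize_funnel(stage_filters(accessions, isolates))
  }

  bundle <- list(alignment = caln, consensus = consensus_seq,
                 variants = variants, pseudogenes = pseudo, blocks = blocks,
                 matches = matches, chimera_reports = reports,
                 diversity = diversity, funnel = funnel)
  if (!is.null(out_dir)) render_reports(bundle, out_dir)
  bundle
}

#' Write a pipeline report bundle to disk
#'
#' @param bundle Bundle from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @param format `"tsv"` (always written) or `"json"` (additionally
#'   writes the diversity and funnel tables as JSON with identical
#'   numbers).
#' @return Named character vector of the files written, invisibly.
#' @export
render_reports <- function(bundle, out_dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- function(f) file.path(out_dir, f)

  write_allele_fasta(bundle$alignment$rows, p("alignment.fasta"))
  files["alignment"] <- p("alignment.fasta")
  write_variants_tsv(bundle$variants, p("variants.tsv"))
  files["variants_tsv"] <- p("variants.tsv")
  write_variants_vcf(bundle$variants, bundle$consensus, p("variants.vcf"))
  files["variants_vcf"] <- p("variants.vcf")
  write_blocks_tsv(bundle$blocks, p("blocks.tsv"))
  files["blocks"] <- p("blocks.tsv")
  utils::write.table(bundle$matches, p("block_matches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files["matches"] <- p("block_matches.tsv")
  jsonlite::write_json(bundle$chimera_reports, p("chimera_reports.json"),
                       auto_unbox = TRUE, digits = NA)
  files["chimera"] <- p("chimera_reports.json")
  if (!is.null(bundle$diversity)) {
    write_diversity_tsv(bundle$diversity, p("diversity.tsv"))
    files["diversity"] <- p("diversity.tsv")
    if (format == "json") {
      jsonlite::write_json(bundle$diversity, p("diversity.json"),
                           auto_unbox = TRUE, digits = NA)
      files["diversity_json"] <- p("diversity.json")
    }
  }
  if (!is.null(bundle$funnel)) {
    utils::write.table(bundle$funnel, p("funnel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files["funnel"] <- p("funnel.tsv")
    if (format == "json") {
      jsonlite::write_json(bundle$funnel, p("funnel.json"),
                           auto_unbox = TRUE, digits = NA)
      files["funnel_json"] <- p("funnel.json")
    }
  }
  manifest <- list(package = "allelemine",
                   version = as.character(utils::packageVersion("allelemine")),
                   n_rows = length(bundle$alignment$rows),
                   n_variants = nrow(bundle$variants),
                   written = as.list(files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  files["manifest"] <- p("manifest.json")
  invisible(files)
}
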