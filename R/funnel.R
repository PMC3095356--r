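#' Default powdery-mildew isolate panel
#'
#' Column names used for per-isolate phenotypes in accession tables.
#' The panel mirrors a six-isolate differential set chosen for its
#' avirulence/virulence pattern on the known resistance alleles.
#' @return Character vector of isolate column names.
#' @export
default_isolate_panel <- function() {
  c("Bgt_98275", "Bgt_Syros_2000_15", "Bgt_96224",
    "Bgt_97011", "Bgt_96229", "Bgt_DB_Asosan")
}

#' In-silico PCR: predict an amplicon from a primer pair
#'
#' Searches the plus strand for the forward primer and, downstream of
#' it, for the reverse complement of the reverse primer, each with at
#' most `max_mismatches` mismatches. The amplicon length is measured
#' from the 5' end of the forward match to the 3' end of the reverse
#' match, inclusive. Returns `NA` when either site is absent or the
#' length falls outside `expected_length +/- length_tolerance` (no
#' check when `expected_length` is `NULL`).
#'
#' @param sequence Template sequence over `{A,C,G,T,N}`.
#' @param assay A list (or `marker_assay()`) with `forward`, `reverse`,
#'   `expected_length`, `max_mismatches`.
#' @param length_tolerance Allowed deviation from the expected length in
#'   bp (default 50).
#' @return Integer amplicon length, or `NA_integer_`.
#' @export
insilico_pcr <- function(sequence, assay, length_tolerance = 50L) {
  for (p in c("forward", "reverse")) {
    if (is.null(assay[[p]]) || nchar(assay[[p]]) == 0L ||
        grepl("[^ACGTN]", assay[[p]])) {
      stop("malformed ", p, " primer")
    }
  }
  mm <- if (is.null(assay$max_mismatches)) 0L else assay$max_mismatches
  subj <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(assay$forward), subj,
                                  max.mismatch = mm)
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(assay$reverse))
  rev <- Biostrings::matchPattern(rc, subj, max.mismatch = mm)
  if (length(fwd) == 0L || length(rev) == 0L) return(NA_integer_)
  best <- NA_integer_
  for (i in seq_along(fwd)) {
    s <- Biostrings::start(fwd)[i]
    ends <- Biostrings::end(rev)
    ends <- ends[ends >= s + nchar(assay$forward) + nchar(assay$reverse) - 1L]
    if (length(ends) == 0L) next
    amp <- min(ends) - s + 1L
    if (is.na(best) || amp < best) best <- amp
  }
  if (is.na(best)) return(NA_integer_)
  if (!is.null(assay$expected_length) &&
      abs(best - assay$expected_length) > length_tolerance) {
    return(NA_integer_)
  }
  as.integer(best)
}

#' Construct a marker assay description
#' @param name Assay name.
#' @param forward,reverse Primer sequences (plus-strand forward primer
#'   and the reverse primer as conventionally given, i.e. reverse
#'   complement of the plus strand).
#' @param expected_length Expected amplicon length in bp.
#' @param max_mismatches Mismatches tolerated per primer site.
#' @return A `marker_assay` list.
#' @export
marker_assay <- function(name, forward, reverse, expected_length,
                         max_mismatches = 0L) {
  if (expected_length <= nchar(forward) + nchar(reverse)) {
    stop("expected amplicon length must exceed the combined primer length")
  }
  structure(list(name = name, forward = toupper(forward),
                 reverse = toupper(reverse),
                 expected_length = as.integer(expected_length),
                 max_mismatches = as.integer(max_mismatches)),
            class = "marker_assay")
}

#' Apply the screening-funnel stage predicates to an accession table
#'
#' Stages, applied cumulatively:
#' 1. all accessions;
#' 2. resistant (R) or intermediately resistant (IR) to at least one
#'    panel isolate;
#' 3. haplotype marker present;
#' 4. none of the known resistance alleles detected;
#' 5. candidate: fully resistant (R, not merely IR) to at least one
#'    isolate — intermediate-resistant lines are dropped here;
#' 6. coding sequence obtained.
#'
#' @param records Accession tibble with columns `id`, `origin`, one
#'   phenotype column per isolate (values in `{R, IR, IS, S}`),
#'   `haplotype_marker` (`present`/`absent`/`untested`),
#'   `known_allele_hits` (comma-separated allele names, `""` for none)
#'   and `sequence_status` (`obtained`/`failed`/`untested`).
#' @param isolates Phenotype column names (default
#'   [default_isolate_panel()]).
#' @return `records` with logical columns `stage1` ... `stage6` added;
#'   records with missing phenotypes are dropped with a warning.
#' @export
stage_filters <- function(records, isolates = default_isolate_panel()) {
  missing_cols <- setdiff(isolates, names(records))
  if (length(missing_cols)) {
    stop("missing phenotype column(s): ", paste(missing_cols, collapse = ", "))
  }
  ph <- as.matrix(records[, isolates])
  ok <- apply(ph, 1, function(r) all(r %in% c("R", "IR", "IS", "S")))
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with missing/invalid phenotypes excluded")
    records <- records[ok, ]
    ph <- ph[ok, , drop = FALSE]
  }
  any_r_ir <- apply(ph, 1, function(r) any(r %in% c("R", "IR")))
  any_r <- apply(ph, 1, function(r) any(r == "R"))
  hits <- ifelse(is.na(records$known_allele_hits), "",
                 records$known_allele_hits)
  records$stage1 <- TRUE
  records$stage2 <- any_r_ir
  records$stage3 <- records$stage2 & records$haplotype_marker == "present"
  records$stage4 <- records$stage3 & hits == ""
  records$stage5 <- records$stage4 & any_r
  records$stage6 <- records$stage5 & records$sequence_status == "obtained"
  records
}

#' Summarize the screening funnel per country of origin
#'
#' @param records Accession tibble with stage flags (see
#'   [stage_filters()]).
#' @return A `funnel_report` tibble: one row per country with the six
#'   stage counts, plus a `Total` row; stage counts are non-increasing
#'   along the funnel by construction.
#' @export
summarize_funnel <- function(records) {
  stage_cols <- paste0("stage", 1:6)
  if (!all(stage_cols %in% names(records))) {
    stop("records lack stage flags; run stage_filters() first")
  }
  if (nrow(records) == 0L) {
    out <- tibble::tibble(origin = "Total")
    for (s in stage_cols) out[[s]] <- 0L
    return(out)
  }
  per <- dplyr::summarise(
    dplyr::group_by(records, origin),
    dplyr::across(dplyr::all_of(stage_cols), ~ sum(.x)),
    .groups = "drop")
  per <- per[order(-per$stage1, per$origin), ]
  tot <- tibble::tibble(origin = "Total")
  for (s in stage_cols) tot[[s]] <- sum(per[[s]])
  dplyr::bind_rows(per, tot)
}

#' Classify a sequenced candidate against the consensus and known variants
#'
#' @param allele_sequence Sequence string of the cloned candidate.
#' @param consensus Consensus (susceptible ancestral) sequence string.
#' @param known_variant_panel Named character vector of known
#'   susceptible variant sequences.
#' @return One of `"consensus_identical"`,
#'   `"known_susceptible_variant"`, `"novel"`.
#' @export
classify_sequenced <- function(allele_sequence, consensus,
                               known_variant_panel = character(0)) {
  if (identical(allele_sequence, consensus)) return("consensus_identical")
  if (length(known_variant_panel) &&
      any(vapply(known_variant_panel, identical, logical(1),
                 x = allele_sequence))) {
    return("known_susceptible_variant")
  }
  "novel"
}

#' Read/write accession tables
#'
#' The accession TSV schema: `id`, `origin`, one column per panel
#' isolate with phenotype in `{R, IR, IS, S}`, `haplotype_marker`,
#' `known_allele_hits`, `sequence_status`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_accessions_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                      na.strings = "NA"))
}

#' @rdname read_accessions_tsv
#' @param records Accession tibble.
#' @export
write_accessions_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
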