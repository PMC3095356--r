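GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_TABLE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Call consensus-relative variants for one allele
#'
#' Compares an allele row to the reference (consensus) row of a shared
#' alignment and emits one record per mismatching column (SNP) and per
#' maximal gap run (insertion/deletion). Positions are 1-based reference
#' coordinates; insertions are anchored after the preceding reference
#' position (0 = before the first base) and indels are left-aligned
#' against the reference. `N` in the allele produces no call.
#'
#' @param alignment An `allele_alignment` whose reference row is the
#'   consensus (see [add_consensus()]).
#' @param allele_id Row to call variants for.
#' @param ref_id Reference row; defaults to the alignment's.
#' @return A tibble with columns `allele_id`, `ref_pos`, `kind`
#'   (`"SNP"`, `"insertion"`, `"deletion"`), `ref`, `alt`, sorted by
#'   position.
#' @export
call_variants <- function(alignment, allele_id, ref_id = alignment$ref_id) {
  if (!allele_id %in% names(alignment$rows)) {
    stop("unknown allele id: ", allele_id)
  }
  ref <- strsplit(alignment$rows[[ref_id]], "")[[1]]
  alle <- strsplit(alignment$rows[[allele_id]], "")[[1]]
  maps <- if (identical(ref_id, alignment$ref_id)) {
    alignment
  } else {
    column_maps(alignment, ref_id)
  }
  refpos <- maps$col_to_refpos
  refseq <- gsub("-", "", paste(ref, collapse = ""), fixed = TRUE)

  snp_col <- ref != "-" & alle != "-" & ref != alle & alle != "N" & ref != "N"
  snp_pos <- refpos[snp_col]
  snp_ref <- ref[snp_col]
  snp_alt <- alle[snp_col]

  # maximal deletion runs: consecutive reference positions gapped in the
  # allele (insertion columns in between do not break a run)
  del_runs <- list()
  del_col <- ref != "-" & alle == "-"
  if (any(del_col)) {
    dp <- refpos[del_col]
    grp <- cumsum(c(1L, diff(dp) > 1L))
    del_runs <- lapply(split(dp, grp), function(v) c(v[1L], v[length(v)]))
  }
  # insertion runs grouped by their anchoring reference position
  ins_runs <- list()
  ins_col <- ref == "-" & alle != "-" & alle != "N"
  if (any(ins_col)) {
    ia <- refpos[ins_col]
    pieces <- split(alle[ins_col], ia)
    ins_runs <- lapply(names(pieces), function(a) {
      list(anchor = as.integer(a),
           string = paste(pieces[[a]], collapse = ""))
    })
  }

  # an equal-length deletion and insertion that are immediately adjacent
  # are a run of substitutions, not an indel pair (alignment artifact of
  # divergent segments); re-express them as SNPs
  if (length(del_runs) && length(ins_runs)) {
    drop_del <- logical(length(del_runs))
    drop_ins <- logical(length(ins_runs))
    for (di in seq_along(del_runs)) {
      s <- del_runs[[di]][1]; e <- del_runs[[di]][2]
      len <- e - s + 1L
      for (ii in seq_along(ins_runs)) {
        if (drop_ins[ii]) next
        anc <- ins_runs[[ii]]$anchor
        str <- ins_runs[[ii]]$string
        if (nchar(str) == len && (anc == e || anc == s - 1L)) {
          ins_chars <- strsplit(str, "")[[1]]
          for (off in seq_len(len)) {
            rp <- s + off - 1L
            rb <- substr(refseq, rp, rp)
            if (ins_chars[off] != rb && ins_chars[off] != "N") {
              snp_pos <- c(snp_pos, rp)
              snp_ref <- c(snp_ref, rb)
              snp_alt <- c(snp_alt, ins_chars[off])
            }
          }
          drop_del[di] <- TRUE; drop_ins[ii] <- TRUE
          break
        }
      }
    }
    del_runs <- del_runs[!drop_del]
    ins_runs <- ins_runs[!drop_ins]
  }

  recs <- list()
  if (length(snp_pos)) {
    recs[[1L]] <- tibble::tibble(ref_pos = snp_pos, kind = "SNP",
                                 ref = snp_ref, alt = snp_alt)
  }
  for (d in del_runs) {
    s <- d[1]; e <- d[2]
    # left-align against the reference
    while (s > 1L && substr(refseq, s - 1L, s - 1L) == substr(refseq, e, e)) {
      s <- s - 1L; e <- e - 1L
    }
    recs[[length(recs) + 1L]] <- tibble::tibble(
      ref_pos = as.integer(s), kind = "deletion",
      ref = substr(refseq, s, e), alt = "")
  }
  for (i in ins_runs) {
    p <- i$anchor; str <- i$string; len <- nchar(str)
    while (p >= 1L && substr(refseq, p, p) == substr(str, len, len)) {
      str <- paste0(substr(refseq, p, p), substr(str, 1L, len - 1L))
      p <- p - 1L
    }
    recs[[length(recs) + 1L]] <- tibble::tibble(
      ref_pos = as.integer(p), kind = "insertion", ref = "", alt = str)
  }
  out <- if (length(recs)) dplyr::bind_rows(recs) else {
    tibble::tibble(ref_pos = integer(0), kind = character(0),
                   ref = character(0), alt = character(0))
  }
  out <- dplyr::arrange(out, ref_pos, kind)
  dplyr::bind_cols(tibble::tibble(allele_id = rep(allele_id, nrow(out))), out)
}

#' Call variants for every non-reference row of an alignment
#'
#' @inheritParams call_variants
#' @param ids Rows to call (default: all rows except the reference).
#' @param gene_model,domain_map If supplied, records are annotated with
#'   region, coding effect and domain (see [classify_effect()]).
#' @return A variant table tibble sorted by `(allele_id, ref_pos)`.
#' @export
call_all_variants <- function(alignment, ids = NULL, gene_model = NULL,
                              domain_map = NULL) {
  if (is.null(ids)) ids <- setdiff(names(alignment$rows), alignment$ref_id)
  tabs <- lapply(sort(ids), function(id) call_variants(alignment, id))
  vt <- dplyr::bind_rows(tabs)
  if (!is.null(gene_model)) {
    vt <- annotate_variants(vt, gene_model, domain_map,
                            degap_row(alignment, alignment$ref_id))
  }
  vt
}

#' Classify the coding effect of a single variant record
#'
#' A SNP inside the CDS is substituted into the consensus codon (the
#' other two codon positions kept at the consensus state) and the
#' translated amino acids compared; an indel inside the CDS is
#' frame-preserving iff the length of its CDS overlap is a multiple of 3.
#'
#' @param record One variant record (a one-row data frame or list with
#'   `ref_pos`, `kind`, `ref`, `alt`).
#' @param gene_model A `gene_model`.
#' @param consensus Ungapped consensus (reference) sequence string.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"intronic"`,
#'   `"frame_preserving_indel"`, `"frame_disrupting"`,
#'   `"not_applicable"`.
#' @export
classify_effect <- function(record, gene_model, consensus) {
  kind <- record$kind
  pos <- record$ref_pos
  if (kind == "SNP") {
    reg <- region_of(pos, gene_model)
    if (reg == "intronic") return("intronic")
    if (reg == "noncoding") return("not_applicable")
    if (is.null(consensus) || nchar(consensus) < gene_model$span[2]) {
      # reference shorter than the model span: no codon context available
      return("not_applicable")
    }
    cds <- splice_cds(consensus, gene_model)
    cpos <- ref_to_cds(pos, gene_model)
    ci <- codon_at(cpos)
    codon <- substr(cds, (ci$codon_index - 1L) * 3L + 1L, ci$codon_index * 3L)
    mutant <- codon
    substr(mutant, ci$offset, ci$offset) <- record$alt
    if (is.na(translate_codon(mutant)) || is.na(translate_codon(codon))) {
      return("not_applicable")
    }
    if (translate_codon(mutant) == translate_codon(codon)) {
      "synonymous"
    } else {
      "nonsynonymous"
    }
  } else if (kind == "deletion") {
    s <- pos; e <- pos + nchar(record$ref) - 1L
    cds_overlap <- sum(!is.na(ref_to_cds(s:e, gene_model)))
    if (cds_overlap == 0L) {
      if (all(region_of(s:e, gene_model) == "intronic")) "intronic"
      else "not_applicable"
    } else if (cds_overlap %% 3L == 0L &&
               !spans_splice_boundary(s, e, gene_model)) {
      "frame_preserving_indel"
    } else {
      "frame_disrupting"
    }
  } else {   # insertion after ref_pos
    left <- region_of(max(pos, 1L), gene_model)
    right <- region_of(min(pos + 1L, gene_model$span[2]), gene_model)
    if (left == "exonic" && right == "exonic") {
      if (nchar(record$alt) %% 3L == 0L) "frame_preserving_indel"
      else "frame_disrupting"
    } else if (left == "intronic" || right == "intronic") {
      "intronic"
    } else {
      "not_applicable"
    }
  }
}

spans_splice_boundary <- function(s, e, gene_model) {
  if (nrow(gene_model$introns) == 0L) return(FALSE)
  bounds <- c(gene_model$introns[, "start"] - 0.5,
              gene_model$introns[, "end"] + 0.5)
  any(bounds > s & bounds < e)
}

#' Annotate a variant table with region, effect and domain
#'
#' @param variant_table Tibble from [call_variants()].
#' @param gene_model A `gene_model`.
#' @param domain_map Domain map tibble; may be `NULL` (no domain column).
#' @param consensus Ungapped consensus sequence string.
#' @return The variant table with `region`, `effect` and `domain`
#'   columns added.
#' @export
annotate_variants <- function(variant_table, gene_model, domain_map,
                              consensus) {
  n <- nrow(variant_table)
  region <- character(n); effect <- character(n); domain <- character(n)
  for (i in seq_len(n)) {
    rec <- variant_table[i, ]
    pos <- if (rec$kind == "insertion") max(rec$ref_pos, 1L) else rec$ref_pos
    region[i] <- region_of(pos, gene_model)
    effect[i] <- classify_effect(rec, gene_model, consensus)
    domain[i] <- NA_character_
    if (!is.null(domain_map)) {
      span <- if (rec$kind == "deletion") {
        rec$ref_pos:(rec$ref_pos + nchar(rec$ref) - 1L)
      } else {
        pos
      }
      cpos <- ref_to_cds(span, gene_model)
      cpos <- cpos[!is.na(cpos)]
      if (length(cpos)) domain[i] <- domain_of(cpos[1L], domain_map)
    }
  }
  variant_table$region <- region
  variant_table$effect <- effect
  variant_table$domain <- domain
  variant_table
}

#' Reconstruct an allele sequence from the consensus and its variants
#'
#' Inverse of [call_variants()]: applies SNPs, deletions and insertions
#' to the ungapped consensus. Used for round-trip validation.
#'
#' @param consensus Ungapped consensus sequence string.
#' @param variant_table Variant records of a single allele.
#' @return The reconstructed allele sequence string.
#' @export
apply_variants <- function(consensus, variant_table) {
  vt <- variant_table[order(variant_table$ref_pos, decreasing = TRUE), ]
  s <- consensus
  for (i in seq_len(nrow(vt))) {
    rec <- vt[i, ]
    if (rec$kind == "SNP") {
      substr(s, rec$ref_pos, rec$ref_pos) <- rec$alt
    } else if (rec$kind == "deletion") {
      e <- rec$ref_pos + nchar(rec$ref) - 1L
      s <- paste0(substr(s, 1L, rec$ref_pos - 1L),
                  substr(s, e + 1L, nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, rec$ref_pos), rec$alt,
                  substr(s, rec$ref_pos + 1L, nchar(s)))
    }
  }
  s
}

#' Flag an allele as a putative pseudogene
#'
#' An allele is flagged when its indels leave a net reading-frame shift
#' over the coding sequence (the summed CDS lengths of insertions minus
#' deletions is not a multiple of 3), or when a deletion removes an
#' exon/intron boundary so that exons and intron can no longer be
#' assigned to the sequence. A lone frame-disrupting indel therefore
#' flags the allele, while a compensating pair that restores the frame
#' downstream does not.
#'
#' @param allele_variants Variant records of one allele.
#' @param gene_model A `gene_model`.
#' @return A list with `pseudogene` (logical) and `reason` (string
#'   citing the triggering record, or `NA`).
#' @export
flag_pseudogene <- function(allele_variants, gene_model) {
  net <- 0L
  first_shift <- NULL
  for (i in seq_len(nrow(allele_variants))) {
    rec <- allele_variants[i, ]
    if (rec$kind == "deletion") {
      s <- rec$ref_pos; e <- rec$ref_pos + nchar(rec$ref) - 1L
      if (spans_splice_boundary(s, e, gene_model)) {
        return(list(pseudogene = TRUE,
                    reason = sprintf(
                      "deletion at position %d spans an exon/intron boundary",
                      s)))
      }
      ov <- sum(!is.na(ref_to_cds(s:e, gene_model)))
      net <- net - ov
      if (ov %% 3L != 0L && is.null(first_shift)) first_shift <- rec
    } else if (rec$kind == "insertion") {
      left <- region_of(max(rec$ref_pos, 1L), gene_model)
      right <- region_of(min(rec$ref_pos + 1L, gene_model$span[2]), gene_model)
      if (left == "exonic" && right == "exonic") {
        net <- net + nchar(rec$alt)
        if (nchar(rec$alt) %% 3L != 0L && is.null(first_shift)) {
          first_shift <- rec
        }
      }
    }
  }
  if (net %% 3L != 0L) {
    rec <- first_shift
    return(list(pseudogene = TRUE,
                reason = sprintf(
                  "net reading-frame shift (%+d bp); first shifting %s of %d bp at position %d",
                  net, rec$kind, max(nchar(rec$ref), nchar(rec$alt)),
                  rec$ref_pos)))
  }
  list(pseudogene = FALSE, reason = NA_character_)
}

#' Write a variant table as TSV
#' @param variant_table Variant table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variant_table, path) {
  utils::write.table(variant_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a variant table as minimal VCF 4.2
#'
#' The consensus is the single reference contig. Insertions and
#' deletions are emitted with the conventional anchor base (the
#' reference base preceding the event).
#'
#' @param variant_table Variant table tibble.
#' @param consensus Ungapped consensus sequence string.
#' @param path Output path.
#' @param contig Contig name (default `"consensus"`).
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variant_table, consensus, path,
                               contig = "consensus") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", contig, nchar(consensus)),
               "##INFO=<ID=ALLELE,Number=1,Type=String,Description=\"Allele id\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  vt <- variant_table[order(variant_table$ref_pos, variant_table$allele_id), ]
  for (i in seq_len(nrow(vt))) {
    rec <- vt[i, ]
    if (rec$kind == "SNP") {
      pos <- rec$ref_pos; ref <- rec$ref; alt <- rec$alt
    } else if (rec$kind == "deletion") {
      pos <- max(rec$ref_pos - 1L, 1L)
      anchor <- substr(consensus, pos, pos)
      ref <- paste0(anchor, rec$ref); alt <- anchor
    } else {
      pos <- max(rec$ref_pos, 1L)
      anchor <- substr(consensus, pos, pos)
      ref <- anchor; alt <- paste0(anchor, rec$alt)
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tALLELE=%s",
                       contig, pos, ref, alt, rec$allele_id), con)
  }
  invisible(path)
}
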