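#' Segment an allele's polymorphisms into blocks and isolated SNPs
#'
#' Polymorphic sites of one allele (relative to the consensus) are
#' clustered greedily left to right: a site joins the current cluster
#' when it lies within `max_gap` bp of the previous site; clusters with
#' at least `min_sites` sites become polymorphic blocks, all remaining
#' sites are reported as isolated SNPs. Every site ends up in exactly one
#' block or in the isolated list.
#'
#' @param variant_table Variant table (all alleles or one).
#' @param allele_id Allele to segment.
#' @param min_sites Minimum number of sites in a block (default 3).
#' @param max_gap Maximum distance between consecutive member sites in
#'   bp (default 250).
#' @return A list with `blocks` (tibble: `allele_id`, `block_id`,
#'   `start`, `end`, `n_sites`, `positions` list-column) and `isolated`
#'   (tibble of leftover records).
#' @export
segment_blocks <- function(variant_table, allele_id, min_sites = 3L,
                           max_gap = 250L) {
  vt <- variant_table[variant_table$allele_id == allele_id, ]
  pos <- sort(unique(vt$ref_pos))
  if (length(pos) == 0L) {
    return(list(blocks = empty_block_table(),
                isolated = vt))
  }
  cluster <- cumsum(c(1L, diff(pos) > max_gap))
  blocks <- list()
  isolated_pos <- integer(0)
  bid <- 0L
  for (k in unique(cluster)) {
    p <- pos[cluster == k]
    if (length(p) >= min_sites) {
      bid <- bid + 1L
      blocks[[bid]] <- tibble::tibble(
        allele_id = allele_id,
        block_id = paste0(allele_id, ".B", bid),
        start = p[1L], end = p[length(p)],
        n_sites = length(p), positions = list(p))
    } else {
      isolated_pos <- c(isolated_pos, p)
    }
  }
  list(blocks = if (length(blocks)) dplyr::bind_rows(blocks)
       else empty_block_table(),
       isolated = vt[vt$ref_pos %in% isolated_pos, ])
}

empty_block_table <- function() {
  tibble::tibble(allele_id = character(0), block_id = character(0),
                 start = integer(0), end = integer(0),
                 n_sites = integer(0), positions = list())
}

#' Score donor sharing of one polymorphic block
#'
#' For each candidate donor, counts the member positions at which the
#' donor carries the allele's non-consensus base at the homologous
#' alignment column. Columns where the allele's variant is an indel, or
#' where the donor has a gap, are excluded from both the shared and the
#' total count. Donors are ranked by shared sites (ties broken by donor
#' id) and classified: `identical` when all comparable sites are shared,
#' `partial` when the shared fraction reaches `partial_threshold`,
#' otherwise `unique`.
#'
#' @param block One row of the `blocks` tibble from [segment_blocks()].
#' @param alignment The shared `allele_alignment` (consensus reference).
#' @param variant_table Variant table providing the allele's alt bases.
#' @param donor_ids Candidate donor row ids (default: every row except
#'   the block's allele and the reference).
#' @param partial_threshold Minimum shared fraction for `partial`
#'   (default 0.4).
#' @return A tibble `block_id`, `allele_id`, `donor_id`, `shared_sites`,
#'   `total_sites`, `classification`, sorted by `shared_sites`
#'   descending then donor id.
#' @export
match_block <- function(block, alignment, variant_table, donor_ids = NULL,
                        partial_threshold = 0.4) {
  if (is.null(donor_ids)) {
    donor_ids <- setdiff(names(alignment$rows),
                         c(block$allele_id, alignment$ref_id))
  }
  missing <- setdiff(donor_ids, names(alignment$rows))
  if (length(missing)) {
    stop("donor(s) missing from alignment: ", paste(missing, collapse = ", "))
  }
  positions <- block$positions[[1L]]
  vt <- variant_table[variant_table$allele_id == block$allele_id &
                        variant_table$ref_pos %in% positions &
                        variant_table$kind == "SNP", ]
  cols <- alignment$refpos_to_col[vt$ref_pos]
  alts <- vt$alt
  res <- lapply(sort(donor_ids), function(d) {
    dch <- strsplit(alignment$rows[[d]], "")[[1]][cols]
    ok <- dch != "-" & dch != "N"
    total <- sum(ok)
    shared <- sum(ok & dch == alts)
    cls <- if (total == 0L) "unique"
    else if (shared == total) "identical"
    else if (shared / total >= partial_threshold) "partial"
    else "unique"
    tibble::tibble(block_id = block$block_id, allele_id = block$allele_id,
                   donor_id = d, shared_sites = shared, total_sites = total,
                   classification = cls)
  })
  out <- dplyr::bind_rows(res)
  out[order(-out$shared_sites, out$donor_id), ]
}

#' Chimera report for one allele
#'
#' Summarizes an allele as a consensus backbone plus polymorphic blocks
#' with their best-matching donors. Blocks whose best donor is a paralog
#' are flagged as candidate paralog-derived conversion tracts; ties for
#' best donor are all listed, in donor-id order.
#'
#' @param allele_id Allele being reported.
#' @param blocks Blocks tibble for this allele (see [segment_blocks()]).
#' @param matches Combined match tibble from [match_block()] over the
#'   allele's blocks.
#' @param roles Optional named character vector mapping donor id to role
#'   (`"allele"`/`"paralog"`), e.g. from the alignment metadata.
#' @return A list: `allele_id`, `backbone` (`"consensus"`), `n_blocks`,
#'   `blocks` (per block: coordinates, best donors, shared/total,
#'   paralog flag) and `summary` (`"SNP-only allele"` or
#'   `"chimeric allele"`).
#' @export
chimera_report <- function(allele_id, blocks, matches, roles = NULL) {
  blocks <- blocks[blocks$allele_id == allele_id, ]
  if (nrow(blocks) == 0L) {
    return(list(allele_id = allele_id, backbone = "consensus",
                n_blocks = 0L, blocks = list(),
                summary = "SNP-only allele"))
  }
  per_block <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    m <- matches[matches$block_id == b$block_id, ]
    best <- m[m$shared_sites == max(m$shared_sites), , drop = FALSE]
    best <- best[order(best$donor_id), ]
    list(block_id = b$block_id, start = b$start, end = b$end,
         n_sites = b$n_sites,
         best_donors = best$donor_id,
         shared_sites = best$shared_sites[1L],
         total_sites = best$total_sites[1L],
         classification = best$classification[1L],
         paralog_derived = if (!is.null(roles)) {
           any(roles[best$donor_id] == "paralog", na.rm = TRUE)
         } else {
           NA
         })
  })
  list(allele_id = allele_id, backbone = "consensus",
       n_blocks = nrow(blocks), blocks = per_block,
       summary = "chimeric allele")
}

#' Count shared polymorphic sites inside a coordinate window
#'
#' Window-query companion to [match_block()]: instead of a segmented
#' block, compares an allele's polymorphic sites falling inside
#' `[start, end]` (consensus coordinates) against one donor or a donor
#' group, counting sites where the donor carries the allele's
#' non-consensus base.
#'
#' @param alignment The shared `allele_alignment`.
#' @param variant_table Variant table with the allele's records.
#' @param allele_id Allele to query.
#' @param start,end Window bounds, 1-based consensus coordinates.
#' @param donor_ids Donor rows; with more than one, a site counts as
#'   shared when any donor carries the alt base.
#' @return A list with `shared_sites`, `total_sites`, `positions`.
#' @export
window_shared_sites <- function(alignment, variant_table, allele_id,
                                start, end, donor_ids) {
  vt <- variant_table[variant_table$allele_id == allele_id &
                        variant_table$kind == "SNP" &
                        variant_table$ref_pos >= start &
                        variant_table$ref_pos <= end, ]
  cols <- alignment$refpos_to_col[vt$ref_pos]
  shared <- rep(FALSE, nrow(vt))
  for (d in donor_ids) {
    dch <- strsplit(alignment$rows[[d]], "")[[1]][cols]
    shared <- shared | (dch == vt$alt)
  }
  list(shared_sites = sum(shared), total_sites = nrow(vt),
       positions = vt$ref_pos[shared])
}

#' Ploidy-group profile of recurring block footprints
#'
#' A block footprint is the set of `(position, alt base)` pairs of a
#' block's SNP members. Footprints recurring across alleles are grouped
#' and their carriers tallied per ploidy group; a footprint carried by at
#' least `min_carriers` members of exactly one group is flagged
#' group-specific.
#'
#' @param variant_table Variant table over all alleles.
#' @param groups Named character vector: allele id -> ploidy group.
#' @param min_sites,max_gap Block segmentation parameters.
#' @param min_carriers Minimum carriers for the group-specific flag
#'   (default 2).
#' @return A tibble with `footprint`, `n_sites`, `start`, `end`,
#'   `carriers` (list), per-group carrier counts and `status`
#'   (`"group_specific"` or `"shared"`).
#' @export
ploidy_block_profile <- function(variant_table, groups, min_sites = 3L,
                                 max_gap = 250L, min_carriers = 2L) {
  alleles <- unique(variant_table$allele_id)
  rows <- list()
  for (id in alleles) {
    seg <- segment_blocks(variant_table, id, min_sites, max_gap)
    for (i in seq_len(nrow(seg$blocks))) {
      b <- seg$blocks[i, ]
      vt <- variant_table[variant_table$allele_id == id &
                            variant_table$ref_pos %in% b$positions[[1L]] &
                            variant_table$kind == "SNP", ]
      fp <- paste(paste0(vt$ref_pos, ":", vt$alt), collapse = ",")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        footprint = fp, allele_id = id, start = b$start, end = b$end,
        n_sites = nrow(vt))
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(footprint = character(0), n_sites = integer(0),
                          start = integer(0), end = integer(0),
                          carriers = list(), status = character(0)))
  }
  all_blocks <- dplyr::bind_rows(rows)
  grp_levels <- sort(unique(unname(groups)))
  out <- lapply(split(all_blocks, all_blocks$footprint), function(fb) {
    carriers <- sort(unique(fb$allele_id))
    counts <- vapply(grp_levels, function(g) {
      sum(groups[carriers] == g, na.rm = TRUE)
    }, integer(1))
    status <- if (sum(counts >= 1L) == 1L && max(counts) >= min_carriers) {
      "group_specific"
    } else {
      "shared"
    }
    res <- tibble::tibble(footprint = fb$footprint[1L],
                          n_sites = fb$n_sites[1L],
                          start = fb$start[1L], end = fb$end[1L],
                          carriers = list(carriers), status = status)
    for (g in grp_levels) res[[paste0("n_", g)]] <- counts[[g]]
    res
  })
  out <- dplyr::bind_rows(out)
  out[order(-out$n_sites), ]
}

#' Write blocks and matches as TSV
#' @param blocks Blocks tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  b <- blocks
  b$positions <- vapply(b$positions, paste, character(1), collapse = ",")
  utils::write.table(b, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
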