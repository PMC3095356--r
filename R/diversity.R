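# Region handling -----------------------------------------------------------

#' Reference positions of a named region
#'
#' @param gene_model A `gene_model`.
#' @param domain_map Domain map tibble over CDS coordinates.
#' @param region `"CDS"` (the whole coding sequence) or a domain label
#'   from the map (e.g. `"CC"`, `"NBS"`, `"Interspacer"`, `"LRR"`).
#' @return Integer vector of 1-based reference positions.
#' @export
region_refpos <- function(gene_model, domain_map, region) {
  if (identical(region, "CDS")) {
    cds <- seq_len(gene_model$cds_length)
  } else {
    row <- domain_map[domain_map$domain == region, ]
    if (nrow(row) != 1L) stop("unknown region: ", region)
    cds <- seq.int(row$start, row$end)
  }
  cds_to_ref(cds, gene_model)
}

# alignment columns of a reference-position set: the positions' own
# columns plus insertion columns anchored after a member position
region_columns <- function(alignment, refpos) {
  base_cols <- alignment$refpos_to_col[refpos]
  ins_cols <- which(alignment$is_insertion &
                      alignment$col_to_refpos %in% refpos)
  sort(c(base_cols, ins_cols))
}

group_char_matrix <- function(alignment, ids, cols = NULL) {
  missing <- setdiff(ids, names(alignment$rows))
  if (length(missing)) {
    stop("group member(s) missing from alignment: ",
         paste(missing, collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(unname(alignment$rows[ids]), ""))
  rownames(mat) <- ids
  if (!is.null(cols)) mat <- mat[, cols, drop = FALSE]
  mat
}

# Polymorphic sites ----------------------------------------------------------

#' Count polymorphic (segregating) sites in a region
#'
#' A column is polymorphic when at least two distinct bases (non-gap,
#' non-N) segregate among the group members. Columns where any member
#' has a gap are excluded entirely (complete deletion).
#'
#' @param alignment An `allele_alignment` with consensus reference.
#' @param ids Group member row ids.
#' @param gene_model,domain_map,region Region selection (see
#'   [region_refpos()]); all `NULL` means the whole alignment.
#' @return Integer count of polymorphic columns.
#' @export
count_polymorphic_sites <- function(alignment, ids, gene_model = NULL,
                                    domain_map = NULL, region = NULL) {
  if (length(ids) == 0L) stop("empty group")
  cols <- if (is.null(region)) {
    seq_len(alignment$length)
  } else {
    region_columns(alignment, region_refpos(gene_model, domain_map, region))
  }
  mat <- group_char_matrix(alignment, ids, cols)
  sum(apply(mat, 2, function(col) {
    if (any(col == "-")) return(FALSE)
    length(unique(col[col != "N"])) >= 2L
  }))
}

# Nucleotide diversity -------------------------------------------------------

#' Nucleotide diversity (pi)
#'
#' Average, over all unordered pairs of group members, of the proportion
#' of differing sites among the sites where both members carry an
#' unambiguous base (pairwise deletion of gaps and N).
#'
#' @inheritParams count_polymorphic_sites
#' @return Numeric pi in `[0, 1]`.
#' @export
nucleotide_diversity <- function(alignment, ids, gene_model = NULL,
                                 domain_map = NULL, region = NULL) {
  if (length(ids) < 2L) stop("need at least 2 group members")
  cols <- if (is.null(region)) {
    seq_len(alignment$length)
  } else {
    region_columns(alignment, region_refpos(gene_model, domain_map, region))
  }
  mat <- group_char_matrix(alignment, ids, cols)
  valid <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  n <- length(ids)
  total <- 0
  npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      both <- valid[i, ] & valid[j, ]
      compared <- sum(both)
      npairs <- npairs + 1L
      if (compared > 0L) {
        total <- total + sum(mat[i, both] != mat[j, both]) / compared
      }
    }
  }
  total / npairs
}

# Synonymous / non-synonymous substitution counting --------------------------

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Fractional synonymous/nonsynonymous tallies for the segregating changes
# of one codon. `changes`: tibble with `offset` (1..3) and `alt`.
# Changes at distinct sites are pathway-averaged over all substitution
# orders (equal weight); when a site carries several minority bases, the
# average additionally runs over the combinations choosing one base per
# site, and each (site, base) change is averaged over the combinations
# containing it. A step to or from a stop codon counts as nonsynonymous.
classify_codon_changes <- function(cons_codon, changes) {
  if (nrow(changes) == 0L) return(c(syn = 0, nonsyn = 0))
  sites <- sort(unique(changes$offset))
  alts_by_site <- lapply(sites, function(s) changes$alt[changes$offset == s])
  combos <- expand.grid(lapply(alts_by_site, seq_along))
  # accumulators per change key "offset:alt"
  keys <- paste0(changes$offset, ":", changes$alt)
  syn_sum <- stats::setNames(numeric(length(keys)), keys)
  combo_n <- stats::setNames(numeric(length(keys)), keys)
  for (ci in seq_len(nrow(combos))) {
    combo_alts <- vapply(seq_along(sites), function(k) {
      alts_by_site[[k]][combos[ci, k]]
    }, character(1))
    orders <- perms(seq_along(sites))
    step_syn <- stats::setNames(numeric(length(sites)), as.character(sites))
    for (ord in orders) {
      codon <- cons_codon
      for (s_idx in ord) {
        before <- translate_codon(codon)
        substr(codon, sites[s_idx], sites[s_idx]) <- combo_alts[s_idx]
        after <- translate_codon(codon)
        is_syn <- !is.na(before) && !is.na(after) && before == after
        step_syn[as.character(sites[s_idx])] <-
          step_syn[as.character(sites[s_idx])] + as.numeric(is_syn)
      }
    }
    step_syn <- step_syn / length(orders)
    for (k in seq_along(sites)) {
      key <- paste0(sites[k], ":", combo_alts[k])
      syn_sum[key] <- syn_sum[key] + step_syn[as.character(sites[k])]
      combo_n[key] <- combo_n[key] + 1
    }
  }
  syn_frac <- sum(syn_sum / combo_n)
  c(syn = syn_frac, nonsyn = length(keys) - syn_frac)
}

round_half_up <- function(x) floor(x + 0.5)

#' Count synonymous and non-synonymous substitutions in a region
#'
#' For each distinct segregating change (site, minority base) relative
#' to the group consensus, the change is classified as synonymous or
#' non-synonymous by translating the consensus codon with and without the
#' change; codons with several segregating sites are handled by
#' equal-weight pathway averaging over substitution orders, and the
#' fractional tallies are rounded half-up at the end. Codons containing
#' any gap or N among the group are skipped (complete deletion).
#'
#' @inheritParams count_polymorphic_sites
#' @param region Must be codon-aligned (`"CDS"` or a domain whose CDS
#'   interval starts at a codon boundary and spans whole codons).
#' @return A list with integer `ks_count` (synonymous), `ka_count`
#'   (non-synonymous) and the raw fractional tallies `ks_frac`,
#'   `ka_frac`.
#' @export
count_substitutions <- function(alignment, ids, gene_model, domain_map = NULL,
                                region = "CDS") {
  if (identical(region, "CDS")) {
    cds_range <- c(1L, gene_model$cds_length)
  } else {
    row <- domain_map[domain_map$domain == region, ]
    if (nrow(row) != 1L) stop("unknown region: ", region)
    cds_range <- c(row$start, row$end)
  }
  if ((cds_range[1L] - 1L) %% 3L != 0L || cds_range[2L] %% 3L != 0L) {
    stop("region is not codon-aligned: CDS interval ",
         cds_range[1L], "-", cds_range[2L])
  }
  cds_pos <- seq.int(cds_range[1L], cds_range[2L])
  cols <- alignment$refpos_to_col[cds_to_ref(cds_pos, gene_model)]
  mat <- group_char_matrix(alignment, ids, cols)
  n_codons <- length(cds_pos) %/% 3L
  # prescreen: only codons that contain a segregating site and no gap/N
  # need the full per-codon treatment
  bad_col <- colSums(mat == "-" | mat == "N") > 0L
  seg_col <- colSums(mat != mat[rep(1L, nrow(mat)), , drop = FALSE]) > 0L
  codon_of_col <- rep(seq_len(n_codons), each = 3L)
  bad_codon <- tapply(bad_col, codon_of_col, any)
  seg_codon <- tapply(seg_col, codon_of_col, any)
  ks <- 0; ka <- 0
  for (ci in which(seg_codon & !bad_codon)) {
    idx <- (ci - 1L) * 3L + 1:3
    sub <- mat[, idx, drop = FALSE]
    cons <- vapply(1:3, function(k) {
      tab <- table(sub[, k])
      nm <- names(tab)[tab == max(tab)]
      sort(nm)[1L]   # tie: lexicographic
    }, character(1))
    changes <- list()
    for (k in 1:3) {
      alts <- setdiff(unique(sub[, k]), cons[k])
      for (a in alts) {
        changes[[length(changes) + 1L]] <- tibble::tibble(offset = k, alt = a)
      }
    }
    if (length(changes) == 0L) next
    tal <- classify_codon_changes(paste(cons, collapse = ""),
                                  dplyr::bind_rows(changes))
    ks <- ks + tal[["syn"]]
    ka <- ka + tal[["nonsyn"]]
  }
  list(ks_count = as.integer(round_half_up(ks)),
       ka_count = as.integer(round_half_up(ka)),
       ks_frac = ks, ka_frac = ka)
}

# Formatters -----------------------------------------------------------------

trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

#' Ka/Ks ratio of raw substitution counts
#'
#' The ratio of the non-synonymous to the synonymous substitution count,
#' truncated (floored) to two decimals by default; `NA` (rendered `"-"`)
#' when the synonymous count is zero. This is the ratio of raw counts,
#' not a per-site normalized rate; see [site_normalized_ratio()] for the
#' Nei-Gojobori pN/pS alternative.
#'
#' @param ka_count,ks_count Non-negative substitution counts.
#' @param mode `"floor"` (truncate, default) or `"round"`.
#' @return Numeric ratio, or `NA` when undefined.
#' @export
substitution_ratio <- function(ka_count, ks_count, mode = c("floor", "round")) {
  mode <- match.arg(mode)
  if (ka_count < 0 || ks_count < 0) stop("counts must be non-negative")
  if (ks_count == 0) return(NA_real_)
  r <- ka_count / ks_count
  if (mode == "floor") trunc2(r) else round(r, 2)
}

#' Polymorphic sites per 100 bp
#'
#' @param count Number of polymorphic sites.
#' @param length Region length in bp (denominator; ungapped reference
#'   length or gapped alignment length — report both where relevant).
#' @param mode `"floor"` (truncate to 2 decimals, default) or `"round"`.
#' @return Numeric sites per 100 bp.
#' @export
per_100bp <- function(count, length, mode = c("floor", "round")) {
  mode <- match.arg(mode)
  if (length <= 0) stop("length must be positive")
  x <- 100 * count / length
  if (mode == "floor") trunc2(x) else round(x, 2)
}

#' Site-normalized Nei-Gojobori pN/pS ratio
#'
#' Explicitly labelled alternative to the raw count ratio: substitution
#' counts are normalized by the numbers of synonymous and non-synonymous
#' sites of the group-consensus region (average over codons, each codon
#' position weighted by the fraction of possible changes that are
#' synonymous), with an optional Jukes-Cantor correction.
#'
#' @inheritParams count_substitutions
#' @param jukes_cantor Apply the Jukes-Cantor multiple-hit correction.
#' @return A list with `pn`, `ps`, `ratio`, `syn_sites`, `nonsyn_sites`.
#' @export
site_normalized_ratio <- function(alignment, ids, gene_model,
                                  domain_map = NULL, region = "CDS",
                                  jukes_cantor = TRUE) {
  counts <- count_substitutions(alignment, ids, gene_model, domain_map, region)
  if (identical(region, "CDS")) {
    cds_range <- c(1L, gene_model$cds_length)
  } else {
    row <- domain_map[domain_map$domain == region, ]
    cds_range <- c(row$start, row$end)
  }
  cds_pos <- seq.int(cds_range[1L], cds_range[2L])
  cols <- alignment$refpos_to_col[cds_to_ref(cds_pos, gene_model)]
  mat <- group_char_matrix(alignment, ids, cols)
  syn_sites <- 0
  n_codons_used <- 0L
  bases <- c("A", "C", "G", "T")
  for (ci in seq_len(length(cds_pos) %/% 3L)) {
    idx <- (ci - 1L) * 3L + 1:3
    sub <- mat[, idx, drop = FALSE]
    if (any(sub == "-" | sub == "N")) next
    n_codons_used <- n_codons_used + 1L
    cons <- vapply(1:3, function(k) {
      tab <- table(sub[, k]); sort(names(tab)[tab == max(tab)])[1L]
    }, character(1))
    codon <- paste(cons, collapse = "")
    for (k in 1:3) {
      for (b in setdiff(bases, cons[k])) {
        mut <- codon
        substr(mut, k, k) <- b
        if (identical(translate_codon(mut), translate_codon(codon))) {
          syn_sites <- syn_sites + 1 / 3
        }
      }
    }
  }
  total_sites <- 3 * n_codons_used
  nonsyn_sites <- total_sites - syn_sites
  ps <- if (syn_sites > 0) counts$ks_frac / syn_sites else NA_real_
  pn <- if (nonsyn_sites > 0) counts$ka_frac / nonsyn_sites else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) return(p)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  if (jukes_cantor) {
    ps <- jc(ps); pn <- jc(pn)
  }
  list(pn = pn, ps = ps,
       ratio = if (!is.na(ps) && ps > 0) pn / ps else NA_real_,
       syn_sites = syn_sites, nonsyn_sites = nonsyn_sites)
}

# Per-region, per-group summary table ----------------------------------------

#' Per-region, per-group diversity summary table
#'
#' Computes, for each ploidy group (and the combined set) and each
#' region (whole CDS plus the protein domains), the number of aligned
#' sites (ungapped reference length and gapped alignment columns), the
#' polymorphic-site count, sites per 100 bp (both denominators),
#' nucleotide diversity, synonymous/non-synonymous substitution counts
#' and their raw-count ratio.
#'
#' @param alignment An `allele_alignment` with consensus reference.
#' @param gene_model A `gene_model`.
#' @param domain_map Domain map tibble.
#' @param groups Named character vector: allele id -> group label (e.g.
#'   `"hexaploid"`/`"tetraploid"`). Alleles to exclude (pseudogenes)
#'   are simply left out of `groups`.
#' @param regions Regions to summarize (default whole CDS + the four
#'   domains).
#' @param combined_label Label of the all-groups row set (default
#'   `"combined"`).
#' @param ratio_mode,per100_mode Formatter modes (see
#'   [substitution_ratio()], [per_100bp()]).
#' @return A tibble with one row per group x region.
#' @export
summarize_diversity <- function(alignment, gene_model, domain_map, groups,
                                regions = c("CDS", "CC", "NBS",
                                            "Interspacer", "LRR"),
                                combined_label = "combined",
                                ratio_mode = "floor", per100_mode = "floor") {
  if (length(groups) == 0L) stop("empty group assignment")
  grp_levels <- unique(unname(groups))
  group_sets <- c(stats::setNames(lapply(grp_levels, function(g) {
    names(groups)[groups == g]
  }), grp_levels),
  stats::setNames(list(names(groups)), combined_label))
  rows <- list()
  for (gname in names(group_sets)) {
    ids <- group_sets[[gname]]
    for (reg in regions) {
      refpos <- region_refpos(gene_model, domain_map, reg)
      cols <- region_columns(alignment, refpos)
      poly <- count_polymorphic_sites(alignment, ids, gene_model,
                                      domain_map, reg)
      pi_val <- nucleotide_diversity(alignment, ids, gene_model,
                                     domain_map, reg)
      subs <- count_substitutions(alignment, ids, gene_model, domain_map, reg)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = gname, region = reg,
        aligned_sites = length(refpos), gapped_sites = length(cols),
        polymorphic_sites = poly,
        per_100bp = per_100bp(poly, length(refpos), per100_mode),
        per_100bp_gapped = per_100bp(poly, length(cols), per100_mode),
        pi = pi_val,
        ks_count = subs$ks_count, ka_count = subs$ka_count,
        ratio = substitution_ratio(subs$ka_count, subs$ks_count, ratio_mode))
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a diversity summary as TSV (ratio rendered "-" when undefined)
#' @param summary Tibble from [summarize_diversity()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diversity_tsv <- function(summary, path) {
  out <- summary
  out$ratio <- ifelse(is.na(out$ratio), "-", format(out$ratio, nsmall = 2))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
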