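#' Read an allele set from a FASTA file
#'
#' Reads a multi-FASTA of allele, paralog or reference sequences together
#' with per-record metadata. Metadata can come from `key=value` tokens in
#' the FASTA headers (`role=`, `ploidy=`, `origin=`) or from a sidecar TSV
#' with columns `id`, `role`, `ploidy_group`, `origin`; the sidecar wins
#' where both are present.
#'
#' @param path Path to a FASTA file. Bases are upper-cased and `U` is
#'   normalized to `T`; only `A`, `C`, `G`, `T`, `N` are accepted.
#' @param metadata Optional path to a sidecar metadata TSV.
#' @return A tibble with columns `id`, `role` (one of `"allele"`,
#'   `"paralog"`, `"reference"`), `ploidy_group` (`"hexaploid"`,
#'   `"tetraploid"`, `"unknown"`), `origin` and `bases`.
#' @export
read_allele_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bases <- toupper(as.character(set))
  bases <- gsub("U", "T", bases, fixed = TRUE)
  for (i in seq_along(bases)) {
    bad <- regexpr("[^ACGTN]", bases[[i]])
    if (bad > 0L) {
      stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                   substr(bases[[i]], bad, bad), ids[[i]], bad))
    }
    if (nchar(bases[[i]]) == 0L) stop("empty sequence for record '", ids[[i]], "'")
  }
  tokens <- function(h, key, default) {
    m <- regmatches(h, regexpr(paste0(key, "=[^ \t]+"), h))
    if (length(m) == 0L) default else sub(paste0(key, "="), "", m)
  }
  out <- tibble::tibble(
    id = ids,
    role = vapply(headers, tokens, character(1), key = "role",
                  default = "allele", USE.NAMES = FALSE),
    ploidy_group = vapply(headers, tokens, character(1), key = "ploidy",
                          default = "unknown", USE.NAMES = FALSE),
    origin = vapply(headers, tokens, character(1), key = "origin",
                    default = NA_character_, USE.NAMES = FALSE),
    bases = unname(bases)
  )
  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    for (col in intersect(c("role", "ploidy_group", "origin"), names(md))) {
      idx <- match(out$id, md$id)
      out[[col]] <- ifelse(is.na(idx), out[[col]], md[[col]][idx])
    }
  }
  bad_role <- setdiff(out$role, c("allele", "paralog", "reference"))
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  bad_pg <- setdiff(out$ploidy_group, c("hexaploid", "tetraploid", "unknown"))
  if (length(bad_pg)) stop("unknown ploidy_group(s): ", paste(bad_pg, collapse = ", "))
  out
}

#' Write sequences to FASTA
#'
#' @param x A named character vector of sequences, or a tibble with `id`
#'   and `bases` columns (as returned by [read_allele_fasta()]).
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @param with_metadata If `TRUE` and `x` is a tibble, `role=`, `ploidy=`
#'   and `origin=` tokens are appended to each header.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(x, path, with_metadata = FALSE) {
  if (is.data.frame(x)) {
    seqs <- x$bases
    hdr <- x$id
    if (with_metadata) {
      hdr <- paste0(hdr, " role=", x$role, " ploidy=", x$ploidy_group,
                    ifelse(is.na(x$origin), "", paste0(" origin=", x$origin)))
    }
    names(seqs) <- hdr
  } else {
    seqs <- x
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

nw_submat <- function(match, mismatch) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

# Pairwise global alignment of one sequence against the reference.
# Returns the two gapped strings (pattern first).
align_pair <- function(seq, ref, params) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq),
    subject = Biostrings::DNAString(ref),
    type = "global",
    substitutionMatrix = nw_submat(params$match, params$mismatch),
    gapOpening = abs(params$gap_open),
    gapExtension = abs(params$gap_extend)
  )
  list(
    pattern = as.character(Biostrings::alignedPattern(pa)),
    subject = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}

# Anchored pairwise alignment for near-identical sequences: exact-match
# k-mer anchors partition the problem and only the divergent segments
# between anchors go through the full dynamic program. Falls back to the
# full alignment when too few anchors chain (e.g. a diverged paralog) or
# for short sequences, so the optimal score is preserved there.
align_pair_anchored <- function(seq, ref, params, k = 64L, step = 200L,
                                min_len = 500L) {
  L <- nchar(ref)
  if (L < min_len || nchar(seq) < min_len) return(align_pair(seq, ref, params))
  if (nchar(seq) == L) {
    # equal-length pairs within moderate divergence align on the diagonal:
    # opening a gap pair costs more than the mismatches it could save at
    # these identity levels
    a <- strsplit(seq, "")[[1]]
    b <- strsplit(ref, "")[[1]]
    informative <- a != "N" & b != "N"
    mism <- sum(a != b & informative)
    if (mism / L <= 0.2) {
      score <- sum(a == b & informative) * params$match +
        mism * params$mismatch
      return(list(pattern = seq, subject = ref, score = score))
    }
  }
  starts <- seq.int(1L, L - k + 1L, by = step)
  anchors <- list()
  for (p in starts) {
    kmer <- substr(ref, p, p + k - 1L)
    hit <- gregexpr(kmer, seq, fixed = TRUE)[[1]]
    if (length(hit) == 1L && hit[1] > 0L) {
      anchors[[length(anchors) + 1L]] <- c(ref = p, seq = hit[1])
    }
  }
  if (length(anchors) < 2L) return(align_pair(seq, ref, params))
  am <- do.call(rbind, anchors)
  # greedy monotone chain (both coordinates strictly increasing, no overlap)
  keep <- 1L
  for (i in 2L:nrow(am)) {
    last <- am[keep[length(keep)], ]
    if (am[i, "ref"] >= last["ref"] + k && am[i, "seq"] >= last["seq"] + k) {
      keep <- c(keep, i)
    }
  }
  am <- am[keep, , drop = FALSE]
  p_parts <- character(0); q_parts <- character(0); score <- 0
  prev_ref <- 0L; prev_seq <- 0L
  segs <- rbind(am, c(ref = L + 1L, seq = nchar(seq) + 1L))
  for (i in seq_len(nrow(segs))) {
    rseg <- substr(ref, prev_ref + 1L, segs[i, "ref"] - 1L)
    sseg <- substr(seq, prev_seq + 1L, segs[i, "seq"] - 1L)
    if (nchar(rseg) == 0L && nchar(sseg) == 0L) {
      # nothing between anchors
    } else if (identical(rseg, sseg)) {
      p_parts <- c(p_parts, sseg); q_parts <- c(q_parts, rseg)
      score <- score + nchar(rseg) * params$match
    } else if (nchar(rseg) == 0L) {
      p_parts <- c(p_parts, sseg)
      q_parts <- c(q_parts, strrep("-", nchar(sseg)))
      score <- score + params$gap_open + nchar(sseg) * params$gap_extend
    } else if (nchar(sseg) == 0L) {
      p_parts <- c(p_parts, strrep("-", nchar(rseg)))
      q_parts <- c(q_parts, rseg)
      score <- score + params$gap_open + nchar(rseg) * params$gap_extend
    } else if (nchar(rseg) == nchar(sseg)) {
      # equal-length segment between exact anchors: diagonal pairing
      a <- strsplit(sseg, "")[[1]]; b <- strsplit(rseg, "")[[1]]
      informative <- a != "N" & b != "N"
      p_parts <- c(p_parts, sseg); q_parts <- c(q_parts, rseg)
      score <- score + sum(a == b & informative) * params$match +
        sum(a != b & informative) * params$mismatch
    } else {
      sub <- align_pair(sseg, rseg, params)
      p_parts <- c(p_parts, sub$pattern); q_parts <- c(q_parts, sub$subject)
      score <- score + sub$score
    }
    if (i <= nrow(am)) {
      kmer <- substr(ref, segs[i, "ref"], segs[i, "ref"] + k - 1L)
      p_parts <- c(p_parts, kmer); q_parts <- c(q_parts, kmer)
      score <- score + k * params$match
      prev_ref <- segs[i, "ref"] + k - 1L
      prev_seq <- segs[i, "seq"] + k - 1L
    }
  }
  list(pattern = paste(p_parts, collapse = ""),
       subject = paste(q_parts, collapse = ""),
       score = score)
}

#' Multiple alignment of near-identical allele sequences
#'
#' Builds a global multiple alignment suitable for allelic series whose
#' members are expected to be highly similar (pairwise identity well above
#' 80%). Each sequence is aligned to a reference sequence by global
#' Needleman-Wunsch alignment with affine gap costs, and the pairwise
#' alignments are merged center-star style: insertions relative to the
#' reference open shared gap columns. This is not a general-purpose MSA;
#' for the near-identical inputs it targets, gap placement is dominated by
#' the reference coordinate system and the merge is exact.
#'
#' @param sequences A tibble from [read_allele_fasta()], or a named
#'   character vector of sequences.
#' @param params Alignment scoring parameters: `match`, `mismatch`,
#'   `gap_open`, `gap_extend` (gap of length L costs
#'   `gap_open + L * gap_extend`, penalties given as negative numbers).
#' @param ref_id Id of the sequence used as the alignment backbone;
#'   defaults to the longest sequence (first on ties).
#' @return An `allele_alignment` object: a list with `rows` (named
#'   character vector of equal-length gapped strings), `length`, `ref_id`,
#'   coordinate maps (see [column_maps()]), per-sequence pairwise `scores`
#'   against the reference, and the metadata tibble `meta`.
#' @export
align_near_identical <- function(sequences,
                                 params = list(match = 1, mismatch = -2,
                                               gap_open = -8, gap_extend = -1),
                                 ref_id = NULL) {
  if (is.data.frame(sequences)) {
    meta <- sequences[, setdiff(names(sequences), "bases")]
    seqs <- stats::setNames(sequences$bases, sequences$id)
  } else {
    seqs <- sequences
    meta <- tibble::tibble(id = names(seqs), role = "allele",
                           ploidy_group = "unknown", origin = NA_character_)
  }
  if (length(seqs) == 0L) stop("no sequences to align")
  if (length(seqs) == 1L) stop("need at least 2 sequences to align")
  if (is.null(ref_id)) ref_id <- names(seqs)[which.max(nchar(seqs))]
  if (!ref_id %in% names(seqs)) stop("unknown ref_id: ", ref_id)
  lens <- nchar(seqs)
  if (max(lens) > 1.25 * min(lens)) {
    warning("sequence lengths differ by more than 25%; alignment may be poor")
  }
  ref <- seqs[[ref_id]]
  L <- nchar(ref)
  others <- setdiff(names(seqs), ref_id)

  # per sequence: chars aligned at each reference position, plus insertion
  # strings keyed by the reference position they follow (0 = before start)
  aligned_at <- list()
  ins <- list()
  scores <- stats::setNames(numeric(length(seqs)), names(seqs))
  scores[[ref_id]] <- sum(nchar(ref)) * params$match
  for (id in others) {
    pw <- align_pair_anchored(seqs[[id]], ref, params)
    scores[[id]] <- pw$score
    p <- strsplit(pw$pattern, "")[[1]]
    q <- strsplit(pw$subject, "")[[1]]
    nongap <- q != "-"
    r_at <- cumsum(nongap)              # ref position per aligned column
    at <- character(L)
    at[r_at[nongap]] <- p[nongap]
    inshere <- rep("", L + 1L)
    if (any(!nongap)) {
      gap_idx <- which(!nongap)
      pieces <- vapply(split(p[gap_idx], r_at[gap_idx]), paste,
                       character(1), collapse = "")
      inshere[as.integer(names(pieces)) + 1L] <- pieces
    }
    aligned_at[[id]] <- at
    ins[[id]] <- inshere
  }
  aligned_at[[ref_id]] <- strsplit(ref, "")[[1]]
  ins[[ref_id]] <- rep("", L + 1L)

  max_ins <- rep(0L, L + 1L)
  for (id in names(seqs)) max_ins <- pmax(max_ins, nchar(ins[[id]]))

  rows <- vapply(names(seqs), function(id) {
    parts <- character(2L * L + 1L)
    pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
    parts[1L] <- pad(ins[[id]][1L], max_ins[1L])
    for (r in seq_len(L)) {
      parts[2L * r] <- aligned_at[[id]][r]
      parts[2L * r + 1L] <- pad(ins[[id]][r + 1L], max_ins[r + 1L])
    }
    paste(parts, collapse = "")
  }, character(1))
  names(rows) <- names(seqs)
  new_allele_alignment(rows, ref_id = ref_id, meta = meta, scores = scores)
}

#' Construct an alignment object from pre-aligned rows
#'
#' Validates and indexes a user-supplied multiple alignment (e.g. read
#' from an aligned FASTA with `-` gap characters).
#'
#' @param rows Named character vector of equal-length gapped strings.
#' @param ref_id Row providing the reference coordinate system.
#' @param meta Optional metadata tibble (`id`, `role`, `ploidy_group`,
#'   `origin`).
#' @param scores Optional per-row alignment scores.
#' @return An `allele_alignment` object.
#' @export
new_allele_alignment <- function(rows, ref_id, meta = NULL, scores = NULL) {
  if (length(rows) < 1L) stop("alignment needs at least one row")
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    stop("alignment rows must have unique names")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("aligned rows have unequal lengths: ",
         paste(range(widths), collapse = " vs "))
  }
  if (!ref_id %in% names(rows)) stop("unknown ref_id: ", ref_id)
  if (is.null(meta)) {
    meta <- tibble::tibble(id = names(rows), role = "allele",
                           ploidy_group = "unknown", origin = NA_character_)
  }
  maps <- column_maps_rows(rows, ref_id)
  structure(list(rows = rows, length = unname(widths[1L]), ref_id = ref_id,
                 col_to_refpos = maps$col_to_refpos,
                 is_insertion = maps$is_insertion,
                 refpos_to_col = maps$refpos_to_col,
                 meta = meta, scores = scores),
            class = "allele_alignment")
}

#' @export
print.allele_alignment <- function(x, ...) {
  cat(sprintf("allele_alignment: %d rows x %d columns (reference: %s, %d bp)\n",
              length(x$rows), x$length, x$ref_id, length(x$refpos_to_col)))
  invisible(x)
}

#' Read a pre-computed alignment from an aligned FASTA
#'
#' @inheritParams read_allele_fasta
#' @param ref_id Row to use as the coordinate reference; defaults to the
#'   first record.
#' @return An `allele_alignment`.
#' @export
read_alignment_fasta <- function(path, ref_id = NULL, metadata = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  rows <- toupper(as.character(set))
  names(rows) <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (is.null(ref_id)) ref_id <- names(rows)[1L]
  meta <- NULL
  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    meta <- tibble::tibble(
      id = names(rows),
      role = md$role[match(names(rows), md$id)],
      ploidy_group = md$ploidy_group[match(names(rows), md$id)],
      origin = md$origin[match(names(rows), md$id)]
    )
    meta$role[is.na(meta$role)] <- "allele"
    meta$ploidy_group[is.na(meta$ploidy_group)] <- "unknown"
  }
  new_allele_alignment(rows, ref_id = ref_id, meta = meta)
}

# shared internal: maps for a set of gapped rows given the reference row
column_maps_rows <- function(rows, ref_id) {
  refchars <- strsplit(rows[[ref_id]], "")[[1]]
  nongap <- refchars != "-"
  col_to_refpos <- cumsum(nongap)
  is_insertion <- !nongap
  refpos_to_col <- which(nongap)
  list(col_to_refpos = as.integer(col_to_refpos),
       is_insertion = is_insertion,
       refpos_to_col = as.integer(refpos_to_col))
}

#' Column/reference coordinate maps of an alignment
#'
#' Reference positions are 1-based over the ungapped reference row. Gap
#' columns in the reference row map to the nearest preceding reference
#' position (0 before the first base) and are flagged as insertions.
#'
#' @param alignment An `allele_alignment`.
#' @param ref_id Reference row id; defaults to the alignment's.
#' @return A list with `col_to_refpos` (integer per column),
#'   `is_insertion` (logical per column) and `refpos_to_col` (integer per
#'   reference position). The maps are mutually inverse on non-gap
#'   reference columns.
#' @export
column_maps <- function(alignment, ref_id = alignment$ref_id) {
  if (!ref_id %in% names(alignment$rows)) stop("unknown ref_id: ", ref_id)
  column_maps_rows(alignment$rows, ref_id)
}

#' Degapped sequence of one alignment row
#' @param alignment An `allele_alignment`.
#' @param id Row id.
#' @return The ungapped sequence string.
#' @export
degap_row <- function(alignment, id) {
  if (!id %in% names(alignment$rows)) stop("unknown row id: ", id)
  gsub("-", "", alignment$rows[[id]], fixed = TRUE)
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the consensus base is the most frequent non-N character
#' among the selected rows; a column where gaps outnumber every base gets
#' a gap consensus (and is later excluded from reference numbering).
#' Base-vs-base ties are broken lexicographically (A < C < G < T) and the
#' tied columns are reported.
#'
#' @param alignment An `allele_alignment`.
#' @param include_roles Roles to include (via the alignment's metadata);
#'   default `"allele"`. Ignored when `ids` is given.
#' @param ids Explicit row ids to include.
#' @return A `consensus_profile`: list with `consensus` (gapped string),
#'   `counts` (5 x ncol matrix of A/C/G/T/gap counts), `tie_columns` and
#'   the ids used.
#' @export
build_consensus <- function(alignment, include_roles = "allele", ids = NULL) {
  if (is.null(ids)) {
    ids <- alignment$meta$id[alignment$meta$role %in% include_roles]
    ids <- intersect(ids, names(alignment$rows))
  }
  if (length(ids) < 1L) stop("no rows selected for consensus")
  mat <- do.call(rbind, strsplit(unname(alignment$rows[ids]), ""))
  syms <- c("A", "C", "G", "T", "-")
  counts <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    vapply(syms, function(s) sum(col == s), integer(1))
  }, integer(5))
  rownames(counts) <- syms
  base_counts <- counts[1:4, , drop = FALSE]
  best <- apply(base_counts, 2, max)
  gapc <- counts[5, ]
  cons <- character(ncol(mat))
  ties <- integer(0)
  for (j in seq_len(ncol(mat))) {
    if (gapc[j] > best[j]) {
      cons[j] <- "-"
    } else if (best[j] == 0L) {
      cons[j] <- "N"   # column is all N
    } else {
      top <- which(base_counts[, j] == best[j])
      if (length(top) > 1L) ties <- c(ties, j)
      cons[j] <- syms[top[1L]]   # lexicographic: rows ordered A,C,G,T
    }
  }
  structure(list(consensus = paste(cons, collapse = ""), counts = counts,
                 tie_columns = ties, ids = ids),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("consensus_profile over %d rows, %d columns, %d tie column(s)\n",
              length(x$ids), nchar(x$consensus), length(x$tie_columns)))
  invisible(x)
}

#' Add a consensus row to an alignment and make it the reference
#'
#' @param alignment An `allele_alignment`.
#' @param profile A `consensus_profile` from [build_consensus()].
#' @param id Row id for the consensus (default `"consensus"`).
#' @return A new `allele_alignment` whose reference coordinate system is
#'   the ungapped consensus; gap-majority columns are excluded from
#'   reference numbering.
#' @export
add_consensus <- function(alignment, profile, id = "consensus") {
  if (id %in% names(alignment$rows)) stop("row id already present: ", id)
  rows <- c(stats::setNames(profile$consensus, id), alignment$rows)
  meta <- rbind(tibble::tibble(id = id, role = "reference",
                               ploidy_group = "unknown",
                               origin = NA_character_),
                alignment$meta[, c("id", "role", "ploidy_group", "origin")])
  new_allele_alignment(rows, ref_id = id, meta = meta,
                       scores = alignment$scores)
}
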