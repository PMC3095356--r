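#' Gene model: exon/intron structure in reference coordinates
#'
#' Intervals are 1-based and inclusive, in the coordinates of the
#' (consensus) reference sequence. The default model mirrors a two-exon
#' gene whose coding sequence of 4242 bp is interrupted by a single
#' 200 bp intron, for a genomic span of 4442 bp.
#'
#' @param exons A list of `c(start, end)` integer pairs, sorted and
#'   non-overlapping.
#' @return A `gene_model` object with fields `exons` (matrix), `introns`
#'   (matrix, possibly 0-row), `cds_length` and `span`.
#' @export
gene_model <- function(exons) {
  ex <- do.call(rbind, lapply(exons, function(e) as.integer(e[1:2])))
  colnames(ex) <- c("start", "end")
  if (any(ex[, "end"] < ex[, "start"])) stop("exon end before start")
  if (is.unsorted(ex[, "start"], strictly = TRUE)) stop("exons must be sorted")
  if (nrow(ex) > 1L && any(ex[-1L, "start"] <= ex[-nrow(ex), "end"])) {
    stop("exons overlap")
  }
  introns <- if (nrow(ex) > 1L) {
    cbind(start = ex[-nrow(ex), "end"] + 1L, end = ex[-1L, "start"] - 1L)
  } else {
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  }
  cds_length <- sum(ex[, "end"] - ex[, "start"] + 1L)
  if (cds_length %% 3L != 0L) {
    stop("total CDS length ", cds_length, " is not divisible by 3")
  }
  structure(list(exons = ex, introns = introns,
                 cds_length = cds_length,
                 span = c(min(ex[, "start"]), max(ex[, "end"]))),
            class = "gene_model")
}

#' Default two-exon gene model (4242 bp CDS, 200 bp intron)
#'
#' @param exon1_length Length of the first exon (default 2500 bp; the
#'   split of the 4242 bp CDS across the two exons is configurable, only
#'   the total is fixed by the gene).
#' @param intron_length Intron length (default 200 bp).
#' @param cds_length Total coding length (default 4242 bp).
#' @return A `gene_model`.
#' @export
default_gene_model <- function(exon1_length = 2500L, intron_length = 200L,
                               cds_length = 4242L) {
  e1 <- as.integer(exon1_length)
  gene_model(list(c(1L, e1),
                  c(e1 + intron_length + 1L, cds_length + intron_length)))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d exon(s), CDS %d bp, span %d-%d\n",
              nrow(x$exons), x$cds_length, x$span[1], x$span[2]))
  invisible(x)
}

#' Protein-domain partition of the coding sequence
#'
#' Returns the named domain intervals tiling the CDS, in CDS coordinates
#' (1-based, inclusive). Default lengths: CC 474, NBS 1062, interspacer
#' 198, LRR 2508 bp (474 + 1062 + 198 + 2508 = 4242). Individual LRR
#' repeat boundaries are not fixed by the gene annotation; with
#' `lrr_split = TRUE` the LRR region is cut into 28 approximately equal
#' slices labelled `LRR_1` ... `LRR_28` and flagged approximate.
#'
#' @param cc,nbs,interspacer,lrr Domain lengths in bp.
#' @param lrr_split Split the LRR region into 28 approximate repeats.
#' @return A tibble with columns `domain`, `start`, `end`, `approximate`.
#' @export
default_domain_map <- function(cc = 474L, nbs = 1062L, interspacer = 198L,
                               lrr = 2508L, lrr_split = FALSE) {
  lens <- c(CC = cc, NBS = nbs, Interspacer = interspacer, LRR = lrr)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  dm <- tibble::tibble(domain = names(lens), start = as.integer(starts),
                       end = as.integer(ends), approximate = FALSE)
  if (!lrr_split) return(dm)
  n <- 28L
  base <- lrr %/% n
  extra <- lrr %% n
  slice_len <- c(rep(base + 1L, extra), rep(base, n - extra))
  s_end <- dm$start[dm$domain == "LRR"] - 1L + cumsum(slice_len)
  s_start <- c(dm$start[dm$domain == "LRR"], utils::head(s_end, -1L) + 1L)
  lrr_rows <- tibble::tibble(domain = paste0("LRR_", seq_len(n)),
                             start = as.integer(s_start),
                             end = as.integer(s_end), approximate = TRUE)
  dplyr::bind_rows(dm[dm$domain != "LRR", ], lrr_rows)
}

validate_domain_map <- function(domain_map, cds_length) {
  dm <- domain_map[order(domain_map$start), ]
  if (dm$start[1L] != 1L || dm$end[nrow(dm)] != cds_length ||
      (nrow(dm) > 1L && any(dm$start[-1L] != dm$end[-nrow(dm)] + 1L))) {
    stop("domain map must tile the CDS without overlap or holes")
  }
  invisible(dm)
}

#' Splice the coding sequence out of a genomic sequence
#'
#' @param sequence Genomic (reference-coordinate) sequence string.
#' @param model A `gene_model`.
#' @return The concatenated exon subsequences (the CDS).
#' @export
splice_cds <- function(sequence, model) {
  if (nchar(sequence) < model$span[2]) {
    stop("sequence (", nchar(sequence), " bp) shorter than gene model span (",
         model$span[2], " bp)")
  }
  paste(vapply(seq_len(nrow(model$exons)), function(i) {
    substr(sequence, model$exons[i, "start"], model$exons[i, "end"])
  }, character(1)), collapse = "")
}

#' Map a reference position into CDS coordinates
#'
#' @param ref_pos Reference position(s), 1-based.
#' @param model A `gene_model`.
#' @return Integer CDS position(s); `NA` for intronic or non-coding
#'   positions.
#' @export
ref_to_cds <- function(ref_pos, model) {
  vapply(as.integer(ref_pos), function(p) {
    off <- 0L
    for (i in seq_len(nrow(model$exons))) {
      s <- model$exons[i, "start"]; e <- model$exons[i, "end"]
      if (p >= s && p <= e) return(off + (p - s + 1L))
      off <- off + (e - s + 1L)
    }
    NA_integer_
  }, integer(1))
}

#' Map a CDS position back to reference coordinates
#' @inheritParams ref_to_cds
#' @param cds_pos CDS position(s), 1-based.
#' @return Reference position(s).
#' @export
cds_to_ref <- function(cds_pos, model) {
  vapply(as.integer(cds_pos), function(p) {
    if (is.na(p) || p < 1L || p > model$cds_length) {
      stop("CDS position out of range: ", p)
    }
    off <- 0L
    for (i in seq_len(nrow(model$exons))) {
      len <- model$exons[i, "end"] - model$exons[i, "start"] + 1L
      if (p <= off + len) return(model$exons[i, "start"] + (p - off - 1L))
      off <- off + len
    }
    NA_integer_   # unreachable
  }, integer(1))
}

#' Classify a reference position as exonic, intronic or non-coding
#' @inheritParams ref_to_cds
#' @return Character vector over `{"exonic", "intronic", "noncoding"}`.
#' @export
region_of <- function(ref_pos, model) {
  vapply(as.integer(ref_pos), function(p) {
    if (!is.na(ref_to_cds(p, model))) return("exonic")
    if (nrow(model$introns) > 0L &&
        any(p >= model$introns[, "start"] & p <= model$introns[, "end"])) {
      return("intronic")
    }
    "noncoding"
  }, character(1))
}

#' Domain containing a CDS position
#'
#' @param cds_pos CDS position(s), 1-based.
#' @param domain_map Domain map tibble (see [default_domain_map()]).
#' @return Domain label(s).
#' @export
domain_of <- function(cds_pos, domain_map) {
  vapply(as.integer(cds_pos), function(p) {
    if (is.na(p) || p < 1L || p > max(domain_map$end)) {
      stop("CDS position out of range: ", p)
    }
    hit <- which(domain_map$start <= p & domain_map$end >= p)
    domain_map$domain[hit[1L]]
  }, character(1))
}

#' Codon index and within-codon offset of a CDS position
#'
#' @param cds_pos CDS position(s), 1-based.
#' @return A tibble with `codon_index` (= `ceiling(pos/3)`) and `offset`
#'   in `{1, 2, 3}`.
#' @export
codon_at <- function(cds_pos) {
  p <- as.integer(cds_pos)
  if (any(is.na(p)) || any(p < 1L)) stop("CDS position must be >= 1")
  tibble::tibble(codon_index = (p + 2L) %/% 3L,
                 offset = ((p - 1L) %% 3L) + 1L)
}

#' Read/write a gene model + domain map configuration as JSON
#'
#' @param path JSON file with fields `exons` (list of `[start, end]`) and
#'   `domains` (records with `domain`, `start`, `end`).
#' @return A list with `model` (a `gene_model`) and `domain_map`.
#' @export
read_gene_config <- function(path) {
  if (!file.exists(path)) stop("gene config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- gene_model(lapply(seq_len(nrow(cfg$exons)),
                             function(i) unlist(cfg$exons[i, ])))
  dm <- tibble::as_tibble(cfg$domains)
  if (!"approximate" %in% names(dm)) dm$approximate <- FALSE
  validate_domain_map(dm, model$cds_length)
  list(model = model, domain_map = dm)
}

#' @rdname read_gene_config
#' @param config A list with `model` and `domain_map`.
#' @export
write_gene_config <- function(config, path) {
  ex <- config$model$exons
  obj <- list(exons = as.data.frame(ex),
              domains = as.data.frame(config$domain_map))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
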