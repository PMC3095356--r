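# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations kept separate from the package code.

# Full affine-gap global alignment score (Gotoh), O(nm) in plain R.
# Gap of length L costs gap_open + L * gap_extend (penalties negative).
oracle_nw_score <- function(a, b, match = 1, mismatch = -2,
                            gap_open = -8, gap_extend = -1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in y (consumes x)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in x (consumes y)
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    X[i + 1, 1] <- gap_open + i * gap_extend
  }
  for (j in seq_len(m)) {
    Y[1, j + 1] <- gap_open + j * gap_extend
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == "N" || y[j] == "N") 0 else {
        if (x[i] == y[j]) match else mismatch
      }
      best_prev <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- best_prev + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force nucleotide diversity: literal all-pairs loop over rows of
# gapped strings.
oracle_pi <- function(rows) {
  mats <- strsplit(rows, "")
  n <- length(mats)
  tot <- 0; npairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- mats[[i]]; b <- mats[[j]]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      npairs <- npairs + 1
      if (any(ok)) tot <- tot + sum(a[ok] != b[ok]) / sum(ok)
    }
  }
  tot / npairs
}

oracle_translate <- function(codon) Biostrings::GENETIC_CODE[[codon]]

# Pathway-averaging oracle for a codon with exactly two changes at two
# distinct sites: enumerate the 2 substitution orders directly.
oracle_two_change <- function(codon, site1, alt1, site2, alt2) {
  step <- function(cod, site, alt) {
    before <- oracle_translate(cod)
    substr(cod, site, site) <- alt
    list(codon = cod, syn = oracle_translate(cod) == before)
  }
  # order 1: site1 then site2
  s1 <- step(codon, site1, alt1)
  s2 <- step(s1$codon, site2, alt2)
  path1 <- c(s1$syn, s2$syn)
  # order 2
  t1 <- step(codon, site2, alt2)
  t2 <- step(t1$codon, site1, alt1)
  path2 <- c(t1$syn, t2$syn)
  syn <- (sum(path1) + sum(path2)) / 2
  c(syn = syn, nonsyn = 2 - syn)
}

# random ungapped sequence
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# mutate a sequence with point substitutions at k distinct positions
mutate_seq <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  list(seq = paste(chars, collapse = ""), pos = sort(pos))
}

# a small aligned panel (equal-length gapless rows) for diversity tests
random_panel <- function(n_rows, len, n_mut_max = 4) {
  anc <- random_seq(len)
  rows <- vapply(seq_len(n_rows), function(i) {
    mutate_seq(anc, sample(0:n_mut_max, 1))$seq
  }, character(1))
  names(rows) <- paste0("s", seq_len(n_rows))
  rows
}

# minimal single-exon gene model + one-domain map for tiny CDS fixtures
tiny_model <- function(len) {
  list(model = gene_model(list(c(1L, as.integer(len)))),
       domain_map = tibble::tibble(domain = "CDS1", start = 1L,
                                   end = as.integer(len),
                                   approximate = FALSE))
}

# build an allele_alignment directly from ungapped equal-length rows,
# first row as reference
panel_alignment <- function(rows, ref_id = names(rows)[1]) {
  new_allele_alignment(rows, ref_id = ref_id)
}
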