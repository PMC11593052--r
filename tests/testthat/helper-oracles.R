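# shared helpers and independent brute-force oracles

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_str <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                      "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive codon-walk oracle: for one transcript, walk every codon of the
# given frame on the (reverse-complemented, for -k) sequence and record the
# forward-strand positions its three nucleotides came from
codon_walk_map <- function(sequence, frame) {
  L <- nchar(sequence)
  k <- abs(frame)
  src_pos <- if (frame > 0) seq_len(L) else rev(seq_len(L))
  off <- k - 1
  n_codons <- (L - off) %/% 3
  lapply(seq_len(n_codons), function(p) {
    idx <- off + (3 * (p - 1) + 1):(3 * p)
    fwd <- src_pos[idx]
    c(min(fwd), max(fwd))
  })
}

# brute-force ORF oracle: scan the nucleotide sequence codon-by-codon in
# each frame for start/stop pairs (one ORF per stop-delimited segment,
# first start codon), independent of the package's translation path
oracle_orfs <- function(sequence, min_aa = 25, start_rule = "ATG",
                        allow_open_end = TRUE) {
  code <- Biostrings::GENETIC_CODE
  revcomp <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
  out <- list()
  for (frame in c(1, 2, 3, -1, -2, -3)) {
    s <- if (frame > 0) sequence else revcomp
    off <- abs(frame) - 1
    n_codons <- (nchar(s) - off) %/% 3
    if (n_codons < 1) next
    codons <- substring(s, off + 3 * (seq_len(n_codons) - 1) + 1,
                        off + 3 * seq_len(n_codons))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    stops <- which(aa == "*")
    seg_start <- c(1, stops + 1)
    seg_end <- c(stops - 1, n_codons)
    terminated <- c(rep(TRUE, length(stops)), FALSE)
    for (i in seq_along(seg_start)) {
      a <- seg_start[i]; b <- seg_end[i]
      if (b < a) next
      if (!terminated[i] && !allow_open_end) next
      if (start_rule == "ATG") {
        ms <- which(codons[a:b] == "ATG")
        if (length(ms) == 0) next
        a <- a + ms[1] - 1
      }
      if (b - a + 1 < min_aa) next
      out[[length(out) + 1]] <- list(
        frame = frame, p_start = a, p_end = b,
        protein = paste(aa[a:b], collapse = ""))
    }
  }
  out
}

# brute-force window-scoring oracle for the built-in domain scanner
oracle_scan <- function(protein, profile) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hits <- list()
  if (!is.null(profile$motif)) {
    mchars <- strsplit(profile$motif, "", fixed = TRUE)[[1]]
    w <- length(mchars)
    if (n < w) return(hits)
    for (i in seq_len(n - w + 1)) {
      nm <- sum(chars[i:(i + w - 1)] == mchars)
      if (nm >= w - profile$max_mismatch) {
        hits[[length(hits) + 1]] <- c(start = i, end = i + w - 1)
      }
    }
  } else {
    w <- ncol(profile$pwm)
    if (n < w) return(hits)
    for (i in seq_len(n - w + 1)) {
      sc <- 0
      ok <- TRUE
      for (j in seq_len(w)) {
        r <- match(chars[i + j - 1], rownames(profile$pwm))
        if (is.na(r)) { ok <- FALSE; break }
        sc <- sc + profile$pwm[r, j]
      }
      if (ok && sc >= profile$threshold) {
        hits[[length(hits) + 1]] <- c(start = i, end = i + w - 1)
      }
    }
  }
  hits
}

# a minimal translations row for hand-built frame translations
fake_translation <- function(protein, frame = 1L, accession = "t1",
                             source_length = 3L * nchar(protein)) {
  tibble::tibble(accession = accession, frame = as.integer(frame),
                 framed_id = framed_id(accession, frame),
                 protein = protein, source_length = source_length)
}
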