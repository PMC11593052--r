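#' Six-frame conceptual translation of a transcriptome
#'
#' Translates every transcript in all six reading frames. Frames +1/+2/+3
#' start at forward-strand positions 1/2/3; frames -1/-2/-3 start at positions
#' 1/2/3 of the reverse complement. Trailing partial codons are dropped, so
#' the protein length of frame `±k` is `floor((L - (k - 1)) / 3)` for a
#' transcript of length `L`. Translation runs through internal stop codons
#' (emitted as `"*"`); segmentation at stops is the job of [find_orfs()],
#' because domain detection operates on whole-frame translations first.
#' Codons containing an ambiguity code that does not resolve to a unique
#' residue translate to `"X"`.
#'
#' @param transcripts Tibble with columns `accession`, `sequence`
#'   (as from [read_fasta()]).
#' @param genetic_code Name of an NCBI genetic-code table understood by
#'   [Biostrings::getGeneticCode()]; default `"Standard"`.
#' @return A tibble with exactly `6 * nrow(transcripts)` rows and columns
#'   `accession`, `frame`, `framed_id`, `protein`, `source_length`, ordered
#'   by input transcript then frame `+1,+2,+3,-1,-2,-3`.
#' @examples
#' six_frame_translate(tibble::tibble(accession = "t1", sequence = "ATGAAA"))
#' @export
six_frame_translate <- function(transcripts, genetic_code = "Standard") {
  check_transcripts(transcripts)
  code <- tryCatch(
    Biostrings::getGeneticCode(genetic_code, full.search = TRUE),
    error = function(e) stop("unknown genetic-code table: ", genetic_code,
                             call. = FALSE)
  )
  n <- nrow(transcripts)
  if (n == 0L) {
    return(tibble::tibble(accession = character(), frame = integer(),
                          framed_id = character(), protein = character(),
                          source_length = integer()))
  }
  dna <- Biostrings::DNAStringSet(transcripts$sequence)
  rc <- Biostrings::reverseComplement(dna)
  len <- Biostrings::width(dna)

  translate_frame <- function(f) {
    src <- if (f > 0L) dna else rc
    off <- abs(f) - 1L
    w <- pmax(0L, (len - off) %/% 3L) * 3L
    start <- ifelse(w > 0L, off + 1L, 1L)
    sub <- Biostrings::subseq(src, start = start, width = w)
    prot <- Biostrings::translate(sub, genetic.code = code,
                                  if.fuzzy.codon = "solve",
                                  no.init.codon = TRUE)
    tibble::tibble(accession = transcripts$accession, frame = f,
                   protein = as.character(prot), source_length = len)
  }

  out <- purrr::map(frame_levels(), translate_frame) |>
    purrr::list_rbind() |>
    dplyr::arrange(match(.data$accession, transcripts$accession),
                   frame_rank(.data$frame))
  out$framed_id <- framed_id(out$accession, out$frame)
  dplyr::relocate(out, "framed_id", .after = "frame")
}

#' Map protein coordinates on a reading frame to transcript nucleotides
#'
#' For frame `+k`, protein position `p` occupies forward-strand nucleotides
#' `[(k-1) + 3(p-1) + 1, (k-1) + 3p]` (1-based, inclusive). For frame `-k`
#' the codon interval is computed on the reverse complement and reported as
#' the corresponding forward-strand interval, so `nt_start <= nt_end` always.
#' [nucleotide_to_protein()] is the exact inverse on codon-aligned intervals.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param frame Frame label(s), in `c(1, 2, 3, -1, -2, -3)`.
#' @param source_length Length(s) of the parent transcript in nucleotides.
#' @param p_start,p_end 1-based protein interval on the frame translation.
#' @return A tibble with columns `nt_start`, `nt_end` (forward strand,
#'   1-based inclusive, span `3 * (p_end - p_start + 1)`).
#' @examples
#' protein_to_nucleotide(1L, 30L, 1L, 2L)  # [1, 6]
#' protein_to_nucleotide(2L, 30L, 1L, 1L)  # [2, 4]
#' @export
protein_to_nucleotide <- function(frame, source_length, p_start, p_end) {
  frame <- check_frame(frame)
  args <- vctrs_recycle(frame = frame, source_length = as.integer(source_length),
                        p_start = as.integer(p_start),
                        p_end = as.integer(p_end))
  with(args, {
    off <- abs(frame) - 1L
    plen <- pmax(0L, (source_length - off) %/% 3L)
    if (any(p_start < 1L | p_start > p_end | p_end > plen)) {
      stop("protein interval out of range for frame translation",
           call. = FALSE)
    }
    fs <- off + 3L * (p_start - 1L) + 1L
    fe <- off + 3L * p_end
    tibble::tibble(
      nt_start = ifelse(frame > 0L, fs, source_length - fe + 1L),
      nt_end   = ifelse(frame > 0L, fe, source_length - fs + 1L)
    )
  })
}

#' @rdname protein_to_nucleotide
#' @param nt_start,nt_end Forward-strand 1-based nucleotide interval; must be
#'   codon-aligned on the given frame.
#' @return For `nucleotide_to_protein()`, a tibble with columns `p_start`,
#'   `p_end`.
#' @export
nucleotide_to_protein <- function(frame, source_length, nt_start, nt_end) {
  frame <- check_frame(frame)
  args <- vctrs_recycle(frame = frame, source_length = as.integer(source_length),
                        nt_start = as.integer(nt_start),
                        nt_end = as.integer(nt_end))
  with(args, {
    off <- abs(frame) - 1L
    # convert the forward interval back to frame-local (reading-direction)
    # coordinates before inverting the codon formula
    fs <- ifelse(frame > 0L, nt_start, source_length - nt_end + 1L)
    fe <- ifelse(frame > 0L, nt_end, source_length - nt_start + 1L)
    if (any(nt_start < 1L | nt_end > source_length | nt_start > nt_end)) {
      stop("nucleotide interval out of range", call. = FALSE)
    }
    if (any((fs - off - 1L) %% 3L != 0L | (fe - fs + 1L) %% 3L != 0L)) {
      stop("nucleotide interval is not codon-aligned on this frame",
           call. = FALSE)
    }
    tibble::tibble(p_start = (fs - off - 1L) %/% 3L + 1L,
                   p_end   = (fe - off) %/% 3L)
  })
}

#' Reverse complement of nucleotide sequences
#'
#' @param sequence Character vector of nucleotide sequences (IUPAC codes
#'   allowed).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sequence)))
}

# minimal common-length recycling for scalar-or-vector coordinate arguments
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- lengths(args) != n & lengths(args) != 1L
  if (any(bad)) {
    stop("arguments must have length 1 or ", n, call. = FALSE)
  }
  lapply(args, function(x) if (length(x) == n) x else rep(x, n))
}
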