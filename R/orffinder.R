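#' ORF enumeration policy
#'
#' Controls how [find_orfs()] enumerates open reading frames. Defaults mirror
#' common ORF-finder settings: ORFs begin at an ATG (a methionine in the frame
#' translation), are at least 25 residues long (~75 nt), and an unterminated
#' ORF running into the 3' end of the frame is kept (flagged
#' `has_terminal_stop = FALSE`).
#'
#' Reported ORF lengths exclude the stop codon, so a 951-nt coding stretch
#' yields a 317-residue protein; this convention is used consistently in all
#' coordinates and lengths.
#'
#' @param start_rule `"ATG"` (ORF starts at the first methionine of a
#'   stop-delimited segment) or `"any"` (starts at the segment itself, i.e.
#'   any sense codon).
#' @param min_aa Minimum protein length in residues (default 25).
#' @param allow_open_end Keep ORFs with no terminal stop codon? Default TRUE.
#' @return An object of class `orf_policy`.
#' @export
orf_policy <- function(start_rule = c("ATG", "any"), min_aa = 25L,
                       allow_open_end = TRUE) {
  start_rule <- match.arg(start_rule)
  min_aa <- as.integer(min_aa)
  stopifnot(length(min_aa) == 1L, !is.na(min_aa), min_aa >= 1L,
            is.logical(allow_open_end), length(allow_open_end) == 1L)
  structure(list(start_rule = start_rule, min_aa = min_aa,
                 allow_open_end = allow_open_end),
            class = "orf_policy")
}

#' Enumerate open reading frames in frame translations
#'
#' Segments each whole-frame translation at stop codons and reports one ORF
#' per segment: from the first start codon under the policy's start rule to
#' the residue before the stop (nested ORFs sharing a stop collapse onto the
#' longest). ORFs are reported in all six frames — the domain-first method
#' evaluates all of them, not only the longest, because real domains are
#' found on non-longest ORFs.
#'
#' Within each transcript, ORFs are sorted by descending protein length, ties
#' broken by frame order `+1,+2,+3,-1,-2,-3`, then by 5' position within the
#' frame.
#'
#' @param translations Tibble from [six_frame_translate()] (columns
#'   `accession`, `frame`, `protein`, `source_length`).
#' @param policy An [orf_policy()].
#' @return Tibble with one row per ORF: `accession`, `frame`, `framed_id`,
#'   `protein_start`, `protein_end` (1-based positions on the frame
#'   translation), `nt_start`, `nt_end` (forward strand, stop codon excluded),
#'   `protein` (no `"*"`), `length_aa`, `has_terminal_stop`.
#' @export
find_orfs <- function(translations, policy = orf_policy()) {
  stopifnot(inherits(policy, "orf_policy"))
  req <- c("accession", "frame", "protein", "source_length")
  if (!is.data.frame(translations) || !all(req %in% names(translations))) {
    stop("`translations` must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  empty <- tibble::tibble(
    accession = character(), frame = integer(), framed_id = character(),
    protein_start = integer(), protein_end = integer(),
    nt_start = integer(), nt_end = integer(), protein = character(),
    length_aa = integer(), has_terminal_stop = logical())
  if (nrow(translations) == 0L) return(empty)

  rows <- purrr::pmap(
    list(translations$accession, translations$frame, translations$protein,
         translations$source_length),
    function(acc, frame, protein, source_length) {
      seg <- orf_segments(protein, policy)
      if (is.null(seg)) return(NULL)
      seg$accession <- acc
      seg$frame <- frame
      seg$source_length <- source_length
      seg
    })
  rows <- purrr::compact(rows)
  if (length(rows) == 0L) return(empty)
  out <- purrr::list_rbind(rows)
  nt <- protein_to_nucleotide(out$frame, out$source_length,
                              out$protein_start, out$protein_end)
  out$nt_start <- nt$nt_start
  out$nt_end <- nt$nt_end
  out$framed_id <- framed_id(out$accession, out$frame)
  out <- out |>
    dplyr::arrange(match(.data$accession, unique(translations$accession)),
                   dplyr::desc(.data$length_aa), frame_rank(.data$frame),
                   .data$protein_start) |>
    dplyr::select("accession", "frame", "framed_id", "protein_start",
                  "protein_end", "nt_start", "nt_end", "protein",
                  "length_aa", "has_terminal_stop")
  out
}

# one frame translation -> tibble of ORFs (protein coordinates only)
orf_segments <- function(protein, policy) {
  n <- nchar(protein)
  if (n == 0L) return(NULL)
  stops <- stringr::str_locate_all(protein, stringr::fixed("*"))[[1L]][, 1L]
  seg_start <- c(1L, stops + 1L)
  seg_end <- c(stops - 1L, n)
  terminated <- c(rep(TRUE, length(stops)), FALSE)
  keep <- seg_end >= seg_start
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  terminated <- terminated[keep]
  if (length(seg_start) == 0L) return(NULL)

  out <- purrr::pmap(list(seg_start, seg_end, terminated),
                     function(s, e, term) {
    if (!term && !policy$allow_open_end) return(NULL)
    if (policy$start_rule == "ATG") {
      seg <- substr(protein, s, e)
      m <- unname(stringr::str_locate(seg, stringr::fixed("M"))[1L, 1L])
      if (is.na(m)) return(NULL)
      s <- s + m - 1L
    }
    len <- e - s + 1L
    if (len < policy$min_aa) return(NULL)
    tibble::tibble(protein_start = s, protein_end = e,
                   protein = substr(protein, s, e),
                   length_aa = len, has_terminal_stop = term)
  })
  out <- purrr::compact(out)
  if (length(out) == 0L) return(NULL)
  purrr::list_rbind(out)
}

#' Longest ORF under the canonical sort order
#'
#' Returns the maximal-length ORF, ties broken by frame order
#' `+1,+2,+3,-1,-2,-3` then 5' position — the "longest ORF per transcript"
#' rule of classic annotation. With `by = "accession"` one row is returned
#' per transcript.
#'
#' @param orfs Tibble from [find_orfs()].
#' @param by `NULL` (a single overall winner) or `"accession"`.
#' @return A zero- or one-row tibble, or one row per group.
#' @export
longest_orf <- function(orfs, by = NULL) {
  if (nrow(orfs) == 0L) return(orfs)
  sorted <- dplyr::arrange(orfs, dplyr::desc(.data$length_aa),
                           frame_rank(.data$frame), .data$protein_start)
  if (is.null(by)) {
    dplyr::slice_head(sorted, n = 1L)
  } else {
    sorted |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::slice_head(n = 1L) |>
      dplyr::ungroup()
  }
}
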