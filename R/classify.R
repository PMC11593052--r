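#' Locate each domain hit inside an open reading frame
#'
#' A hit counts as "in an ORF" iff its protein interval lies entirely within
#' some ORF of the same transcript and frame; partial overlap (a hit
#' straddling an ORF boundary) does not count. Among multiple containing
#' ORFs the longest wins.
#'
#' @param hits Tibble of domain hits (columns `accession`, `frame`,
#'   `hit_start`, `hit_end`).
#' @param orfs Tibble from [find_orfs()].
#' @return `hits` with added columns `in_orf` (logical) and, for contained
#'   hits, the containing ORF's `orf_protein_start`, `orf_protein_end`,
#'   `orf_protein`, `orf_length_aa`.
#' @export
domain_in_orf <- function(hits, orfs) {
  hits <- dplyr::mutate(hits, .hit_row = dplyr::row_number())
  orf_cols <- orfs |>
    dplyr::select("accession", "frame",
                  orf_protein_start = "protein_start",
                  orf_protein_end = "protein_end",
                  orf_protein = "protein", orf_length_aa = "length_aa")
  contained <- hits |>
    dplyr::inner_join(orf_cols, by = c("accession", "frame"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$orf_protein_start <= .data$hit_start,
                  .data$hit_end <= .data$orf_protein_end) |>
    dplyr::arrange(dplyr::desc(.data$orf_length_aa),
                   .data$orf_protein_start) |>
    dplyr::distinct(.data$.hit_row, .keep_all = TRUE) |>
    dplyr::select(".hit_row", "orf_protein_start", "orf_protein_end",
                  "orf_protein", "orf_length_aa")
  out <- hits |>
    dplyr::left_join(contained, by = ".hit_row") |>
    dplyr::mutate(in_orf = !is.na(.data$orf_protein_start)) |>
    dplyr::select(-".hit_row")
  out
}

#' Merge two polypeptides split across transcripts
#'
#' Assembly can split one protein across two transcripts that share an exact
#' suffix-prefix polypeptide overlap at the junction. If a suffix of `a` of
#' length `>= min_overlap` exactly equals a prefix of `b` (either ordering;
#' the longest exact overlap wins, ties favouring a-then-b), the two are
#' merged with the overlap counted once.
#'
#' @param a,b Protein strings (no `"*"`).
#' @param min_overlap Minimum exact overlap in residues; default 8.
#' @return `NULL` if no qualifying overlap, else a list with `merged`,
#'   `overlap_peptide`, `overlap_length`, `order` (ids `c("a","b")` in merge
#'   order).
#' @examples
#' merge_split_transcripts("AAAHERKMRIAKEFS", "HERKMRIAKEFSGGG")
#' @export
merge_split_transcripts <- function(a, b, min_overlap = 8L) {
  min_overlap <- as.integer(min_overlap)
  stopifnot(min_overlap >= 1L, is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  k_ab <- longest_suffix_prefix(a, b, min_overlap)
  k_ba <- longest_suffix_prefix(b, a, min_overlap)
  if (k_ab == 0L && k_ba == 0L) return(NULL)
  if (k_ab >= k_ba) {
    list(merged = paste0(a, substr(b, k_ab + 1L, nchar(b))),
         overlap_peptide = substr(b, 1L, k_ab),
         overlap_length = k_ab, order = c("a", "b"))
  } else {
    list(merged = paste0(b, substr(a, k_ba + 1L, nchar(a))),
         overlap_peptide = substr(a, 1L, k_ba),
         overlap_length = k_ba, order = c("b", "a"))
  }
}

# length of the longest exact overlap where a suffix of x equals a prefix
# of y, 0 if shorter than kmin
longest_suffix_prefix <- function(x, y, kmin) {
  kmax <- min(nchar(x), nchar(y))
  if (kmax < kmin) return(0L)
  for (k in kmax:kmin) {
    if (substr(x, nchar(x) - k + 1L, nchar(x)) == substr(y, 1L, k)) {
      return(as.integer(k))
    }
  }
  0L
}

#' Find suffix-prefix merge partners among candidate ORF proteins
#'
#' Pairwise scan of the domain-bearing ORF proteins for exact suffix-prefix
#' overlaps (identical proteins are skipped — those are duplicates, not
#' split fragments).
#'
#' @param calls Tibble with columns `accession` and `orf_protein`.
#' @param min_overlap Minimum exact overlap in residues.
#' @return Tibble with one row per merged pair: `accession_a`,
#'   `accession_b` (in merge order), `overlap_peptide`, `overlap_length`,
#'   `merged_protein`.
#' @export
find_merge_partners <- function(calls, min_overlap = 8L) {
  empty <- tibble::tibble(accession_a = character(),
                          accession_b = character(),
                          overlap_peptide = character(),
                          overlap_length = integer(),
                          merged_protein = character())
  n <- nrow(calls)
  if (n < 2L) return(empty)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pa <- calls$orf_protein[i]; pb <- calls$orf_protein[j]
      if (is.na(pa) || is.na(pb) || pa == pb) next
      m <- merge_split_transcripts(pa, pb, min_overlap)
      if (is.null(m)) next
      first <- if (m$order[1L] == "a") i else j
      second <- if (m$order[1L] == "a") j else i
      out[[length(out) + 1L]] <- tibble::tibble(
        accession_a = calls$accession[first],
        accession_b = calls$accession[second],
        overlap_peptide = m$overlap_peptide,
        overlap_length = m$overlap_length,
        merged_protein = m$merged)
    }
  }
  if (length(out) == 0L) return(empty)
  purrr::list_rbind(out)
}

#' Detect a protein split across reading frames of one transcript
#'
#' An indel introduced during assembly can leave the N-terminus of a protein
#' in one reading frame of a transcript and the C-terminus in another. The
#' reference architecture is considered frame-split when its domains are
#' covered by in-ORF hits in at least two distinct frames of the same
#' transcript, with each frame covering a contiguous block of the reference
#' order and blocks not overlapping. Reference domains covered by no frame
#' are reported as the uncovered gap.
#'
#' @param frame_hits Tibble of in-ORF domain hits for ONE transcript:
#'   columns `frame`, `domain_name`, `hit_start`.
#' @param reference Non-empty character vector: reference architecture.
#' @return `NULL` if no split, else a list with `frames` (tibble `frame`,
#'   `ref_start`, `ref_end`, `domains` list-column) and `uncovered`
#'   (character vector of reference domains in no block).
#' @export
detect_frame_split <- function(frame_hits, reference) {
  if (length(reference) == 0L) {
    stop("`reference` architecture must be non-empty", call. = FALSE)
  }
  if (nrow(frame_hits) == 0L) return(NULL)
  per_frame <- frame_hits |>
    dplyr::arrange(frame_rank(.data$frame), .data$hit_start) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(arch = list(.data$domain_name), .groups = "drop")
  blocks <- purrr::pmap(list(per_frame$frame, per_frame$arch),
                        function(f, arch) {
    idx <- subsequence_match(arch, reference)
    if (is.null(idx)) return(NULL)
    # a frame must cover one contiguous run of the reference order
    if (length(idx) != max(idx) - min(idx) + 1L) return(NULL)
    tibble::tibble(frame = f, ref_start = min(idx), ref_end = max(idx),
                   domains = list(reference[min(idx):max(idx)]))
  })
  blocks <- purrr::compact(blocks)
  if (length(blocks) < 2L) return(NULL)
  blocks <- purrr::list_rbind(blocks) |> dplyr::arrange(.data$ref_start)
  if (any(blocks$ref_start[-1L] <= blocks$ref_end[-nrow(blocks)])) {
    return(NULL)  # overlapping blocks: not a clean split
  }
  covered <- unlist(purrr::map2(blocks$ref_start, blocks$ref_end, seq))
  uncovered <- setdiff(seq_along(reference), covered)
  list(frames = blocks, uncovered = reference[uncovered])
}

#' Assign the category of each domain-bearing transcript
#'
#' The three-way category system:
#' \describe{
#'   \item{1}{matched to a known protein: the best homology hit passes the
#'     criteria and every domain of that protein is present in the same
#'     arrangement (architecture full-match).}
#'   \item{2}{assembly error or truncated RNA: a passing hit exists but the
#'     architecture is partial — explained by a merge partner on another
#'     transcript, a frame split within the transcript, or plain
#'     truncation. A passing hit with a disjoint architecture is also
#'     category 2, with reason `"architecture-disjoint"` and `review = TRUE`.}
#'   \item{3}{no hit passed the criteria (`best_match` is `NA`).}
#' }
#' A transcript whose target-domain hit lies in no ORF is excluded from
#' categorisation (`category = NA`, reason `"hit-outside-orf"`). When
#' conflicting evidence arises (full-match AND a merge partner) category 1
#' wins and a warning is recorded in the `warning` column.
#'
#' @param evidence Tibble with one row per transcript and columns
#'   `accession`, `domain_in_orf` (logical), `best_match` (chr or NA),
#'   `best_passes` (logical), `architecture_verdict`, `missing_domains`
#'   (list), `merge_partner` (chr or NA), `overlap_peptide`, `frame_split`
#'   (list of NULL or split descriptions), `on_longest_orf`, `orf_protein`.
#' @return The evidence tibble with added `category` (integer, NA when
#'   excluded), `reason`, `review`, `warning` columns; `best_match` is
#'   cleared for category 3 rows.
#' @export
assign_category <- function(evidence) {
  stopifnot(all(c("accession", "domain_in_orf", "best_match", "best_passes",
                  "architecture_verdict", "merge_partner", "frame_split")
                %in% names(evidence)))
  n <- nrow(evidence)
  category <- rep(NA_integer_, n)
  reason <- character(n)
  review <- logical(n)
  warn <- rep(NA_character_, n)
  has_split <- vapply(evidence$frame_split, Negate(is.null), logical(1))
  has_merge <- !is.na(evidence$merge_partner)
  for (i in seq_len(n)) {
    if (!isTRUE(evidence$domain_in_orf[i])) {
      reason[i] <- "hit-outside-orf"
      next
    }
    if (!isTRUE(evidence$best_passes[i])) {
      category[i] <- 3L
      reason[i] <- "no-passing-match"
      next
    }
    verdict <- evidence$architecture_verdict[i]
    if (identical(verdict, "full-match")) {
      category[i] <- 1L
      reason[i] <- "full-architecture-match"
      if (has_merge[i]) {
        warn[i] <- "full-match but a merge partner was also found"
      }
    } else if (identical(verdict, "partial-subsequence")) {
      category[i] <- 2L
      reason[i] <- if (has_merge[i]) "split-across-transcripts"
        else if (has_split[i]) "frame-split"
        else "truncated"
    } else {
      category[i] <- 2L
      reason[i] <- "architecture-disjoint"
      review[i] <- TRUE
    }
  }
  out <- evidence
  out$category <- category
  out$reason <- reason
  out$review <- review
  out$warning <- warn
  out$best_match[!is.na(out$category) & out$category == 3L] <- NA_character_
  out
}

#' Collapse transcripts coding for the same protein to one identity
#'
#' Transcripts whose domain-bearing ORF proteins are exactly identical (the
#' amino-acid string, so silent nucleotide variants collapse) are counted as
#' one identity, represented by the lexicographically smallest accession.
#'
#' @param calls Tibble with columns `accession` and `orf_protein`.
#' @return List with `unique` (one representative row per identity),
#'   `duplicates` (tibble `representative`, `member` for the collapsed
#'   non-representatives) and `n_duplicates_removed`.
#' @export
dedup_unique_orfs <- function(calls) {
  if (nrow(calls) == 0L) {
    return(list(unique = calls,
                duplicates = tibble::tibble(representative = character(),
                                            member = character()),
                n_duplicates_removed = 0L))
  }
  grouped <- calls |>
    dplyr::group_by(.data$orf_protein) |>
    dplyr::mutate(.rep = min(.data$accession)) |>
    dplyr::ungroup()
  dup <- grouped |>
    dplyr::filter(.data$accession != .data$.rep) |>
    dplyr::select(representative = ".rep", member = "accession")
  uniq <- grouped |>
    dplyr::filter(.data$accession == .data$.rep) |>
    dplyr::select(-".rep")
  list(unique = uniq, duplicates = dup, n_duplicates_removed = nrow(dup))
}

#' Apply a contamination screen: remove and trim listed records
#'
#' Reproduces the arithmetic of a submission contamination screen: records
#' on the removal list are dropped, records on the trim list are truncated
#' to the retained interval but kept, so the output count is the input count
#' minus the number of removals. Removal takes precedence when a record is
#' on both lists.
#'
#' @param transcripts Transcript tibble.
#' @param remove_accessions Character vector of accessions to remove.
#' @param trim Optional tibble with columns `accession`, `start`, `end`
#'   (1-based inclusive retained interval).
#' @return List with `transcripts` (filtered/trimmed tibble), `n_input`,
#'   `n_removed`, `n_trimmed`, `n_output`.
#' @export
contamination_filter <- function(transcripts, remove_accessions = character(),
                                 trim = NULL) {
  check_transcripts(transcripts)
  unknown <- setdiff(remove_accessions, transcripts$accession)
  if (length(unknown) > 0L) {
    stop("removal list references unknown accession(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  n_input <- nrow(transcripts)
  n_trimmed <- 0L
  if (!is.null(trim) && nrow(trim) > 0L) {
    stopifnot(all(c("accession", "start", "end") %in% names(trim)))
    unknown <- setdiff(trim$accession, transcripts$accession)
    if (length(unknown) > 0L) {
      stop("trim list references unknown accession(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
    # removal dominates: do not bother trimming records slated for removal
    trim <- dplyr::filter(trim, !(.data$accession %in% remove_accessions))
    idx <- match(trim$accession, transcripts$accession)
    lens <- nchar(transcripts$sequence[idx])
    if (any(trim$start < 1L | trim$end > lens | trim$start > trim$end)) {
      stop("invalid trim interval(s)", call. = FALSE)
    }
    transcripts$sequence[idx] <- substr(transcripts$sequence[idx],
                                        trim$start, trim$end)
    n_trimmed <- nrow(trim)
  }
  out <- dplyr::filter(transcripts,
                       !(.data$accession %in% remove_accessions))
  list(transcripts = out, n_input = n_input,
       n_removed = length(unique(remove_accessions)),
       n_trimmed = n_trimmed, n_output = nrow(out))
}
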