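#' Homology match criteria
#'
#' The explicit thresholds a homology hit must meet to count as a match:
#' query coverage >= 50%, identity >= 30%, e-value <= 1e-5 by default. All
#' three boundaries are inclusive.
#'
#' @param min_query_coverage Minimum query coverage, percent (0-100).
#' @param min_identity Minimum percent identity (0-100).
#' @param max_evalue Maximum e-value (> 0).
#' @return An object of class `match_criteria`.
#' @export
match_criteria <- function(min_query_coverage = 50, min_identity = 30,
                           max_evalue = 1e-5) {
  stopifnot(is.numeric(min_query_coverage), min_query_coverage >= 0,
            min_query_coverage <= 100,
            is.numeric(min_identity), min_identity >= 0, min_identity <= 100,
            is.numeric(max_evalue), max_evalue > 0)
  structure(list(min_query_coverage = min_query_coverage,
                 min_identity = min_identity, max_evalue = max_evalue),
            class = "match_criteria")
}

#' Parse BLAST 12-column tabular output
#'
#' Reads the standard 12-column tabular alignment dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score). An optional 13th
#' column supplies query coverage directly; otherwise coverage is computed
#' as `100 * query alignment span / query length` from `query_lengths`.
#'
#' @param path Path to the tabular file.
#' @param query_lengths Optional named numeric vector of query lengths,
#'   used to compute coverage when no 13th column is present.
#' @return Tibble of homology hits with columns `query`, `subject`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`,
#'   `query_coverage`.
#' @export
parse_blast_tab <- function(path, query_lengths = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  empty <- tibble::tibble(
    query = character(), subject = character(), percent_identity = double(),
    alignment_length = integer(), mismatches = integer(),
    gap_opens = integer(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), evalue = double(),
    bitscore = double(), query_coverage = double())
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L & nf != 13L)
  if (length(bad) > 0L) {
    stop("expected 12 (or 13) tab-separated columns but found ", nf[bad[1L]],
         " at row ", bad[1L], " of ", path, call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:12]))
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    miss <- which(is.na(v))
    if (length(miss) > 0L) {
      stop("row ", miss[1L], ": cannot parse ", what, " value '",
           m[miss[1L], j], "'", call. = FALSE)
    }
    v
  }
  out <- tibble::tibble(
    query = m[, 1L], subject = m[, 2L],
    percent_identity = num(3L, "identity"),
    alignment_length = as.integer(num(4L, "alignment length")),
    mismatches = as.integer(num(5L, "mismatches")),
    gap_opens = as.integer(num(6L, "gap opens")),
    q_start = as.integer(num(7L, "query start")),
    q_end = as.integer(num(8L, "query end")),
    s_start = as.integer(num(9L, "subject start")),
    s_end = as.integer(num(10L, "subject end")),
    evalue = num(11L, "evalue"),
    bitscore = num(12L, "bitscore"))
  if (any(nf == 13L)) {
    cov <- rep(NA_real_, nrow(out))
    has13 <- nf == 13L
    cov[has13] <- suppressWarnings(
      as.numeric(vapply(fields[has13], `[`, character(1), 13L)))
    out$query_coverage <- cov
  } else if (!is.null(query_lengths)) {
    qlen <- query_lengths[out$query]
    if (anyNA(qlen)) {
      warning("query length missing for ",
              sum(is.na(qlen)), " row(s); coverage is NA", call. = FALSE)
    }
    out$query_coverage <- 100 * (abs(out$q_end - out$q_start) + 1) /
      as.numeric(qlen)
  } else {
    warning("no coverage column and no `query_lengths`; ",
            "query_coverage is NA", call. = FALSE)
    out$query_coverage <- NA_real_
  }
  out
}

#' Do homology hits pass the match criteria?
#'
#' A hit passes iff `query_coverage >= min_query_coverage`,
#' `percent_identity >= min_identity` and `evalue <= max_evalue` — all
#' boundaries inclusive. `NA` in any field fails (never passes silently).
#' The decision is monotone in each field.
#'
#' @param hits Tibble of homology hits (see [parse_blast_tab()]).
#' @param criteria A [match_criteria()].
#' @return Logical vector, one element per hit.
#' @export
passes_criteria <- function(hits, criteria = match_criteria()) {
  stopifnot(inherits(criteria, "match_criteria"))
  ok <- hits$query_coverage >= criteria$min_query_coverage &
    hits$percent_identity >= criteria$min_identity &
    hits$evalue <= criteria$max_evalue
  ok & !is.na(ok)
}

#' Best passing homology hit
#'
#' Among hits that pass the criteria, the best is the one with the lowest
#' e-value; ties broken by highest bit score, then highest identity. With
#' `by` given (e.g. `"query"`), one best hit is returned per group.
#'
#' @param hits Tibble of homology hits.
#' @param criteria A [match_criteria()].
#' @param by Optional grouping column name.
#' @return A tibble with zero rows if nothing passes, else one row (per
#'   group).
#' @export
best_hit <- function(hits, criteria = match_criteria(), by = NULL) {
  passing <- hits[passes_criteria(hits, criteria), , drop = FALSE]
  if (nrow(passing) == 0L) return(passing)
  sorted <- dplyr::arrange(passing, .data$evalue, dplyr::desc(.data$bitscore),
                           dplyr::desc(.data$percent_identity))
  if (is.null(by)) {
    dplyr::slice_head(sorted, n = 1L)
  } else {
    sorted |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::slice_head(n = 1L) |>
      dplyr::ungroup()
  }
}

#' Compare domain architectures
#'
#' A domain architecture is the ordered N-to-C list of domain names.
#' The candidate is a `"full-match"` iff it equals the reference exactly;
#' a `"partial-subsequence"` iff it is a proper ordered sublist of the
#' reference (gaps allowed, so a truncated protein still registers as
#' partial); `"disjoint"` otherwise. The reference domains absent from the
#' candidate are reported as `missing`.
#'
#' @param candidate Character vector of candidate domain names (N to C).
#' @param reference Non-empty character vector of reference domain names.
#' @return List with elements `verdict` (one of `"full-match"`,
#'   `"partial-subsequence"`, `"disjoint"`) and `missing` (character).
#' @examples
#' compare_architecture(c("SH3", "SH2"), c("SH3", "SH2", "Kinase"))
#' @export
compare_architecture <- function(candidate, reference) {
  if (length(reference) == 0L) {
    stop("`reference` architecture must be non-empty", call. = FALSE)
  }
  candidate <- as.character(candidate)
  reference <- as.character(reference)
  if (length(candidate) == length(reference) &&
      all(candidate == reference)) {
    return(list(verdict = "full-match", missing = character()))
  }
  matched <- subsequence_match(candidate, reference)
  if (!is.null(matched) && length(candidate) > 0L) {
    return(list(verdict = "partial-subsequence",
                missing = reference[-matched]))
  }
  list(verdict = "disjoint", missing = reference)
}

# greedy leftmost ordered-sublist matching: indices of `reference` consumed
# by `candidate`, or NULL if candidate is not an ordered sublist
subsequence_match <- function(candidate, reference) {
  if (length(candidate) == 0L) return(NULL)
  idx <- integer(length(candidate))
  j <- 1L
  for (i in seq_along(candidate)) {
    while (j <= length(reference) && reference[j] != candidate[i]) {
      j <- j + 1L
    }
    if (j > length(reference)) return(NULL)
    idx[i] <- j
    j <- j + 1L
  }
  idx
}

#' Self-contained local-alignment homology search
#'
#' Aligns each query against each subject with Smith-Waterman local
#' alignment (BLOSUM62, gap open 11, gap extend 1 — via
#' [Biostrings::pairwiseAlignment()]) and reports hits in the same tabular
#' shape as [parse_blast_tab()]. Bit scores use the standard
#' Karlin-Altschul conversion for gapped BLOSUM62 (`lambda = 0.267`,
#' `K = 0.041`) and `evalue = m * n * 2^-bits`. This is the package's
#' built-in alignment route for self-contained runs; externally produced
#' tabular files are equally accepted throughout.
#'
#' @param queries,subjects Tibbles with columns `id` and `protein`.
#' @param gap_opening,gap_extension Gap penalties.
#' @return Tibble of homology hits (one row per query/subject pair).
#' @export
align_homology <- function(queries, subjects, gap_opening = 11,
                           gap_extension = 1) {
  stopifnot(all(c("id", "protein") %in% names(queries)),
            all(c("id", "protein") %in% names(subjects)))
  if (nrow(queries) == 0L || nrow(subjects) == 0L) {
    return(tibble::tibble(
      query = character(), subject = character(),
      percent_identity = double(), alignment_length = integer(),
      mismatches = integer(), gap_opens = integer(),
      q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(),
      evalue = double(), bitscore = double(), query_coverage = double()))
  }
  mat <- blosum62_matrix()
  subj_set <- Biostrings::AAStringSet(subjects$protein)
  lambda <- 0.267; K <- 0.041
  purrr::pmap(list(queries$id, queries$protein),
              function(qid, qprot) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = subj_set, subject = qprot, type = "local",
      substitutionMatrix = mat, gapOpening = gap_opening,
      gapExtension = gap_extension)
    raw <- Biostrings::score(aln)
    bits <- (lambda * raw - log(K)) / log(2)
    qlen <- nchar(qprot)
    slen <- nchar(subjects$protein)
    q_rng_start <- BiocGenerics::start(Biostrings::subject(aln))
    q_rng_end <- BiocGenerics::end(Biostrings::subject(aln))
    s_rng_start <- BiocGenerics::start(Biostrings::pattern(aln))
    s_rng_end <- BiocGenerics::end(Biostrings::pattern(aln))
    tibble::tibble(
      query = qid, subject = subjects$id,
      percent_identity = Biostrings::pid(aln, type = "PID1"),
      alignment_length = Biostrings::nchar(aln),
      mismatches = Biostrings::nmismatch(aln),
      gap_opens = NA_integer_,
      q_start = q_rng_start, q_end = q_rng_end,
      s_start = s_rng_start, s_end = s_rng_end,
      evalue = pmin(qlen * slen * 2^(-bits), Inf),
      bitscore = bits,
      query_coverage = 100 * (q_rng_end - q_rng_start + 1) / qlen)
  }) |> purrr::list_rbind()
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
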