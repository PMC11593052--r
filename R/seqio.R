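#' Read a FASTA file into a tibble of transcripts
#'
#' Reads nucleotide or protein FASTA into the tabular form used throughout the
#' package: one row per record with `accession` (first whitespace-delimited
#' token of the header), `sequence` (uppercased) and `description` (remainder
#' of the header, possibly empty).
#'
#' Nucleotide input is canonicalised to a cDNA alphabet: sequences are
#' uppercased and `U` is mapped to `T`. IUPAC ambiguity codes (including `N`)
#' are retained and resolved at translation time, not rejected here.
#'
#' @param path Path to a FASTA file.
#' @param type `"nucleotide"` (default) or `"protein"`. Only affects the
#'   `U -> T` mapping.
#' @return A tibble with columns `accession`, `sequence`, `description`.
#' @examples
#' tmp <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "atgaaa"), tmp)
#' read_fasta(tmp)
#' @export
read_fasta <- function(path, type = c("nucleotide", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      # an empty file is a valid empty collection; anything else is malformed
      if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
        return(Biostrings::BStringSet())
      }
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    return(tibble::tibble(accession = character(), sequence = character(),
                          description = character()))
  }
  headers <- names(set)
  accession <- stringr::str_extract(headers, "^\\S+")
  description <- stringr::str_trim(stringr::str_remove(headers, "^\\S*"))
  sequence <- unname(toupper(as.character(set)))
  bad <- which(is.na(accession) | accession == "" | nchar(sequence) == 0L)
  if (length(bad) > 0L) {
    stop("malformed FASTA record(s) at index ",
         paste(bad, collapse = ", "), " in ", path,
         " (empty header or empty sequence)", call. = FALSE)
  }
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (type == "nucleotide") {
    sequence <- chartr("U", "T", sequence)
  }
  tibble::tibble(accession = accession, sequence = sequence,
                 description = description)
}

#' Write (identifier, sequence) records to FASTA
#'
#' Round-trips exactly with [read_fasta()] on `(accession, sequence)` pairs for
#' any alphabet used in this package (protein sequences containing `*` pass
#' through verbatim). Lines are wrapped at 60 columns.
#'
#' @param records A data frame with columns `accession` and `sequence`
#'   (a `description` column, if present, is appended to the header).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (!all(c("accession", "sequence") %in% names(records))) {
    stop("`records` must have columns `accession` and `sequence`",
         call. = FALSE)
  }
  dup <- unique(records$accession[duplicated(records$accession)])
  if (length(dup) > 0L) {
    stop("duplicate identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  headers <- records$accession
  if ("description" %in% names(records)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    headers[has_desc] <- paste(headers[has_desc],
                               records$description[has_desc])
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Frame-suffixed identifiers for translated records
#'
#' Translated frames are named `"<accession>_<frame>"` with an explicit sign,
#' e.g. `"GGEY02003111.1_-1"` for frame -1. `framed_id()` renders and
#' [parse_framed_id()] parses; the two are exact inverses for all six frames.
#'
#' @param accession Character vector of transcript accessions.
#' @param frame Integer vector of frames in `c(1, 2, 3, -1, -2, -3)`
#'   (recycled against `accession`).
#' @return Character vector of framed identifiers.
#' @examples
#' framed_id("GGEY02003111.1", -1L)
#' parse_framed_id("GGEY02003111.1_-1")
#' @export
framed_id <- function(accession, frame) {
  frame <- check_frame(frame)
  if (any(is.na(accession) | !nzchar(accession))) {
    stop("accession must be non-empty", call. = FALSE)
  }
  sprintf("%s_%+d", accession, frame)
}

#' @rdname framed_id
#' @param x Character vector of framed identifiers,
#'   e.g. `"GGEY02080031.1_+2"`.
#' @return For `parse_framed_id()`, a tibble with columns `accession` and
#'   `frame` (integer, signed).
#' @export
parse_framed_id <- function(x) {
  m <- stringr::str_match(x, "^(.+)_([+-][123])$")
  bad <- which(is.na(m[, 1L]))
  if (length(bad) > 0L) {
    stop("cannot parse framed identifier(s): ",
         paste(utils::head(x[bad], 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "",
         " (expected \"<accession>_<signed frame 1-3>\")", call. = FALSE)
  }
  tibble::tibble(accession = m[, 2L], frame = as.integer(m[, 3L]))
}

# frame vocabulary used everywhere: +1,+2,+3 start at forward positions 1/2/3;
# -1,-2,-3 start at positions 1/2/3 of the reverse complement
frame_levels <- function() c(1L, 2L, 3L, -1L, -2L, -3L)

check_frame <- function(frame) {
  frame <- as.integer(frame)
  if (any(is.na(frame)) || !all(frame %in% frame_levels())) {
    stop("frame must be one of +1,+2,+3,-1,-2,-3", call. = FALSE)
  }
  frame
}

frame_rank <- function(frame) match(frame, frame_levels())

check_transcripts <- function(transcripts) {
  if (!is.data.frame(transcripts) ||
      !all(c("accession", "sequence") %in% names(transcripts))) {
    stop("expected a transcript data frame with columns ",
         "`accession` and `sequence`", call. = FALSE)
  }
  dup <- unique(transcripts$accession[duplicated(transcripts$accession)])
  if (length(dup) > 0L) {
    stop("duplicate transcript accession(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(transcripts)
}
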