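#' Randomly split a six-frame proteome into batches
#'
#' Batch CD-Search-style services cap upload sizes, so the translated
#' proteome is randomly partitioned into files of at most `batch_size`
#' records (default 4000). The partition is a true partition — no record is
#' lost or duplicated — and is reproducible for a fixed seed.
#'
#' @param translations Tibble of frame translations (or any tibble of
#'   records to batch).
#' @param batch_size Maximum records per batch; default 4000.
#' @param seed Optional integer seed for the random permutation; `NULL`
#'   leaves the RNG state alone.
#' @return A list of tibbles, each with `<= batch_size` rows.
#' @export
split_batches <- function(translations, batch_size = 4000L, seed = NULL) {
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L) {
    stop("`batch_size` must be a positive integer", call. = FALSE)
  }
  n <- nrow(translations)
  if (n == 0L) return(list())
  perm <- if (is.null(seed)) {
    sample.int(n)
  } else {
    withr::with_seed(as.integer(seed), sample.int(n))
  }
  idx <- split(perm, ceiling(seq_len(n) / batch_size))
  lapply(unname(idx), function(i) translations[i, , drop = FALSE])
}

#' Write proteome batches to numbered FASTA files
#'
#' @param batches List of tibbles from [split_batches()]; each needs columns
#'   `framed_id` and `protein`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; files are `<prefix>_<i>.fa`.
#' @return Character vector of file paths, invisibly.
#' @export
write_batches <- function(batches, dir, prefix = "batch") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(batches, function(b, i) {
    p <- file.path(dir, sprintf("%s_%03d.fa", prefix, as.integer(i)))
    write_fasta(tibble::tibble(accession = b$framed_id,
                               sequence = b$protein), p)
    p
  })
  invisible(paths)
}

#' Parse a Batch CD-Search hit table
#'
#' Reads the NCBI Batch CD-Search "hits" tabular dialect: `#`-prefixed
#' comment lines, then a tab-separated header containing at least the
#' columns `Query`, `Hit type`, `From`, `To`, `E-Value`, `Bitscore`,
#' `Short name`. Query strings of the form `"Q#1 - ><id>"` are unwrapped,
#' and identifiers are parsed with the `"<accession>_<frame>"` grammar.
#' Rows whose query does not follow that grammar are kept with `NA`
#' accession/frame and reported with a warning, never silently dropped.
#'
#' Hit types (specific, non-specific, superfamily, ...) are preserved in
#' `hit_type` for downstream filtering; none are discarded here.
#'
#' @param path Path to a hit table.
#' @return Tibble of domain hits: `query`, `accession`, `frame`,
#'   `domain_name`, `hit_type`, `hit_start`, `hit_end`, `evalue`,
#'   `bitscore`, `source = "cdd-batch"` (plus `pssm_id`, `domain_accession`,
#'   `superfamily` when present).
#' @export
parse_cdd_hits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  cols_out <- tibble::tibble(
    query = character(), accession = character(), frame = integer(),
    domain_name = character(), hit_type = character(),
    hit_start = integer(), hit_end = integer(),
    evalue = double(), bitscore = double(), source = character())
  if (length(lines) == 0L) return(cols_out)
  tab <- suppressMessages(readr::read_tsv(
    I(paste(lines, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE))
  required <- c("Query", "Hit type", "From", "To", "E-Value", "Bitscore",
                "Short name")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("Batch CD-Search table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  query <- stringr::str_remove(tab$Query, "^Q#\\d+\\s*-\\s*>")
  parsed <- stringr::str_match(query, "^(.+)_([+-][123])$")
  unparsable <- is.na(parsed[, 1L])
  if (any(unparsable)) {
    warning(sum(unparsable), " hit row(s) have queries that do not follow ",
            "the <accession>_<frame> grammar; kept with NA accession/frame",
            call. = FALSE)
  }
  out <- tibble::tibble(
    query = query,
    accession = parsed[, 2L],
    frame = suppressWarnings(as.integer(parsed[, 3L])),
    domain_name = tab$`Short name`,
    hit_type = tab$`Hit type`,
    hit_start = as.integer(tab$From),
    hit_end = as.integer(tab$To),
    evalue = as.numeric(tab$`E-Value`),
    bitscore = as.numeric(tab$Bitscore),
    source = "cdd-batch")
  if ("PSSM-ID" %in% names(tab)) out$pssm_id <- tab$`PSSM-ID`
  if ("Accession" %in% names(tab)) out$domain_accession <- tab$Accession
  if ("Superfamily" %in% names(tab)) out$superfamily <- tab$Superfamily
  out
}

#' Define a domain profile for the built-in scanner
#'
#' A lightweight detector used in place of an external conserved-domain
#' search when the pipeline must run self-contained (tests, synthetic data).
#' Either an exact/approximate residue motif (with up to `max_mismatch`
#' mismatching positions) or a position-weight profile: a numeric matrix
#' with one column per position, rows named by residue, scored window-wise
#' against a finite threshold.
#'
#' @param name Short model name (e.g. `"SH2"`).
#' @param motif Residue string to match (mutually exclusive with `pwm`).
#' @param max_mismatch Mismatches tolerated for `motif`; default 0 (exact).
#' @param pwm Numeric matrix, rows = residues, columns = positions.
#' @param threshold Minimum window score for a `pwm` hit; must be finite.
#' @return An object of class `domain_profile`.
#' @export
domain_profile <- function(name, motif = NULL, max_mismatch = 0L,
                           pwm = NULL, threshold = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(motif) == is.null(pwm)) {
    stop("supply exactly one of `motif` or `pwm`", call. = FALSE)
  }
  if (!is.null(motif)) {
    stopifnot(is.character(motif), length(motif) == 1L, nchar(motif) >= 1L)
    max_mismatch <- as.integer(max_mismatch)
    stopifnot(max_mismatch >= 0L, max_mismatch < nchar(motif))
  } else {
    stopifnot(is.matrix(pwm), is.numeric(pwm), !is.null(rownames(pwm)),
              ncol(pwm) >= 1L)
    if (is.null(threshold) || !is.finite(threshold)) {
      stop("`threshold` must be a finite number for a pwm profile",
           call. = FALSE)
    }
  }
  structure(list(name = name, motif = motif,
                 max_mismatch = as.integer(max_mismatch),
                 pwm = pwm, threshold = threshold),
            class = "domain_profile")
}

#' Scan frame translations with built-in domain profiles
#'
#' Deterministic window scanner: every window of the profile's width whose
#' score reaches the profile's threshold yields a hit (for motifs, "score"
#' is the number of matching positions and the threshold is
#' `width - max_mismatch`). Residues outside the profile alphabet (such as
#' `"X"`) never match and score `-Inf` under a pwm, so untranslatable runs
#' produce no hits. Exact motifs (the common case) are located via fast
#' fixed-string search.
#'
#' @param translations Tibble with columns `accession`, `frame`, `protein`.
#' @param profiles A `domain_profile` or list of them; must be non-empty.
#' @return Tibble of domain hits with `source = "builtin"`; `bitscore` is
#'   twice the window score and `evalue = 2^-bitscore` (a deterministic
#'   stand-in scale, monotone in score).
#' @export
builtin_scan <- function(translations, profiles) {
  if (inherits(profiles, "domain_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) {
    stop("`profiles` must be non-empty", call. = FALSE)
  }
  stopifnot(all(vapply(profiles, inherits, logical(1), "domain_profile")))
  hits <- purrr::pmap(
    list(translations$accession, translations$frame, translations$protein),
    function(acc, frame, protein) {
      per_prof <- purrr::map(profiles, function(p) scan_one(protein, p))
      per_prof <- purrr::compact(per_prof)
      if (length(per_prof) == 0L) return(NULL)
      out <- purrr::list_rbind(per_prof)
      out$accession <- acc
      out$frame <- frame
      out
    })
  hits <- purrr::compact(hits)
  empty <- tibble::tibble(
    query = character(), accession = character(), frame = integer(),
    domain_name = character(), hit_type = character(),
    hit_start = integer(), hit_end = integer(),
    evalue = double(), bitscore = double(), source = character())
  if (length(hits) == 0L) return(empty)
  out <- purrr::list_rbind(hits)
  out$query <- framed_id(out$accession, out$frame)
  out$hit_type <- "builtin"
  out$source <- "builtin"
  dplyr::select(out, "query", "accession", "frame", "domain_name",
                "hit_type", "hit_start", "hit_end", "evalue", "bitscore",
                "source")
}

scan_one <- function(protein, profile) {
  n <- nchar(protein)
  if (!is.null(profile$motif)) {
    w <- nchar(profile$motif)
    if (n < w) return(NULL)
    if (profile$max_mismatch == 0L) {
      loc <- stringr::str_locate_all(protein,
                                     stringr::fixed(profile$motif))[[1L]]
      if (nrow(loc) == 0L) return(NULL)
      starts <- loc[, 1L]
      score <- rep(w, length(starts))
    } else {
      chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
      mchars <- strsplit(profile$motif, "", fixed = TRUE)[[1L]]
      nmatch <- vapply(seq_len(n - w + 1L), function(i) {
        sum(chars[i:(i + w - 1L)] == mchars)
      }, integer(1))
      keep <- nmatch >= w - profile$max_mismatch
      if (!any(keep)) return(NULL)
      starts <- which(keep)
      score <- nmatch[keep]
    }
  } else {
    w <- ncol(profile$pwm)
    if (n < w) return(NULL)
    chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
    ridx <- match(chars, rownames(profile$pwm))
    score_at <- vapply(seq_len(n - w + 1L), function(i) {
      rows <- ridx[i:(i + w - 1L)]
      if (anyNA(rows)) return(-Inf)
      sum(profile$pwm[cbind(rows, seq_len(w))])
    }, double(1))
    keep <- score_at >= profile$threshold
    if (!any(keep)) return(NULL)
    starts <- which(keep)
    score <- score_at[keep]
  }
  tibble::tibble(domain_name = profile$name,
                 hit_start = as.integer(starts),
                 hit_end = as.integer(starts + w - 1L),
                 bitscore = 2 * score,
                 evalue = 2^(-2 * score))
}

#' Select hits for the target domain
#'
#' Retains hits whose model short name contains the target token,
#' case-insensitively — so target `"SH2"` matches both `"SH2"` and
#' `"SH2 superfamily"` (superfamily-only transcripts are retained and
#' labelled downstream, not dropped). Idempotent and monotone.
#'
#' @param hits Tibble of domain hits.
#' @param target Non-empty domain-name token, default `"SH2"`.
#' @return The subset of `hits` naming the target.
#' @export
select_target_hits <- function(hits, target = "SH2") {
  stopifnot(is.character(target), length(target) == 1L)
  if (!nzchar(target)) stop("`target` must be non-empty", call. = FALSE)
  dplyr::filter(hits, stringr::str_detect(
    .data$domain_name, stringr::fixed(target, ignore_case = TRUE)))
}
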