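#' Run configuration with the method's default settings
#'
#' Collects every tunable of the pipeline in one place. The defaults are the
#' method's stated settings: match criteria of >=50% query coverage, >=30%
#' identity, e-value <= 1e-5; batch size 4000; ATG-start ORFs of >= 25
#' residues; target domain `"SH2"`; minimum exact merge overlap 8 residues.
#'
#' @param target Target domain-name token.
#' @param orf_policy An [orf_policy()].
#' @param criteria A [match_criteria()].
#' @param batch_size Proteome batch size for external domain searches.
#' @param min_overlap Minimum exact suffix-prefix overlap for merges.
#' @param seed Integer seed for the stages that randomise (batching).
#' @param genetic_code Genetic-code table name.
#' @return An object of class `run_config`.
#' @export
run_config <- function(target = "SH2", orf_policy = domainfirst::orf_policy(),
                       criteria = match_criteria(), batch_size = 4000L,
                       min_overlap = 8L, seed = 1L,
                       genetic_code = "Standard") {
  stopifnot(inherits(orf_policy, "orf_policy"),
            inherits(criteria, "match_criteria"))
  structure(list(target = target, orf_policy = orf_policy,
                 criteria = criteria, batch_size = as.integer(batch_size),
                 min_overlap = as.integer(min_overlap),
                 seed = as.integer(seed), genetic_code = genetic_code),
            class = "run_config")
}

#' Domain-first ("novel") annotation of a transcriptome
#'
#' The unbiased mode: translate every transcript in all six frames, detect
#' the target domain anywhere in the conceptual proteome, map hits back to
#' ORFs, match candidate ORFs against the reference panel, compare domain
#' architectures, detect split-across-transcripts and frame-split assembly
#' errors, classify every domain-bearing transcript, and deduplicate to
#' unique protein identities — with every funnel stage counted.
#'
#' Domain evidence comes either from an external Batch CD-Search-style hit
#' table (`hits`, see [parse_cdd_hits()]) or from the built-in scanner run
#' with the panel's profiles. Homology evidence comes either from an
#' external tabular file (`homology`, keyed by the candidate ORF's
#' `framed_id`) or from the built-in local aligner against the panel.
#'
#' @param transcripts Transcript tibble (see [read_fasta()]).
#' @param panel Reference-protein tibble with `protein_id`, `architecture`,
#'   `protein` (see [plant_reference_panel()]).
#' @param config A [run_config()].
#' @param hits Optional pre-parsed domain-hit tibble; `NULL` runs
#'   [builtin_scan()].
#' @param homology Optional pre-parsed homology-hit tibble; `NULL` runs
#'   [align_homology()].
#' @return An object of class `domain_run`: list with `calls` (one row per
#'   domain-bearing transcript), `funnel` (stage counts), `bins` (terminal
#'   bin per input transcript), `merges`, `duplicates`, `mode`, `config`.
#' @export
run_novel <- function(transcripts, panel, config = run_config(),
                      hits = NULL, homology = NULL) {
  stopifnot(inherits(config, "run_config"))
  check_transcripts(transcripts)
  if (is.null(hits) && (is.null(panel) || nrow(panel) == 0L)) {
    stop("novel mode needs either a domain-hit table or a reference panel ",
         "with built-in profiles", call. = FALSE)
  }

  n_input <- nrow(transcripts)
  translations <- six_frame_translate(transcripts,
                                      genetic_code = config$genetic_code)
  n_translated <- nrow(translations)

  if (is.null(hits)) {
    hits <- builtin_scan(translations, panel_profiles(panel))
  }
  target_hits <- select_target_hits(hits, config$target)
  hit_accessions <- unique(target_hits$accession)
  n_domain_hit <- length(hit_accessions)

  if (n_domain_hit == 0L) {
    return(new_domain_run(
      calls = empty_calls(), bins = terminal_bins(transcripts, character(),
                                                  empty_calls(),
                                                  dedup_none(), NULL),
      merges = find_merge_partners(empty_calls()),
      duplicates = dedup_none()$duplicates,
      funnel = funnel_tbl(n_input, n_translated, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      mode = "novel", config = config))
  }

  # ORFs for every frame of every domain-bearing transcript
  orfs <- find_orfs(
    dplyr::filter(translations, .data$accession %in% hit_accessions),
    config$orf_policy)

  hits_in <- domain_in_orf(dplyr::filter(hits,
                                         .data$accession %in% hit_accessions),
                           orfs)
  target_in <- select_target_hits(hits_in, config$target)

  # per transcript: the target hit whose containing ORF is longest
  candidates <- target_in |>
    dplyr::filter(.data$in_orf) |>
    dplyr::arrange(dplyr::desc(.data$orf_length_aa), .data$hit_start) |>
    dplyr::distinct(.data$accession, .keep_all = TRUE)
  outside <- setdiff(hit_accessions, candidates$accession)

  longest <- longest_orf(orfs, by = "accession")
  candidates <- candidates |>
    dplyr::left_join(dplyr::select(longest, "accession",
                                   longest_protein = "protein"),
                     by = "accession") |>
    dplyr::mutate(on_longest_orf =
                    .data$orf_protein == .data$longest_protein)

  # homology of each candidate ORF against the panel
  queries <- tibble::tibble(id = framed_id(candidates$accession,
                                           candidates$frame),
                            protein = candidates$orf_protein)
  hom <- if (is.null(homology)) {
    align_homology(queries,
                   tibble::tibble(id = panel$protein_id,
                                  protein = panel$protein))
  } else {
    homology
  }
  best <- best_hit(hom, config$criteria, by = "query")

  evidence <- candidates |>
    dplyr::mutate(query = framed_id(.data$accession, .data$frame)) |>
    dplyr::left_join(dplyr::select(best, "query", best_match = "subject",
                                   best_evalue = "evalue",
                                   best_identity = "percent_identity",
                                   best_coverage = "query_coverage"),
                     by = "query") |>
    dplyr::mutate(best_passes = !is.na(.data$best_match))

  # candidate architecture: all in-ORF hits on the candidate ORF, collapsed
  # to non-overlapping intervals (best bitscore first), N to C
  arch_info <- purrr::pmap(
    list(evidence$accession, evidence$frame, evidence$orf_protein_start,
         evidence$orf_protein_end, evidence$best_match),
    function(acc, frame, os, oe, bm) {
      mine <- dplyr::filter(hits_in, .data$accession == acc,
                            .data$frame == frame, .data$in_orf,
                            .data$hit_start >= os, .data$hit_end <= oe)
      cand <- collapse_architecture(mine)
      ref <- if (is.na(bm)) NULL else
        panel$architecture[[match(bm, panel$protein_id)]]
      cmp <- if (is.null(ref)) list(verdict = NA_character_,
                                    missing = character())
             else compare_architecture(cand, ref)
      list(candidate_architecture = cand, verdict = cmp$verdict,
           missing = cmp$missing, reference = ref)
    })
  evidence$candidate_architecture <-
    purrr::map(arch_info, "candidate_architecture")
  evidence$architecture_verdict <-
    purrr::map_chr(arch_info, "verdict")
  evidence$missing_domains <- purrr::map(arch_info, "missing")

  # split-across-transcripts evidence: merging explains a partial
  # architecture, so only partial-architecture candidates are scanned
  merges <- find_merge_partners(
    evidence |>
      dplyr::filter(.data$architecture_verdict %in% "partial-subsequence") |>
      dplyr::select("accession", "orf_protein"),
    config$min_overlap)
  partner_of <- c(stats::setNames(merges$accession_b, merges$accession_a),
                  stats::setNames(merges$accession_a, merges$accession_b))
  evidence$merge_partner <-
    unname(partner_of[evidence$accession])
  evidence$overlap_peptide <- dplyr::if_else(
    is.na(evidence$merge_partner), NA_character_,
    merges$overlap_peptide[match(
      pmin(evidence$accession, evidence$merge_partner),
      pmin(merges$accession_a, merges$accession_b))])

  # frame-split evidence against the best match's architecture
  evidence$frame_split <- purrr::pmap(
    list(evidence$accession, purrr::map(arch_info, "reference")),
    function(acc, ref) {
      if (is.null(ref)) return(NULL)
      fh <- hits_in |>
        dplyr::filter(.data$accession == acc, .data$in_orf) |>
        dplyr::select("frame", "domain_name", "hit_start")
      detect_frame_split(fh, ref)
    })

  calls <- assign_category(
    dplyr::bind_rows(
      dplyr::select(evidence, "accession", "frame", "framed_id" = "query",
                    "domain_name", "hit_start", "hit_end", "orf_protein",
                    "orf_protein_start", "orf_protein_end",
                    "on_longest_orf", "best_match", "best_evalue",
                    "best_identity", "best_coverage", "best_passes",
                    "candidate_architecture", "architecture_verdict",
                    "missing_domains", "merge_partner", "overlap_peptide",
                    "frame_split") |>
        dplyr::mutate(domain_in_orf = TRUE),
      tibble::tibble(accession = outside, domain_in_orf = FALSE,
                     best_match = NA_character_, best_passes = FALSE,
                     architecture_verdict = NA_character_,
                     merge_partner = NA_character_,
                     frame_split = vector("list", length(outside)))))

  dedup <- dedup_unique_orfs(
    dplyr::filter(calls, !is.na(.data$category)))
  bins <- terminal_bins(transcripts, hit_accessions, calls, dedup, merges)

  n_unique <- nrow(dedup$unique)
  merged_members <- unique(c(merges$accession_a, merges$accession_b))
  merged_reps <- dedup$unique$accession[dedup$unique$accession %in%
                                          merged_members]
  # each merge group collapses to one identity in the merged counting
  n_merge_collapsed <- if (nrow(merges) > 0L) {
    groups <- merge_groups(merges)
    sum(vapply(groups, function(g) {
      max(0L, sum(g %in% dedup$unique$accession) - 1L)
    }, integer(1)))
  } else 0L

  funnel <- funnel_tbl(
    n_input = n_input, n_translated = n_translated,
    n_domain_hit_transcripts = n_domain_hit,
    n_duplicates_removed = dedup$n_duplicates_removed,
    n_truncated_removed = n_merge_collapsed,
    n_hits_outside_orf = length(outside),
    n_unique_orfs = n_unique,
    n_unique_identities_merged = n_unique - n_merge_collapsed,
    n_on_non_longest_orf = sum(!calls$on_longest_orf, na.rm = TRUE))

  new_domain_run(calls = calls, funnel = funnel, bins = bins,
                 merges = merges, duplicates = dedup$duplicates,
                 mode = "novel", config = config)
}

# connected components of the merge-partner graph
merge_groups <- function(merges) {
  edges <- purrr::map2(merges$accession_a, merges$accession_b, c)
  groups <- list()
  for (e in edges) {
    hit <- which(vapply(groups, function(g) any(e %in% g), logical(1)))
    if (length(hit) == 0L) {
      groups[[length(groups) + 1L]] <- e
    } else {
      merged <- unique(c(unlist(groups[hit]), e))
      groups <- groups[-hit]
      groups[[length(groups) + 1L]] <- merged
    }
  }
  groups
}

# greedy interval collapse: keep best-scoring non-overlapping hits, N to C
collapse_architecture <- function(hits) {
  if (nrow(hits) == 0L) return(character())
  picked <- hits |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$hit_start)
  kept <- list()
  for (i in seq_len(nrow(picked))) {
    h <- picked[i, ]
    overlaps <- any(vapply(kept, function(k) {
      h$hit_start <= k$hit_end && k$hit_start <= h$hit_end
    }, logical(1)))
    if (!overlaps) kept[[length(kept) + 1L]] <- h
  }
  kept <- purrr::list_rbind(kept) |> dplyr::arrange(.data$hit_start)
  kept$domain_name
}

empty_calls <- function() {
  tibble::tibble(accession = character(), domain_in_orf = logical(),
                 best_match = character(), best_passes = logical(),
                 architecture_verdict = character(),
                 merge_partner = character(),
                 frame_split = list(), orf_protein = character(),
                 on_longest_orf = logical(), category = integer(),
                 reason = character(), review = logical(),
                 warning = character())
}

dedup_none <- function() {
  list(unique = tibble::tibble(accession = character(),
                               orf_protein = character()),
       duplicates = tibble::tibble(representative = character(),
                                   member = character()),
       n_duplicates_removed = 0L)
}

funnel_tbl <- function(n_input, n_translated, n_domain_hit_transcripts,
                       n_duplicates_removed, n_truncated_removed,
                       n_hits_outside_orf, n_unique_orfs,
                       n_unique_identities_merged, n_on_non_longest_orf) {
  tibble::tibble(
    n_input_transcripts = as.integer(n_input),
    n_translated = as.integer(n_translated),
    n_domain_hit_transcripts = as.integer(n_domain_hit_transcripts),
    n_duplicates_removed = as.integer(n_duplicates_removed),
    n_truncated_removed = as.integer(n_truncated_removed),
    n_hits_outside_orf = as.integer(n_hits_outside_orf),
    n_unique_orfs = as.integer(n_unique_orfs),
    n_unique_identities_merged = as.integer(n_unique_identities_merged),
    n_on_non_longest_orf = as.integer(n_on_non_longest_orf))
}

# every input transcript lands in exactly one terminal bin
terminal_bins <- function(transcripts, hit_accessions, calls, dedup,
                          merges) {
  bin <- stats::setNames(rep("no-domain", nrow(transcripts)),
                         transcripts$accession)
  excluded <- calls$accession[is.na(calls$category) &
                                calls$accession %in% names(bin)]
  bin[excluded] <- "hit-outside-orf"
  kept <- calls$accession[!is.na(calls$category)]
  bin[kept] <- "unique"
  bin[dedup$duplicates$member] <- "duplicate"
  if (!is.null(merges) && nrow(merges) > 0L) {
    for (g in merge_groups(merges)) {
      reps <- sort(g[g %in% dedup$unique$accession])
      if (length(reps) > 1L) bin[reps[-1L]] <- "merged-into-partner"
    }
  }
  tibble::tibble(accession = names(bin), bin = unname(bin))
}

new_domain_run <- function(calls, funnel, bins, merges, duplicates, mode,
                           config) {
  structure(list(calls = calls, funnel = funnel, bins = bins,
                 merges = merges, duplicates = duplicates, mode = mode,
                 config = config),
            class = "domain_run")
}

#' Classic target-driven annotation of a transcriptome
#'
#' For each reference protein in the panel, the transcriptome's ORFs are
#' searched for the best match under the criteria; a target is called on a
#' transcript only when the match passes AND all domains of the reference
#' are present on the ORF in the same arrangement (architecture
#' full-match). This is the biased counterpart of [run_novel()]: it can
#' only find what is on the target list.
#'
#' @inheritParams run_novel
#' @param homology Optional pre-computed homology tibble with `query` =
#'   reference `protein_id` and `subject` = ORF `framed_id`; `NULL` runs the
#'   built-in aligner (reference protein as query).
#' @return A `domain_run` with one call row per recovered target.
#' @export
run_classic <- function(transcripts, panel, config = run_config(),
                        homology = NULL) {
  stopifnot(inherits(config, "run_config"))
  check_transcripts(transcripts)
  if (is.null(panel) || nrow(panel) == 0L) {
    stop("classic mode needs a non-empty target-protein panel",
         call. = FALSE)
  }
  translations <- six_frame_translate(transcripts,
                                      genetic_code = config$genetic_code)
  orfs <- find_orfs(translations, config$orf_policy)
  if (nrow(orfs) == 0L) {
    calls <- tibble::tibble(protein_id = character(),
                            accession = character(),
                            framed_id = character(),
                            orf_protein = character(),
                            architecture_verdict = character(),
                            on_longest_orf = logical(),
                            category = integer())
    return(new_domain_run(calls = calls, funnel = NULL, bins = NULL,
                          merges = NULL, duplicates = NULL,
                          mode = "classic", config = config))
  }
  hom <- if (is.null(homology)) {
    align_homology(
      tibble::tibble(id = panel$protein_id, protein = panel$protein),
      tibble::tibble(id = orfs$framed_id, protein = orfs$protein))
  } else {
    homology
  }
  best <- best_hit(hom, config$criteria, by = "query")
  profiles <- panel_profiles(panel)
  longest <- longest_orf(orfs, by = "accession")

  empty_classic <- tibble::tibble(
    protein_id = character(), accession = character(),
    framed_id = character(), orf_protein = character(),
    architecture_verdict = character(), on_longest_orf = logical(),
    category = integer())
  if (nrow(best) == 0L) {
    return(new_domain_run(calls = empty_classic, funnel = NULL,
                          bins = NULL, merges = NULL, duplicates = NULL,
                          mode = "classic", config = config))
  }
  calls <- purrr::pmap(list(best$query, best$subject), function(pid, fid) {
    orf <- orfs[match(fid, orfs$framed_id), ]
    scan <- builtin_scan(tibble::tibble(accession = orf$accession,
                                        frame = orf$frame,
                                        protein = orf$protein),
                         profiles)
    cand <- collapse_architecture(scan)
    ref <- panel$architecture[[match(pid, panel$protein_id)]]
    cmp <- compare_architecture(cand, ref)
    tibble::tibble(protein_id = pid, accession = orf$accession,
                   framed_id = fid, orf_protein = orf$protein,
                   architecture_verdict = cmp$verdict,
                   on_longest_orf = orf$protein ==
                     longest$protein[match(orf$accession,
                                           longest$accession)],
                   category = if (cmp$verdict == "full-match") 1L
                              else 2L)
  }) |> purrr::list_rbind()
  # a classic call requires the full architecture
  calls <- dplyr::filter(calls, .data$architecture_verdict == "full-match")
  new_domain_run(calls = calls, funnel = NULL, bins = NULL, merges = NULL,
                 duplicates = NULL, mode = "classic", config = config)
}

#' Compare the transcript sets found by the two modes
#'
#' @param novel,classic `domain_run` objects (or call tibbles with an
#'   `accession` column). For the novel run, the identified set is every
#'   domain-bearing transcript whose hit lies in an ORF.
#' @return List of three disjoint accession sets partitioning the union:
#'   `shared`, `novel_only`, `classic_only`.
#' @export
venn_calls <- function(novel, classic) {
  acc_of <- function(x, novel_mode) {
    calls <- if (inherits(x, "domain_run")) x$calls else x
    if (nrow(calls) == 0L) return(character())
    if (novel_mode && "category" %in% names(calls)) {
      calls <- dplyr::filter(calls, !is.na(.data$category))
    }
    unique(calls$accession)
  }
  a <- acc_of(novel, TRUE)
  b <- acc_of(classic, FALSE)
  list(shared = sort(intersect(a, b)),
       novel_only = sort(setdiff(a, b)),
       classic_only = sort(setdiff(b, a)))
}

#' Write the outputs of a run to disk
#'
#' Writes the call table and funnel report as TSV, merged proteins as
#' FASTA, and a JSON snapshot of the full run configuration (including the
#' seed) beside them, so a run can be reproduced from its own record.
#'
#' @param run A `domain_run`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "domain_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  flat_calls <- run$calls |>
    dplyr::select(-dplyr::any_of(c("frame_split", "missing_domains",
                                   "candidate_architecture")))
  p <- file.path(dir, "calls.tsv")
  readr::write_tsv(flat_calls, p); files <- c(files, p)
  if (!is.null(run$funnel)) {
    p <- file.path(dir, "funnel.tsv")
    readr::write_tsv(run$funnel, p); files <- c(files, p)
  }
  if (!is.null(run$bins)) {
    p <- file.path(dir, "terminal_bins.tsv")
    readr::write_tsv(run$bins, p); files <- c(files, p)
  }
  if (!is.null(run$merges) && nrow(run$merges) > 0L) {
    p <- file.path(dir, "merged_proteins.fa")
    write_fasta(tibble::tibble(
      accession = paste0(run$merges$accession_a, "+",
                         run$merges$accession_b),
      sequence = run$merges$merged_protein), p)
    files <- c(files, p)
  }
  p <- file.path(dir, "run_config.json")
  cfg <- run$config
  cfg$orf_policy <- unclass(cfg$orf_policy)
  cfg$criteria <- unclass(cfg$criteria)
  jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}

#' @export
print.domain_run <- function(x, ...) {
  cat("<domain_run: ", x$mode, " mode>\n", sep = "")
  if (!is.null(x$funnel)) {
    f <- x$funnel
    cat("  transcripts in:        ", f$n_input_transcripts, "\n")
    cat("  six-frame records:     ", f$n_translated, "\n")
    cat("  domain-hit transcripts:", f$n_domain_hit_transcripts, "\n")
    cat("  hits outside any ORF:  ", f$n_hits_outside_orf, "\n")
    cat("  duplicates removed:    ", f$n_duplicates_removed, "\n")
    cat("  unique domain ORFs:    ", f$n_unique_orfs,
        " (", f$n_unique_identities_merged, " counting merged pairs once)\n",
        sep = "")
  } else {
    cat("  calls: ", nrow(x$calls), "\n")
  }
  invisible(x)
}

#' Tidy the calls of a run
#'
#' `tidy()` returns the call table (one row per domain-bearing transcript);
#' `glance()` returns the one-row funnel summary.
#'
#' @param x A `domain_run`.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy
#' @method tidy domain_run
#' @export
tidy.domain_run <- function(x, ...) {
  x$calls |>
    dplyr::select(-dplyr::any_of(c("frame_split", "missing_domains",
                                   "candidate_architecture")))
}

#' @rdname tidy.domain_run
#' @importFrom generics glance
#' @method glance domain_run
#' @export
glance.domain_run <- function(x, ...) {
  if (is.null(x$funnel)) {
    tibble::tibble(mode = x$mode, n_calls = nrow(x$calls))
  } else {
    dplyr::mutate(x$funnel, mode = x$mode, .before = 1L)
  }
}

#' Funnel plot for a run
#'
#' Bar chart of the stage counts of the annotation funnel.
#'
#' @param object A `domain_run` with a funnel (novel mode).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot domain_run
#' @export
autoplot.domain_run <- function(object, ...) {
  if (is.null(object$funnel)) {
    stop("no funnel to plot for a ", object$mode, " run", call. = FALSE)
  }
  df <- tidyr::pivot_longer(object$funnel, dplyr::everything(),
                            names_to = "stage", values_to = "count") |>
    dplyr::mutate(stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), hjust = -0.15,
                       size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(c(0, 0.12))) +
    ggplot2::labs(x = "records", y = NULL,
                  title = "Domain-first annotation funnel") +
    ggplot2::theme_minimal()
}

#' Set-overlap plot for the two annotation modes
#'
#' @param venn Output of [venn_calls()].
#' @return A ggplot object.
#' @export
plot_venn <- function(venn) {
  df <- tibble::tibble(
    set = factor(c("shared", "novel only", "classic only"),
                 levels = c("shared", "novel only", "classic only")),
    count = c(length(venn$shared), length(venn$novel_only),
              length(venn$classic_only)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "transcripts",
                  title = "Novel vs classic annotation") +
    ggplot2::theme_minimal()
}
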