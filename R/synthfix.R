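# Synthetic domain peptides: fixed, methionine-free stand-ins for conserved
# domain models, so that (a) exact-motif scanning is deterministic and (b)
# every start codon in a planted protein is placed deliberately (all M
# residues live in linkers). These are synthetic sequences, not real domain
# consensi.
synthetic_domain_peptides <- function() {
  c(
    SH2 = "HVRKGGQPCSVFPPVPECQRNKKRFECQRSRSKDCCHETECRRTR",
    SH3 = "VELPVGCIDKIQECGNPTWSNFHFSGYVNEPARVCSLKCC",
    KIN = "PNVFKQAVFAQWHRYQCNCNSKVDGWLWWLKQFGGIHDFRGNRARECWRHNAHPANHWNT",
    PLC = "IERINNGPYGYYPDIRDNPENNCEWWLELGRCNATGHCIAIEYAALARGT",
    C2  = "SSGEEFKWPTYEDETWICNAKSYVVTINNCPDESNHDAGVTI",
    WW  = "HGTDSCGCACWFQLGAEYWDHKAQPRRHERNKGA",
    SAM = "DQSSNKIWHYGVQREAGTDLSSLDLVWDGCACHYKEINAIPLHIGFIN",
    PHA = "DRSNKYENHELRNGRIWEDILHSEDFLFLSAQHPWCGTWSIEVT",
    FN3 = "EFEDGVDWLKTHTDNACWYNDIKKNAWAWLTATKIAVVAG",
    ANK = "KSNTYICEKNYAFAIECAHPSSCAYNVVVTQICPACLP"
  )
}

# Inter-domain linker; the M at position 3 is the canonical internal start
# codon used by split/frameshift plants. The tail varies deterministically
# with (protein, position) so that unrelated synthetic proteins never share
# long suffix-prefix overlaps through their linkers.
synthetic_linker <- function(protein_id, i) {
  alpha <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1L]]  # M-free
  h <- sum(utf8ToInt(protein_id)) * 31L + i * 7L
  tail <- alpha[(h + (1:7) * 5L) %% length(alpha) + 1L]
  paste0("GS", "M", paste(tail, collapse = ""))
}

# architectures of the synthetic protein set; NOVL1 is deliberately absent
# from the default reference panel so it plays the "novel protein" role
synthetic_architectures <- function() {
  list(
    SRCK1 = c("SH3", "SH2", "KIN"),
    PLCG1 = c("PLC", "SH2", "SH2", "SH3", "C2"),
    ADAP1 = c("SH2"),
    WWS1  = c("WW", "SH2"),
    BLNK1 = c("SAM", "PHA", "SH2"),
    NOVL1 = c("SH2", "FN3", "ANK")
  )
}

# protein = M + linker + D1 + linker + D2 + ... ; returns the string plus
# the residue position of the linker M immediately preceding each domain
build_synthetic_protein <- function(architecture, protein_id = "P") {
  peps <- synthetic_domain_peptides()
  unknown <- setdiff(architecture, names(peps))
  if (length(unknown) > 0L) {
    stop("no synthetic peptide for domain(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  protein <- "M"
  pre_m <- integer(length(architecture))  # linker-M position before domain i
  dom_start <- integer(length(architecture))
  for (i in seq_along(architecture)) {
    pre_m[i] <- nchar(protein) + 3L  # M sits at linker position 3
    protein <- paste0(protein, synthetic_linker(protein_id, i),
                      peps[[architecture[i]]])
    dom_start[i] <- nchar(protein) - nchar(peps[[architecture[i]]]) + 1L
  }
  list(protein = protein, pre_m = pre_m, dom_start = dom_start)
}

#' Reference panel of synthetic target proteins
#'
#' A small stand-in for a curated list of target proteins with known domain
#' architectures (a kinase-like `[SH3, SH2, KIN]`, a phospholipase-like
#' multi-domain protein, a bare `[SH2]` adaptor, `[WW, SH2]`, and a
#' `[SAM, PHA, SH2]` adaptor). All sequences are synthetic, assembled from
#' the package's synthetic domain peptides.
#'
#' @param proteins Character vector of panel member ids; must be non-empty
#'   and drawn from the synthetic set (`SRCK1`, `PLCG1`, `ADAP1`, `WWS1`,
#'   `BLNK1`, `NOVL1`).
#' @return Tibble with columns `protein_id`, `architecture` (list of
#'   character vectors, N to C) and `protein`.
#' @export
plant_reference_panel <- function(proteins = c("SRCK1", "PLCG1", "ADAP1",
                                               "WWS1", "BLNK1")) {
  if (length(proteins) == 0L) {
    stop("the reference panel must be non-empty", call. = FALSE)
  }
  archs <- synthetic_architectures()
  unknown <- setdiff(proteins, names(archs))
  if (length(unknown) > 0L) {
    stop("unknown synthetic protein(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    protein_id = proteins,
    architecture = unname(archs[proteins]),
    protein = vapply(proteins, function(p) {
      build_synthetic_protein(archs[[p]], p)$protein
    }, character(1), USE.NAMES = FALSE))
}

#' Exact-motif profiles for every domain in a reference panel
#'
#' @param panel Tibble from [plant_reference_panel()].
#' @return List of [domain_profile()]s, one per distinct domain name.
#' @export
panel_profiles <- function(panel) {
  doms <- unique(unlist(panel$architecture))
  peps <- synthetic_domain_peptides()
  purrr::map(doms, function(d) domain_profile(d, motif = peps[[d]]))
}

#' Specification of a synthetic transcriptome with planted ground truth
#'
#' Describes a seeded synthetic transcriptome: GC-balanced background
#' transcripts plus planted protein-coding features with known category
#' outcomes. Plant types:
#' \describe{
#'   \item{intact}{full-length coding sequence; expected category 1.}
#'   \item{split}{the protein split across two transcripts sharing an exact
#'     suffix-prefix overlap (`split_overlap` residues, default 12) at an
#'     internal start codon; both expected category 2 with each other as
#'     merge partner.}
#'   \item{frameshift}{an engineered junction places the last domain of the
#'     protein in a different reading frame of the same transcript (the
#'     N-terminal ORF is the longer one); expected category 2 via frame
#'     split, with the target-domain ORF not the longest.}
#'   \item{truncated}{only a prefix of the architecture is planted;
#'     expected category 2 via partial architecture.}
#'   \item{duplicate}{an exact copy of the coding sequence of the matching
#'     intact plant on a new transcript; collapses at deduplication.}
#'   \item{outside_orf}{the target-domain peptide is encoded with no start
#'     codon in its stop-delimited segment, so the hit lies in no ORF;
#'     excluded with reason `"hit-outside-orf"`.}
#'   \item{novel}{a protein whose architecture is absent from the reference
#'     panel; expected category 3.}
#' }
#'
#' @param n_background Number of background (non-coding) transcripts.
#' @param length_range Uniform bounds on background transcript length (nt).
#' @param plants Tibble with columns `protein_id`, `frame`, `type`; the
#'   default covers every plant type above.
#' @param n_contaminants Number of additional transcripts flagged as
#'   contaminants in the ground truth (for screen tests).
#' @param gc GC fraction of background/flank sequence; default 0.5.
#' @param split_overlap Exact overlap length for split plants; default 12.
#' @param seed Integer seed; a fixed seed makes [generate_transcriptome()]
#'   byte-identical.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(n_background = 60L,
                       length_range = c(300L, 900L),
                       plants = default_plants(),
                       n_contaminants = 0L,
                       gc = 0.5,
                       split_overlap = 12L,
                       seed = 1L) {
  stopifnot(n_background >= 0L, length(length_range) == 2L,
            length_range[1L] >= 30L, length_range[1L] <= length_range[2L],
            n_contaminants >= 0L, gc > 0, gc < 1, split_overlap >= 1L,
            is.numeric(seed), length(seed) == 1L)
  if (nrow(plants) > 0L) {
    stopifnot(all(c("protein_id", "frame", "type") %in% names(plants)))
    check_frame(plants$frame)
    types <- c("intact", "split", "frameshift", "truncated", "duplicate",
               "outside_orf", "novel")
    bad <- setdiff(plants$type, types)
    if (length(bad) > 0L) {
      stop("unknown plant type(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    archs <- synthetic_architectures()
    unknown <- setdiff(plants$protein_id, names(archs))
    if (length(unknown) > 0L) {
      stop("unknown synthetic protein(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_background = as.integer(n_background),
                 length_range = as.integer(length_range),
                 plants = plants,
                 n_contaminants = as.integer(n_contaminants),
                 gc = gc, split_overlap = as.integer(split_overlap),
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' @rdname plant_spec
#' @export
default_plants <- function() {
  tibble::tibble(
    protein_id = c("SRCK1", "ADAP1", "WWS1", "BLNK1", "PLCG1", "SRCK1",
                   "BLNK1", "SRCK1", "ADAP1", "NOVL1"),
    frame = c(2L, -1L, 3L, 1L, -2L, 1L, -1L, 1L, 2L, -3L),
    type = c("intact", "intact", "intact", "intact", "split", "truncated",
             "frameshift", "duplicate", "outside_orf", "novel"))
}

# One fixed codon per residue; ATG appears only for M and no codon is a
# stop. L = TTA and S = TCA read as TAA/TGA on the codon-aligned reverse
# frame, so planted coding regions do not leave long stop-free phantom ORFs
# on the opposite strand.
codon_table <- function() {
  c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
    E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "TTA", K = "AAA",
    M = "ATG", F = "TTT", P = "CCT", S = "TCA", T = "ACT", W = "TGG",
    Y = "TAT", V = "GTT")
}

#' Reverse-translate a protein with the generator's fixed codon table
#'
#' @param protein Protein string (20 standard residues).
#' @return Nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein) {
  tab <- codon_table()
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  codons <- tab[chars]
  if (anyNA(codons)) {
    stop("cannot reverse-translate residue(s): ",
         paste(unique(chars[is.na(codons)]), collapse = ", "),
         call. = FALSE)
  }
  paste(codons, collapse = "")
}

# uniform integers on [lo, hi], robust to lo == hi
sample_int_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# vectorised random DNA of (possibly unequal) lengths
random_dna <- function(n, lengths, gc) {
  if (n == 0L) return(character())
  maxlen <- max(lengths)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  cols <- lapply(seq_len(maxlen), function(i) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
  })
  full <- do.call(paste0, cols)
  substr(full, 1L, lengths)
}

# Wrap a coding insert into a transcript so that the insert starts at the
# requested frame. The insert is always preceded by an in-frame TAA so no
# upstream start codon can extend the planted ORF. For negative frames the
# forward construction is reverse-complemented whole.
embed_insert <- function(insert, frame, gc) {
  k <- abs(frame)
  left_len <- sample(20:80, 1L)
  left_len <- left_len + ((k - 1L) - left_len) %% 3L
  right_len <- sample(20:80, 1L)
  fwd <- paste0(random_dna(1L, left_len, gc), "TAA", insert,
                random_dna(1L, right_len, gc))
  if (frame > 0L) fwd else reverse_complement(fwd)
}

#' Generate a synthetic transcriptome with planted ground truth
#'
#' Deterministic for a fixed seed (byte-identical regeneration). Every
#' planted feature is recorded in a ground-truth table: accession(s), the
#' reading frame(s), the planted ORF protein, the expected category, and —
#' for split plants — the merge partner and the exact overlap peptide.
#'
#' @param spec A [plant_spec()].
#' @return List with `transcripts` (tibble `accession`, `sequence`,
#'   `description`), `truth` (one row per transcript), and `panel` (the
#'   default reference panel, for convenience).
#' @export
generate_transcriptome <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  withr::with_seed(spec$seed, generate_impl(spec))
}

generate_impl <- function(spec) {
  archs <- synthetic_architectures()
  rows <- list()     # transcript rows
  truths <- list()   # ground-truth rows
  acc_i <- 0L
  next_acc <- function() {
    acc_i <<- acc_i + 1L
    sprintf("SYNT%07d.1", acc_i)
  }
  add <- function(sequence, description, truth) {
    acc <- next_acc()
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      accession = acc, sequence = sequence, description = description)
    truth$accession <- acc
    truths[[length(truths) + 1L]] <<- truth
    acc
  }
  truth_row <- function(role, protein_id = NA_character_,
                        type = NA_character_, frame = NA_integer_,
                        frame2 = NA_integer_, orf_protein = NA_character_,
                        category_expected = NA_integer_,
                        merge_partner = NA_character_,
                        overlap_peptide = NA_character_,
                        exclusion_reason = NA_character_) {
    tibble::tibble(role = role, protein_id = protein_id, type = type,
                   frame = frame, frame2 = frame2,
                   orf_protein = orf_protein,
                   category_expected = category_expected,
                   merge_partner = merge_partner,
                   overlap_peptide = overlap_peptide,
                   exclusion_reason = exclusion_reason)
  }

  # background and contaminants (bulk-generated; contaminants are
  # background-like transcripts flagged for contamination-screen tests)
  bulk <- function(n, role, description) {
    if (n == 0L) return()
    lens <- sample_int_range(spec$length_range[1L], spec$length_range[2L],
                             n)
    acc <- sprintf("SYNT%07d.1", acc_i + seq_len(n))
    acc_i <<- acc_i + n
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      accession = acc, sequence = random_dna(n, lens, spec$gc),
      description = description)
    truths[[length(truths) + 1L]] <<- tibble::tibble(
      role = role, protein_id = NA_character_, type = NA_character_,
      frame = NA_integer_, frame2 = NA_integer_,
      orf_protein = NA_character_, category_expected = NA_integer_,
      merge_partner = NA_character_, overlap_peptide = NA_character_,
      exclusion_reason = NA_character_, accession = acc)
  }
  bulk(spec$n_background, "background", "synthetic background")
  bulk(spec$n_contaminants, "contaminant", "synthetic contaminant")

  plants <- spec$plants
  intact_cds <- list()  # protein_id -> cds, for duplicate plants
  if (nrow(plants) > 0L) {
    for (i in seq_len(nrow(plants))) {
      pid <- plants$protein_id[i]
      frame <- plants$frame[i]
      type <- plants$type[i]
      built <- build_synthetic_protein(archs[[pid]], pid)
      protein <- built$protein
      if (nchar(protein) * 3L + 120L >
          max(spec$length_range[2L] * 4L, 4000L)) {
        stop("infeasible spec: planted protein longer than any transcript",
             call. = FALSE)
      }

      if (type %in% c("intact", "duplicate")) {
        cds <- paste0(reverse_translate(protein), "TAA")
        if (type == "duplicate") {
          if (!is.null(intact_cds[[pid]])) cds <- intact_cds[[pid]]
        } else {
          intact_cds[[pid]] <- cds
        }
        add(embed_insert(cds, frame, spec$gc),
            paste("synthetic plant", pid, type),
            truth_row("plant", pid, type, frame, orf_protein = protein,
                      category_expected = 1L))
      } else if (type == "novel") {
        cds <- paste0(reverse_translate(protein), "TAA")
        add(embed_insert(cds, frame, spec$gc),
            paste("synthetic plant", pid, type),
            truth_row("plant", pid, type, frame, orf_protein = protein,
                      category_expected = 3L))
      } else if (type == "truncated") {
        n_dom <- length(archs[[pid]])
        if (n_dom < 2L) {
          stop("a truncated plant needs a protein with >= 2 domains",
               call. = FALSE)
        }
        keep <- seq_len(n_dom - 1L)  # drop the C-terminal domain
        trunc_prot <- substr(protein, 1L,
                             built$dom_start[max(keep)] +
                               nchar(synthetic_domain_peptides()[[
                                 archs[[pid]][max(keep)]]]) - 1L)
        cds <- paste0(reverse_translate(trunc_prot), "TAA")
        add(embed_insert(cds, frame, spec$gc),
            paste("synthetic plant", pid, type),
            truth_row("plant", pid, type, frame, orf_protein = trunc_prot,
                      category_expected = 2L))
      } else if (type == "split") {
        # split at the internal linker M before domain floor(n/2)+1 so the
        # target domain ends up on both fragments for SH2-bearing panels
        n_dom <- length(archs[[pid]])
        j <- n_dom %/% 2L + 1L
        s <- built$pre_m[j]
        k <- spec$split_overlap
        frag1 <- substr(protein, 1L, s + k - 1L)
        frag2 <- substr(protein, s, nchar(protein))
        overlap <- substr(protein, s, s + k - 1L)
        cds1 <- paste0(reverse_translate(frag1), "TAA")
        cds2 <- paste0(reverse_translate(frag2), "TAA")
        seq1 <- embed_insert(cds1, frame, spec$gc)
        seq2 <- embed_insert(cds2, frame, spec$gc)
        a1 <- add(seq1, paste("synthetic plant", pid, "split fragment 1"),
                  truth_row("plant", pid, type, frame, orf_protein = frag1,
                            category_expected = 2L,
                            overlap_peptide = overlap))
        a2 <- add(seq2, paste("synthetic plant", pid, "split fragment 2"),
                  truth_row("plant", pid, type, frame, orf_protein = frag2,
                            category_expected = 2L, merge_partner = a1,
                            overlap_peptide = overlap))
        truths[[length(truths) - 1L]]$merge_partner <- a2
      } else if (type == "frameshift") {
        # Engineered frameshift junction: the final domain of the protein
        # continues in the next reading frame of the same transcript. The
        # junction TAA|C|TAA places an in-frame stop in BOTH frames (frame f
        # right after part 1, frame f+1 right before part 2's start codon),
        # so each fragment is a clean ORF. The N-terminal ORF (all preceding
        # domains) is the longer one, so the target-domain ORF is not the
        # longest ORF of the transcript.
        n_dom <- length(archs[[pid]])
        s <- built$pre_m[n_dom]
        part1 <- substr(protein, 1L, s - 1L)
        part2 <- substr(protein, s, nchar(protein))  # starts with linker M
        insert <- paste0(reverse_translate(part1), "TAAC", "TAA",
                         reverse_translate(part2), "TAA")
        k <- abs(frame)
        frame2_fwd <- (k %% 3L) + 1L  # net 7-nt junction shifts by +1
        frame2 <- if (frame > 0L) frame2_fwd else -frame2_fwd
        add(embed_insert(insert, frame, spec$gc),
            paste("synthetic plant", pid, type),
            truth_row("plant", pid, type, frame, frame2 = frame2,
                      orf_protein = part2, category_expected = 2L))
      } else if (type == "outside_orf") {
        # the target peptide with no start codon in its stop-delimited
        # segment: a hit that lies within no ORF
        pep <- synthetic_domain_peptides()[["SH2"]]
        insert <- paste0(reverse_translate(pep), "TAA")
        add(embed_insert(insert, frame, spec$gc),
            paste("synthetic plant", pid, type),
            truth_row("plant", pid, type, frame,
                      category_expected = NA_integer_,
                      exclusion_reason = "hit-outside-orf"))
      }
    }
  }

  transcripts <- purrr::list_rbind(rows)
  truth <- purrr::list_rbind(truths) |>
    dplyr::relocate("accession")
  list(transcripts = transcripts, truth = truth,
       panel = plant_reference_panel())
}
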