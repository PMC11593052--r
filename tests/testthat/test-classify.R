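test_that("hit-in-ORF containment requires full inclusion", {
  orfs <- find_orfs(fake_translation(
    paste0("M", strrep("A", 316), "*"), frame = 1L, source_length = 954L))
  h <- function(s, e) tibble::tibble(accession = "t1", frame = 1L,
                                     hit_start = s, hit_end = e)
  inside <- domain_in_orf(h(10L, 105L), orfs)
  expect_true(inside$in_orf)
  expect_equal(inside$orf_protein_start, 1L)

  # no ORF on that frame
  none <- domain_in_orf(tibble::tibble(accession = "t1", frame = 2L,
                                       hit_start = 10L, hit_end = 105L),
                        orfs)
  expect_false(none$in_orf)

  # straddling the ORF boundary is excluded
  straddle <- domain_in_orf(h(300L, 330L), orfs)
  expect_false(straddle$in_orf)

  # among multiple containers the longest wins
  two <- dplyr::bind_rows(
    find_orfs(fake_translation("MAAAAAAAAA*", frame = 1L,
                               source_length = 33L),
              orf_policy(min_aa = 3L)),
    find_orfs(fake_translation("MAAAA*", frame = 2L, source_length = 19L),
              orf_policy(min_aa = 3L)))
  both <- domain_in_orf(tibble::tibble(accession = "t1", frame = 1L,
                                       hit_start = 2L, hit_end = 4L), two)
  expect_equal(both$orf_length_aa, 10L)
})

test_that("the printed junction peptide merges with overlap twelve", {
  a <- paste0("MTTTTTTTTTT", "HERKMRIAKEFS")
  b <- paste0("HERKMRIAKEFS", "GGGGGGGGGG")
  m <- merge_split_transcripts(a, b)
  expect_equal(m$overlap_length, 12L)
  expect_equal(m$overlap_peptide, "HERKMRIAKEFS")
  expect_equal(m$merged, paste0("MTTTTTTTTTT", "HERKMRIAKEFS",
                                "GGGGGGGGGG"))
  # ordering is detected automatically
  expect_equal(merge_split_transcripts(b, a)$merged, m$merged)

  expect_null(merge_split_transcripts("MKLVWYPQ", "MTRHENDC"))
  expect_null(merge_split_transcripts(a, b, min_overlap = 13L))
})

test_that("fragment-and-reassemble recovers the original protein", {
  withr::with_seed(80, {
    for (i in 1:15) {
      n <- sample(60:200, 1)
      protein <- random_protein_str(n)
      cut <- sample(20:(n - 30), 1)
      k <- sample(8:15, 1)
      frag1 <- substr(protein, 1, cut + k - 1)
      frag2 <- substr(protein, cut, n)
      m <- merge_split_transcripts(frag1, frag2, min_overlap = 8L)
      expect_false(is.null(m))
      expect_gte(m$overlap_length, k)  # longest exact overlap wins
      expect_equal(m$merged, protein)
    }
  })
})

test_that("frame splits are detected as contiguous reference blocks", {
  ref <- c("SAM", "PHA02682", "SH2")
  hits <- tibble::tibble(
    frame = c(-3L, -1L, -1L),
    domain_name = c("SAM", "PHA02682", "SH2"),
    hit_start = c(5L, 10L, 60L))
  split <- detect_frame_split(hits, ref)
  expect_equal(nrow(split$frames), 2L)
  expect_equal(split$frames$frame, c(-3L, -1L))
  expect_equal(split$frames$domains[[2]], c("PHA02682", "SH2"))
  expect_equal(split$uncovered, character())

  # all domains on one frame: no split
  one_frame <- dplyr::mutate(hits, frame = -1L)
  expect_null(detect_frame_split(one_frame, ref))

  # a gap in the reference is reported as uncovered
  gap <- detect_frame_split(hits[c(1, 3), ], ref)
  expect_equal(gap$uncovered, "PHA02682")
  expect_error(detect_frame_split(hits, character()), "non-empty")
})

test_that("an engineered frameshift is found at the planted junction", {
  sim <- generate_transcriptome(plant_spec(
    n_background = 2L,
    plants = tibble::tibble(protein_id = "BLNK1", frame = -1L,
                            type = "frameshift"),
    seed = 81L))
  tru <- sim$truth[sim$truth$role == "plant", ]
  tl <- six_frame_translate(sim$transcripts)
  orfs <- find_orfs(tl)
  hits <- domain_in_orf(builtin_scan(tl, panel_profiles(sim$panel)), orfs)
  fh <- dplyr::filter(hits, accession == tru$accession, in_orf)
  split <- detect_frame_split(
    dplyr::select(fh, frame, domain_name, hit_start),
    c("SAM", "PHA", "SH2"))
  expect_false(is.null(split))
  expect_setequal(split$frames$frame, c(tru$frame, tru$frame2))
})

test_that("category assignment follows the three-way system", {
  ev <- tibble::tibble(
    accession = c("kin", "splitA", "novel", "outside", "conflict"),
    domain_in_orf = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    best_match = c("SFK", "PLCG", "PLCG", NA, "SFK"),
    best_passes = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    architecture_verdict = c("full-match", "partial-subsequence", NA,
                             NA, "full-match"),
    missing_domains = list(character(), c("PI-PLC", "C2"), NULL, NULL,
                           character()),
    merge_partner = c(NA, "splitB", NA, NA, "other"),
    overlap_peptide = c(NA, "HERKMRIAKEFS", NA, NA, NA),
    frame_split = list(NULL, NULL, NULL, NULL, NULL),
    on_longest_orf = TRUE, orf_protein = "M")
  calls <- assign_category(ev)
  expect_equal(calls$category, c(1L, 2L, 3L, NA, 1L))
  expect_equal(calls$reason,
               c("full-architecture-match", "split-across-transcripts",
                 "no-passing-match", "hit-outside-orf",
                 "full-architecture-match"))
  # category 3 clears the best match; conflicts warn but stay category 1
  expect_true(is.na(calls$best_match[3]))
  expect_false(is.na(calls$warning[5]))

  # disjoint-but-passing is category 2 flagged for review
  dis <- assign_category(dplyr::mutate(
    ev[1, ], architecture_verdict = "disjoint"))
  expect_equal(dis$category, 2L)
  expect_equal(dis$reason, "architecture-disjoint")
  expect_true(dis$review)
})

test_that("identical ORF proteins collapse to one identity", {
  calls <- tibble::tibble(accession = c("b", "a", "c", "d"),
                          orf_protein = c("MKL", "MKL", "MKV", "MKL"))
  d <- dedup_unique_orfs(calls)
  expect_equal(nrow(d$unique), 2L)
  expect_equal(sort(d$unique$accession), c("a", "c"))  # smallest accession
  expect_equal(sort(d$duplicates$member), c("b", "d"))
  expect_equal(d$n_duplicates_removed, 2L)

  # single-residue difference keeps both; n copies always collapse to one
  expect_equal(nrow(dedup_unique_orfs(
    tibble::tibble(accession = c("a", "b"),
                   orf_protein = c("MKL", "MKI")))$unique), 2L)
  many <- tibble::tibble(accession = paste0("t", 1:7), orf_protein = "MWW")
  expect_equal(nrow(dedup_unique_orfs(many)$unique), 1L)
})

test_that("contamination screening removes, trims, and checks references", {
  trs <- tibble::tibble(accession = paste0("t", 1:10),
                        sequence = strrep("ACGT", 10))
  res <- contamination_filter(trs, remove_accessions = c("t1", "t5"),
                              trim = tibble::tibble(accession = "t2",
                                                    start = 5L, end = 20L))
  expect_equal(res$n_output, 8L)
  expect_equal(nchar(res$transcripts$sequence[
    res$transcripts$accession == "t2"]), 16L)

  # empty lists are the identity
  same <- contamination_filter(trs)
  expect_identical(same$transcripts, trs)

  # removal dominates when a record is on both lists
  both <- contamination_filter(trs, remove_accessions = "t3",
                               trim = tibble::tibble(accession = "t3",
                                                     start = 1L, end = 4L))
  expect_false("t3" %in% both$transcripts$accession)
  expect_equal(both$n_trimmed, 0L)

  expect_error(contamination_filter(trs, remove_accessions = "nope"),
               "unknown accession")
  expect_error(contamination_filter(
    trs, trim = tibble::tibble(accession = "t1", start = 1L, end = 999L)),
    "invalid trim")
})
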