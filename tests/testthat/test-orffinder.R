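test_that("a simple terminated ORF is found with its stop excluded", {
  tl <- fake_translation("MKKK*", source_length = 15L)
  orfs <- find_orfs(tl, orf_policy(min_aa = 3L))
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$protein, "MKKK")
  expect_true(orfs$has_terminal_stop)
  expect_equal(orfs$length_aa, 4L)
  expect_equal(orfs$nt_end - orfs$nt_start + 1L, 12L)  # 3 x 4, stop excluded
})

test_that("a 951-nt coding stretch yields a 317-residue protein", {
  # stop codon excluded from the reported length: 951 = 3 * 317
  withr::with_seed(50, {
    protein <- paste0("M", random_protein_str(
      316, setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "M")))
  })
  cds <- paste0(domainfirst::reverse_translate(protein), "TAA")
  tl <- six_frame_translate(tibble::tibble(accession = "t", sequence = cds))
  orfs <- find_orfs(tl)
  main <- orfs[orfs$frame == 1L, ]
  expect_equal(main$length_aa, 317L)
  expect_equal(main$nt_end - main$nt_start + 1L, 951L)
  expect_equal(main$protein, protein)
})

test_that("no start codon under the ATG rule means no ORF", {
  tl <- fake_translation("KKKKKKKKKKKKKKKKKKKKKKKKKKKKKK")
  expect_equal(nrow(find_orfs(tl, orf_policy(min_aa = 3L))), 0L)
  # ... but the any-sense-codon rule accepts the segment
  got <- find_orfs(tl, orf_policy(start_rule = "any", min_aa = 3L))
  expect_equal(nrow(got), 1L)
  expect_false(got$has_terminal_stop)
})

test_that("ORF enumeration matches the positional scan oracle", {
  withr::with_seed(51, {
    for (i in 1:12) {
      s <- random_dna_str(sample(60:400, 1))
      tl <- six_frame_translate(tibble::tibble(accession = "t",
                                               sequence = s))
      got <- find_orfs(tl, orf_policy(min_aa = 5L))
      exp <- oracle_orfs(s, min_aa = 5)
      expect_equal(nrow(got), length(exp))
      got_key <- sort(paste(got$frame, got$protein_start,
                            got$protein_end, got$protein))
      exp_key <- sort(vapply(exp, function(o) {
        paste(o$frame, o$p_start, o$p_end, o$protein)
      }, character(1)))
      expect_identical(got_key, exp_key)
    }
  })
})

test_that("re-translating an ORF's nucleotide interval reproduces it", {
  withr::with_seed(52, {
    for (i in 1:8) {
      s <- random_dna_str(sample(90:300, 1))
      tl <- six_frame_translate(tibble::tibble(accession = "t",
                                               sequence = s))
      orfs <- find_orfs(tl, orf_policy(min_aa = 5L))
      for (r in seq_len(nrow(orfs))) {
        nt <- substr(s, orfs$nt_start[r], orfs$nt_end[r])
        if (orfs$frame[r] < 0L) nt <- reverse_complement(nt)
        re <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
        expect_identical(re, orfs$protein[r])
      }
    }
  })
})

test_that("ORF sets mirror under reverse complement", {
  withr::with_seed(53, {
    for (i in 1:6) {
      s <- random_dna_str(sample(90:300, 1))
      a <- find_orfs(six_frame_translate(
        tibble::tibble(accession = "t", sequence = s)),
        orf_policy(min_aa = 5L))
      b <- find_orfs(six_frame_translate(
        tibble::tibble(accession = "t",
                       sequence = reverse_complement(s))),
        orf_policy(min_aa = 5L))
      expect_identical(sort(a$protein), sort(b$protein))
      # frame +k ORFs appear as frame -k ORFs with mirrored coordinates
      L <- nchar(s)
      a_key <- sort(paste(-a$frame, L - a$nt_end + 1L, L - a$nt_start + 1L))
      b_key <- sort(paste(b$frame, b$nt_start, b$nt_end))
      expect_identical(a_key, b_key)
    }
  })
})

test_that("longest-ORF selection breaks ties by frame order then position", {
  orfs <- dplyr::bind_rows(
    find_orfs(fake_translation("MAAAA*", frame = -1L, source_length = 18L),
              orf_policy(min_aa = 3L)),
    find_orfs(fake_translation("MCCCC*", frame = 2L, source_length = 19L),
              orf_policy(min_aa = 3L)))
  top <- longest_orf(orfs)
  expect_equal(top$frame, 2L)  # +2 precedes -1 at equal length
  expect_equal(nrow(longest_orf(orfs[0, ])), 0L)

  lengths <- find_orfs(fake_translation("MAAAAAAAA*MCC*"),
                       orf_policy(min_aa = 1L))
  expect_equal(longest_orf(lengths)$protein, "MAAAAAAAA")
})
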