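test_that("batch splitting is a reproducible partition", {
  recs <- tibble::tibble(framed_id = paste0("t", 1:4001, "_+1"),
                         protein = "M")
  b <- split_batches(recs, 4000L, seed = 9L)
  expect_equal(length(b), 2L)
  expect_equal(sort(sapply(b, nrow)), c(1L, 4000L))
  expect_identical(split_batches(recs, 4000L, seed = 9L), b)

  expect_equal(length(split_batches(recs[1:4000, ], 4000L, seed = 1L)), 1L)
  expect_error(split_batches(recs, 0L), "positive")

  # partition property: nothing lost or duplicated, any size and seed
  withr::with_seed(10, {
    for (i in 1:5) {
      n <- sample(1:200, 1); size <- sample(1:50, 1)
      recs <- tibble::tibble(framed_id = paste0("r", 1:n), protein = "A")
      parts <- split_batches(recs, size, seed = sample(1e6, 1))
      expect_true(all(sapply(parts, nrow) <= size))
      expect_identical(sort(unlist(lapply(parts, `[[`, "framed_id"))),
                       sort(recs$framed_id))
    }
  })
})

cdd_fixture <- function(rows) {
  c("#Batch CD-search tool\tNIH/NLM/NCBI", "#cdsid\tQM3-qcdsearch-ABC",
    "#datatype\thitsFull Results", "#status\t0",
    paste("Query", "Hit type", "PSSM-ID", "From", "To", "E-Value",
          "Bitscore", "Accession", "Short name", "Incomplete",
          "Superfamily", sep = "\t"),
    rows)
}

test_that("Batch CD-Search tables parse with framed-id attribution", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(cdd_fixture(c(
    paste("Q#1 - >GGEY02085024.1_+2", "specific", "214570", "10", "105",
          "3.1e-40", "120.5", "cd10349", "SH2", "-", "cl15255", sep = "\t"),
    paste("Q#2 - >GGEY02003111.1_-1", "superfamily", "474616", "12", "88",
          "2e-12", "60.1", "cl15255", "SH2 superfamily", "-", "-",
          sep = "\t"))), tmp)
  hits <- parse_cdd_hits(tmp)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$accession, c("GGEY02085024.1", "GGEY02003111.1"))
  expect_equal(hits$frame, c(2L, -1L))
  expect_equal(hits$domain_name[1], "SH2")
  expect_equal(hits$hit_start[1], 10L)
  expect_equal(hits$hit_end[1], 105L)
  expect_equal(hits$hit_type, c("specific", "superfamily"))
  expect_equal(hits$source, c("cdd-batch", "cdd-batch"))

  # comment-only file is an empty collection
  writeLines(c("#only", "#comments"), tmp)
  expect_equal(nrow(parse_cdd_hits(tmp)), 0L)
})

test_that("missing columns and odd queries are reported, not dropped", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Query\tFrom\tTo", "q\t1\t2"), tmp)
  expect_error(parse_cdd_hits(tmp), "Hit type")

  writeLines(cdd_fixture(
    paste("Q#1 - >noframe", "specific", "1", "1", "5", "1e-3", "10",
          "cd1", "WW", "-", "-", sep = "\t")), tmp)
  expect_warning(hits <- parse_cdd_hits(tmp), "grammar")
  expect_equal(nrow(hits), 1L)
  expect_true(is.na(hits$accession))
})

test_that("the built-in scanner finds planted motifs deterministically", {
  prof <- domain_profile("SH2", motif = "WHEREISTHESIGNAL")
  withr::with_seed(60, {
    protein <- paste0(random_protein_str(40), "WHEREISTHESIGNAL",
                      random_protein_str(30))
  })
  hits <- builtin_scan(fake_translation(protein), list(prof))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$hit_start, 41L)
  expect_equal(hits$hit_end, 56L)
  expect_equal(hits$source, "builtin")

  # all-X (untranslatable) protein yields nothing, under motif and pwm
  allx <- fake_translation(strrep("X", 50))
  expect_equal(nrow(builtin_scan(allx, list(prof))), 0L)
  pwm <- matrix(1, nrow = 2, ncol = 3,
                dimnames = list(c("A", "C"), NULL))
  expect_equal(nrow(builtin_scan(
    allx, list(domain_profile("toy", pwm = pwm, threshold = 0)))), 0L)

  expect_error(builtin_scan(allx, list()), "non-empty")
})

test_that("scanner output equals the brute-force window oracle", {
  withr::with_seed(61, {
    aas <- strsplit("ACDEFG", "")[[1]]  # small alphabet => frequent hits
    profs <- list(
      domain_profile("exact", motif = "CADFA"),
      domain_profile("fuzzy", motif = "DEFACD", max_mismatch = 2L),
      domain_profile("pwm", threshold = 3,
                     pwm = matrix(stats::runif(6 * 4, -1, 2), nrow = 6,
                                  dimnames = list(aas, NULL))))
    for (i in 1:10) {
      protein <- random_protein_str(sample(20:200, 1), aas)
      tl <- fake_translation(protein)
      for (p in profs) {
        got <- builtin_scan(tl, list(p))
        exp <- oracle_scan(protein, p)
        expect_equal(nrow(got), length(exp))
        if (length(exp) > 0) {
          expect_equal(got$hit_start,
                       vapply(exp, `[[`, numeric(1), "start"))
        }
      }
    }
  })
})

test_that("target selection is substring, case-insensitive, and monotone", {
  hits <- tibble::tibble(
    domain_name = c("SH2", "WW", "SAM", "SH2 superfamily", "sh2-like"),
    accession = paste0("t", 1:5))
  sel <- select_target_hits(hits, "SH2")
  expect_equal(sel$domain_name, c("SH2", "SH2 superfamily", "sh2-like"))

  # idempotent
  expect_identical(select_target_hits(sel, "SH2"), sel)
  # monotone: a superset of hits yields a superset of selections
  expect_true(all(sel$accession %in%
                    select_target_hits(dplyr::bind_rows(
                      hits, tibble::tibble(domain_name = "SH2",
                                           accession = "t9")),
                      "SH2")$accession))
  expect_equal(nrow(select_target_hits(hits[0, ], "SH2")), 0L)
  expect_error(select_target_hits(hits, ""), "non-empty")
})
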