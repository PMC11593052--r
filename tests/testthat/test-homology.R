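blast_row <- function(q = "q1", s = "s1", id = 99.6, len = 250, mm = 1,
                      go = 0, qs = 1, qe = 250, ss = 1, se = 250,
                      ev = 1e-100, bs = 500, cov = NULL) {
  f <- c(q, s, id, len, mm, go, qs, qe, ss, se, ev, bs)
  if (!is.null(cov)) f <- c(f, cov)
  paste(f, collapse = "\t")
}

test_that("12-column BLAST tables parse, with coverage from lengths", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(blast_row(id = 99.6, qs = 1, qe = 250),
               blast_row(q = "q2", s = "XP_038070561", id = 92,
                         qs = 11, qe = 60)), tmp)
  hits <- parse_blast_tab(tmp, query_lengths = c(q1 = 250, q2 = 100))
  expect_equal(hits$percent_identity, c(99.6, 92))
  expect_equal(hits$subject[2], "XP_038070561")
  expect_equal(hits$query_coverage, c(100, 50))

  # 13th column supplies coverage directly
  writeLines(blast_row(cov = 87.5), tmp)
  expect_equal(parse_blast_tab(tmp)$query_coverage, 87.5)

  writeLines(character(), tmp)
  expect_equal(nrow(suppressWarnings(parse_blast_tab(tmp))), 0L)
})

test_that("malformed BLAST rows raise format errors naming the row", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(blast_row(), "q1\ts1\tonly-three"), tmp)
  expect_error(parse_blast_tab(tmp), "row 2")

  writeLines("q1\ts1\t90\t100\t1\t0\t1\t100\t1\t100\tnot-a-number\t55", tmp)
  expect_error(parse_blast_tab(tmp), "evalue")
})

test_that("match criteria boundaries are all inclusive", {
  c0 <- match_criteria()
  h <- function(cov, id, ev) {
    tibble::tibble(query_coverage = cov, percent_identity = id,
                   evalue = ev, bitscore = 1)
  }
  expect_true(passes_criteria(h(50, 30, 1e-5), c0))    # exactly at bounds
  expect_false(passes_criteria(h(49.9, 90, 1e-30), c0))
  expect_false(passes_criteria(h(100, 31, 1e-4), c0))
  expect_false(passes_criteria(h(NA, 99, 1e-30), c0))  # NA never passes
  expect_error(match_criteria(max_evalue = 0), "max_evalue")
})

test_that("pass decisions are monotone in every field", {
  c0 <- match_criteria()
  withr::with_seed(70, {
    for (i in 1:50) {
      h <- tibble::tibble(query_coverage = stats::runif(1, 0, 100),
                          percent_identity = stats::runif(1, 0, 100),
                          evalue = 10^stats::runif(1, -30, 2),
                          bitscore = 1)
      better <- dplyr::mutate(h,
        query_coverage = pmin(100, query_coverage + stats::runif(1, 0, 20)),
        percent_identity = pmin(100, percent_identity +
                                  stats::runif(1, 0, 20)),
        evalue = evalue / 10^stats::runif(1, 0, 5))
      if (passes_criteria(h, c0)) expect_true(passes_criteria(better, c0))
    }
  })
})

test_that("best-hit selection orders by evalue, bitscore, identity", {
  hits <- tibble::tibble(
    query = "q", subject = c("a", "b", "c", "d"),
    percent_identity = c(80, 90, 95, 99),
    query_coverage = c(90, 90, 90, 40),
    evalue = c(1e-20, 1e-8, 1e-20, 1e-50),
    bitscore = c(190, 100, 210, 500))
  best <- best_hit(hits)
  expect_equal(best$subject, "c")  # evalue tie broken by bitscore
  expect_equal(nrow(best_hit(hits[hits$subject == "d", ])), 0L)

  # whenever anything passes, the returned hit passes
  withr::with_seed(71, {
    for (i in 1:20) {
      h <- tibble::tibble(query = "q", subject = letters[1:6],
                          percent_identity = stats::runif(6, 0, 100),
                          query_coverage = stats::runif(6, 0, 100),
                          evalue = 10^stats::runif(6, -40, 2),
                          bitscore = stats::runif(6, 20, 500))
      b <- best_hit(h)
      if (any(passes_criteria(h))) {
        expect_equal(nrow(b), 1L)
        expect_true(passes_criteria(b))
        expect_equal(b$evalue,
                     min(h$evalue[passes_criteria(h)]))
      } else {
        expect_equal(nrow(b), 0L)
      }
    }
  })
})

test_that("architecture comparison distinguishes full, partial, disjoint", {
  full <- compare_architecture(c("SH3", "SH2", "Kinase"),
                               c("SH3", "SH2", "Kinase"))
  expect_equal(full$verdict, "full-match")
  expect_equal(full$missing, character())

  # a phospholipase fragment missing its lipase and C2 domains
  plc_ref <- c("PI-PLC", "SH2", "SH2", "SH3", "C2")
  part <- compare_architecture(c("SH2", "SH2", "SH3"), plc_ref)
  expect_equal(part$verdict, "partial-subsequence")
  expect_setequal(part$missing, c("PI-PLC", "C2"))

  dis <- compare_architecture(c("WW", "SH2"), "Kinase")
  expect_equal(dis$verdict, "disjoint")

  # order violations are disjoint even when domains are shared
  expect_equal(compare_architecture(c("SH2", "SH3"),
                                    c("SH3", "SH2", "Kinase"))$verdict,
               "disjoint")
  expect_error(compare_architecture("SH2", character()), "non-empty")

  # identity property on random architectures
  withr::with_seed(72, {
    for (i in 1:10) {
      arch <- sample(c("SH2", "SH3", "WW", "SAM", "C2"),
                     sample(1:6, 1), replace = TRUE)
      expect_equal(compare_architecture(arch, arch)$verdict, "full-match")
    }
  })
})

test_that("the built-in aligner recovers exact homologues decisively", {
  panel <- plant_reference_panel()
  q <- tibble::tibble(id = "q", protein = panel$protein[1])
  hom <- align_homology(q, tibble::tibble(id = panel$protein_id,
                                          protein = panel$protein))
  expect_equal(nrow(hom), nrow(panel))
  best <- best_hit(hom)
  expect_equal(best$subject, panel$protein_id[1])
  expect_equal(best$percent_identity, 100)
  expect_equal(best$query_coverage, 100)
  expect_lt(best$evalue, 1e-20)
})
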