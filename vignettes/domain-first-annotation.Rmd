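---
title: "Domain-first annotation of de novo transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-first annotation of de novo transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainfirst)
library(dplyr)
```

## The problem

De novo assembled transcriptomes — common in non-model organisms such as
echinoderms, where no reference genome constrains the assembly — are usually
annotated *target-first*: a curated list of known proteins is aligned against
the transcriptome, and a transcript is annotated when it matches a target.
That strategy can only find what is already on the list, and it is blind to
assembly artifacts: a protein split across two transcript records, or a
single transcript whose coding sequence changes reading frame mid-protein
because of an indel introduced during assembly.

`domainfirst` implements the complementary *domain-first* strategy. Instead
of asking "where is protein X?", it asks "which transcripts could encode
*any* protein carrying the domain of interest?" (an SH2 domain, say — the
~100-residue module that binds phosphotyrosine and organises tyrosine-kinase
signalling). The pipeline:

1. conceptually translates every transcript in all six reading frames;
2. searches the whole conceptual proteome for the target domain;
3. maps each hit back to an open reading frame (ORF) and to transcript
   nucleotide coordinates;
4. identifies the best homologous known protein under explicit criteria;
5. compares domain architectures, merges split transcripts, and detects
   frame splits;
6. classifies every domain-bearing transcript and counts each funnel stage.

Because the domain search runs on whole-frame translations *before* ORF
selection, domains on non-longest ORFs — invisible to longest-ORF-first
annotation — are found.

## Coordinate conventions

Frames `+1/+2/+3` start at forward positions 1/2/3; `-1/-2/-3` start at
positions 1/2/3 of the reverse complement. Translated records are named
`"<accession>_<frame>"` with an explicit sign (`parse_framed_id()` /
`framed_id()`). All reported coordinates are 1-based inclusive on the
forward strand. Protein position $p$ on frame $+k$ occupies nucleotides
$[(k-1)+3(p-1)+1,\; (k-1)+3p]$; on $-k$ the same interval is computed on the
reverse complement and reported as the corresponding forward-strand
interval, so `nt_start <= nt_end` always. `protein_to_nucleotide()` and
`nucleotide_to_protein()` are exact inverses on codon-aligned intervals,
and the test suite checks them against an exhaustive codon-walk oracle.

Translation runs *through* internal stop codons (emitted as `*`), because
segmentation at stops is the ORF finder's job, and codons containing an
ambiguity code that does not resolve to a unique residue become `X`.

## ORF conventions

`find_orfs()` segments each frame translation at stop codons and reports
one ORF per segment, from the first start codon (policy `"ATG"`; `"any"`
accepts any sense codon) to the residue before the stop. Two conventions
deserve explicit statement:

* **Nested ORFs collapse.** Several methionines upstream of one stop define
  nested ORFs; only the longest (first start) is reported. Nested ORFs add
  no information for domain containment — any hit inside a nested ORF is
  inside the longest one.
* **Lengths exclude the stop codon.** A 951-nt coding stretch corresponds
  to a 317-residue protein ($951 = 3 \times 317$). Some ORF finders include
  the stop in the nucleotide length; this package never does, so protein
  and nucleotide lengths always satisfy `3 * length_aa == span`.

Defaults — ATG start, minimum 25 residues, unterminated 3' ORFs kept — are
all configurable through `orf_policy()`. Ties in "longest ORF" break by
frame order `+1,+2,+3,-1,-2,-3`, then 5' position, so results are
deterministic.

## Domain evidence

The conserved-domain search itself is an external adapter: the package
writes six-frame proteome batches (`split_batches()`, default 4000 records
per batch, seeded random partition recorded in the run configuration) and
parses the tabular hit files such services return (`parse_cdd_hits()`). All
hit types — specific, non-specific, superfamily — are parsed and preserved;
transcripts whose only evidence is a superfamily-level hit are retained and
labelled, never dropped. Target selection (`select_target_hits()`) is a
case-insensitive substring match on the model short name, so `"SH2"`
selects both `"SH2"` and `"SH2 superfamily"`.

For self-contained work (tests, synthetic studies) `builtin_scan()`
provides a deterministic window scanner over exact/approximate motifs or
position-weight profiles. It is deliberately simple — every window at or
above threshold is a hit — and is verified against a brute-force
window-scoring oracle.

## Homology criteria and architectures

A homology hit counts as a match iff query coverage $\ge$ 50%, identity
$\ge$ 30%, and e-value $\le 10^{-5}$ — all boundaries inclusive, all three
configurable via `match_criteria()`. Among passing hits the best has the
lowest e-value, ties broken by bit score then identity. Hits arrive either
as standard 12-column tabular alignment files (`parse_blast_tab()`; an
optional 13th column or a vector of query lengths supplies coverage) or
from the built-in Smith–Waterman route (`align_homology()`: BLOSUM62, gap
open 11 / extend 1, Karlin–Altschul bit-score and e-value conversion with
the standard gapped-BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$).
The gap penalties matter: cheaper extensions let local alignments bridge
unrelated regions and inflate coverage, which is exactly the artifact the
coverage criterion exists to exclude.

Architectures are ordered N-to-C domain-name lists. `compare_architecture()`
returns `full-match` (exact equality), `partial-subsequence` (the candidate
is a proper ordered sublist — gaps allowed, so truncations register as
partial — with the missing domains reported), or `disjoint`. Order
violations are disjoint even when domains are shared.

## Assembly-error evidence

**Split transcripts.** When one protein is split across two transcript
records, the two partial polypeptides share the junction sequence.
`merge_split_transcripts()` merges two ORF proteins when a suffix of one
exactly equals a prefix of the other for at least 8 residues (configurable;
the longest exact overlap wins, both orderings tried). Exactness is
deliberate: approximate overlaps would invite spurious merges, and observed
real junctions (twelve residues in the motivating case) comfortably exceed
the floor. Only candidates with a *partial* architecture are scanned for
partners — a merge is an explanation for missing domains, so full-match
calls are not candidates.

**Frame splits.** `detect_frame_split()` reports a reference architecture
as frame-split when its domains are covered by in-ORF hits in two or more
frames of the same transcript, each frame covering a contiguous block of
the reference order, blocks disjoint; reference domains covered by no frame
are reported as the uncovered gap. This is the within-transcript analogue
of the split-transcript case and typically indicates a single-indel
assembly error.

## The category system and the funnel

Every transcript with a target-domain hit inside an ORF receives exactly
one category:

| category | meaning | requirement |
|---|---|---|
| 1 | matched to a known protein | best hit passes criteria AND architecture full-match |
| 2 | assembly error / truncated RNA | best hit passes, architecture partial — explained by a merge partner, a frame split, or plain truncation |
| 3 | no match | no hit passes the criteria (the best match is cleared) |

Hits lying in no ORF exclude the transcript with reason `hit-outside-orf`.
Two edge rules are decisions this package makes explicitly: a passing hit
with a *disjoint* architecture is category 2 with reason
`architecture-disjoint` and a review flag (the alternative, category 3,
would discard a passing match silently); and conflicting evidence
(full-match plus a merge partner) resolves to category 1 with a recorded
warning.

Transcripts whose domain-bearing ORF proteins are exactly identical
collapse to one identity (`dedup_unique_orfs()`; the amino-acid string is
the key, so silent nucleotide variants collapse, represented by the
lexicographically smallest accession). The funnel report counts every
stage, and every input transcript lands in exactly one terminal bin
(`no-domain`, `hit-outside-orf`, `duplicate`, `merged-into-partner`,
`unique`) — a conservation law the tests assert. Because a merged pair of
truncated transcripts can be counted as one identity or two, the funnel
exposes both countings (`n_unique_orfs` and `n_unique_identities_merged`)
rather than choosing silently; stage removals can overlap, so no
subtraction identity between stages is asserted or implied.

## The synthetic study generator

`generate_transcriptome(plant_spec(...))` builds seeded synthetic
transcriptomes with planted ground truth, so the whole pipeline is testable
without downloads. What it emulates: uniform-composition background
transcripts (configurable GC), domain-encoding ORFs embedded at chosen
frames on either strand, and the three error classes — split pairs with an
exact junction overlap (default 12 residues), engineered frameshift
junctions, truncations — plus duplicates, hits outside any ORF, and novel
architectures absent from the reference panel. All sequences derive from a
fixed, methionine-free set of synthetic domain peptides (stand-ins for real
domain models, not consensus sequences) joined by linkers whose `M` at a
fixed position provides deliberate internal start codons; linker tails vary
per protein and position so unrelated synthetic proteins never share long
suffix–prefix overlaps.

Two generator details are load-bearing. The reverse-translation codon table
is fixed (one codon per residue) with `L = TTA` and `S = TCA`, whose
reverse-complement readings are stop codons — without this, planted coding
regions leave long stop-free "phantom" ORFs on the opposite strand that can
outrank the planted ORF. And the frameshift junction `TAA|C|TAA` places an
in-frame stop in *both* frames at the junction, so each fragment is a clean
ORF: the N-terminal fragment (all domains but the last) is the longer one,
which makes the target-domain ORF a *non-longest* ORF — the situation
longest-ORF-first annotation misses.

What the generator does **not** emulate: real codon usage, expression
levels, sequencing error, chimeras, or any assembly artifact beyond the
three planted classes. Passing the planted-recovery tests therefore shows
the pipeline's logic is correct under its stated assumptions, not that any
particular biological transcriptome will be annotated completely.

Default study conditions: 60 background transcripts of 300–900 nt at GC
0.5, and ten plants covering every category (four intact proteins, one
split pair, one truncation, one frameshift, one duplicate, one
outside-ORF decoy, one novel architecture). Quantitative conventions are
exercised at full scale in the acceptance checks: 96,723 transcripts
translate to exactly 580,338 records, and a 105,191-record screen with
8,468 removals and 226 trims leaves 96,723.

## A worked run

```{r run}
sim <- generate_transcriptome(plant_spec(seed = 1L))
run <- run_novel(sim$transcripts, sim$panel)
run

tidy(run) |>
  select(accession, category, reason, best_match, merge_partner) |>
  arrange(accession)

glance(run)
```

Classic (target-first) mode and the comparison of the two:

```{r classic}
cls <- run_classic(sim$transcripts, sim$panel)
venn_calls(run, cls)
```

The classic-only set is empty — everything the target-driven search finds,
the domain-first search also finds, while the reverse does not hold.

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(run)
```

## Numerical choices and limitations

* All thresholds are surfaced (`run_config()`); there are no hidden
  constants, and every run can write a JSON snapshot of its configuration
  (including the batching seed) beside its outputs (`write_run()`).
* Degenerate inputs are defined: empty transcriptomes run to an empty call
  table and a zero funnel; empty FASTA files are empty collections;
  zero-length ORF sets are valid everywhere.
* The built-in aligner is a true Smith–Waterman and behaves sensibly on
  the synthetic panel, but it is not a substitute for a database search
  against comprehensive protein collections; for real data, feed external
  tabular results through `parse_blast_tab()` / `parse_cdd_hits()`.
* Sub-threshold "borderline" matches that a human might rescue from an
  alignment's graphic summary are *not* emulated; the package only flags
  review cases. Manual judgment stays manual.
* Published counts from any particular organism's transcriptome depend on
  the deposited assembly and database versions and are not reproduced
  here; the package's claims are the conventions and conservation laws its
  tests compute.

## Problem sizes used by the test suite

Unit and property tests run on transcripts up to a few hundred nucleotides
and proteins up to 200 residues (where brute-force oracles are exact and
fast); the end-to-end synthetic studies use 25–40 background transcripts
plus the ten standard plants; the count-convention checks run once at full
scale (96,723 and 105,191 records). The complete suite runs in about a
minute on one core.
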