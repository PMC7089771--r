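# Annotation parsing, landmark detection and single-isoform selection.

test_that("single-exon plus-strand GTF parses with CDS bounds intact", {
  # 120 nt transcript, CDS (incl. stop) at 31..90, stop codon TAA at 88..90
  seq <- paste0(strrep("A", 30), "ATG", strrep("GCT", 18), "TAA", strrep("C", 30))
  genome <- c(chr1 = seq)
  f <- write_toy_gtf(c(
    gtf_line("chr1", "gene", 1, 120, "+", "g1", "t1"),
    gtf_line("chr1", "transcript", 1, 120, "+", "g1", "t1"),
    gtf_line("chr1", "exon", 1, 120, "+", "g1", "t1"),
    gtf_line("chr1", "CDS", 31, 87, "+", "g1", "t1"),
    gtf_line("chr1", "stop_codon", 88, 90, "+", "g1", "t1")
  ), genome)
  ts <- parse_annotation(f$gtf, f$fasta, verbose = FALSE)
  expect_equal(nrow(ts$table), 1L)
  expect_equal(ts$table$cds_start, 31L)
  expect_equal(ts$table$cds_end, 90L)   # includes the stop codon
  expect_equal(ts$table$stop_codon, "TAA")
  expect_equal(ts$table$plus4, "C")
  expect_equal(unname(ts$seq["t1"]), seq)
})

test_that("CDS lacking a stop_codon feature is extended by sequence check", {
  seq <- paste0(strrep("A", 30), "ATG", strrep("GCT", 18), "TGA", strrep("C", 30))
  f <- write_toy_gtf(c(
    gtf_line("chr1", "exon", 1, 120, "+", "g1", "t1"),
    gtf_line("chr1", "CDS", 31, 87, "+", "g1", "t1")
  ), c(chr1 = seq))
  ts <- parse_annotation(f$gtf, f$fasta, verbose = FALSE)
  expect_equal(ts$table$cds_end, 90L)
  expect_equal(ts$table$stop_codon, "TGA")
})

test_that("minus-strand two-exon transcript splices to the reverse complement", {
  # transcript built explicitly, then laid on the minus strand in two exons:
  # the transcript's 5' part sits on the genomic RIGHT exon
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  tx <- paste0(strrep("C", 12), "ATG", "GCTGCAGAA", "TAA", strrep("A", 12),
               "TAG", strrep("G", 9))  # 5'UTR 12 nt, CDS 13..27 (incl TAA)
  len <- nchar(tx)
  half <- 30L                          # splice junction 3' of the stop codon
  g_ex2 <- rc(substr(tx, 1, half))     # transcript 5' half on right exon
  g_ex1 <- rc(substr(tx, half + 1L, len))
  genome <- c(chr2 = paste0(strrep("T", 10), g_ex1, strrep("G", 20), g_ex2,
                            strrep("T", 10)))
  e1s <- 11L; e1e <- 10L + nchar(g_ex1)
  e2s <- e1e + 21L; e2e <- e2s + nchar(g_ex2) - 1L
  cds_start <- 13L; cds_end <- 27L          # 15 nt CDS incl TAA
  f <- write_toy_gtf(c(
    gtf_line("chr2", "exon", e1s, e1e, "-", "g2", "t2"),
    gtf_line("chr2", "exon", e2s, e2e, "-", "g2", "t2"),
    # CDS in genomic coordinates: transcript 13..24 (excl stop) lies in 5' half
    # -> genomic on exon2 (right), top strand positions:
    gtf_line("chr2", "CDS", e2e - 24L + 1L, e2e - 13L + 1L, "-", "g2", "t2"),
    gtf_line("chr2", "stop_codon", e2e - 27L + 1L, e2e - 25L + 1L, "-", "g2", "t2")
  ), genome)
  ts <- parse_annotation(f$gtf, f$fasta, verbose = FALSE)
  expect_equal(unname(ts$seq["t2"]), tx)
  expect_equal(ts$table$cds_start, cds_start)
  expect_equal(ts$table$cds_end, cds_end)
  expect_equal(ts$table$stop_codon, "TAA")
  # landmark: first in-frame 3'UTR stop is the planted TAG 12 nt downstream
  expect_equal(ts$table$tc3_pos, cds_end + 13L)
})

test_that("transcripts without both UTRs or with incomplete CDS are dropped", {
  seq1 <- paste0("ATG", strrep("GCT", 8), "TAA", strrep("C", 20))  # no 5'UTR
  seq2 <- paste0(strrep("A", 12), "ATG", strrep("GCT", 8), "TAA")  # no 3'UTR
  seq3 <- paste0(strrep("A", 12), "ATGGC", "TAA", strrep("C", 20)) # len%%3 != 0
  ok <- paste0(strrep("A", 12), "ATG", strrep("GCT", 8), "TAA", strrep("C", 20))
  genome <- c(c1 = seq1, c2 = seq2, c3 = seq3, c4 = ok)
  lines <- c(
    gtf_line("c1", "exon", 1, nchar(seq1), "+", "g1", "t1"),
    gtf_line("c1", "CDS", 1, 27, "+", "g1", "t1"),
    gtf_line("c1", "stop_codon", 28, 30, "+", "g1", "t1"),
    gtf_line("c2", "exon", 1, nchar(seq2), "+", "g2", "t2"),
    gtf_line("c2", "CDS", 13, 39, "+", "g2", "t2"),
    gtf_line("c2", "stop_codon", 40, 42, "+", "g2", "t2"),
    gtf_line("c3", "exon", 1, nchar(seq3), "+", "g3", "t3"),
    gtf_line("c3", "CDS", 13, 17, "+", "g3", "t3"),
    gtf_line("c3", "stop_codon", 18, 20, "+", "g3", "t3"),
    gtf_line("c4", "exon", 1, nchar(ok), "+", "g4", "t4"),
    gtf_line("c4", "CDS", 13, 39, "+", "g4", "t4"),
    gtf_line("c4", "stop_codon", 40, 42, "+", "g4", "t4"))
  f <- write_toy_gtf(lines, genome)
  ts <- parse_annotation(f$gtf, f$fasta, verbose = FALSE)
  expect_equal(ts$table$transcript_id, "t4")
})

test_that("missing chromosome in FASTA is a hard error naming the transcript", {
  seq <- paste0(strrep("A", 12), "ATG", strrep("GCT", 8), "TAA", strrep("C", 20))
  lines <- c(gtf_line("nochr", "exon", 1, nchar(seq), "+", "gX", "tX"),
             gtf_line("nochr", "CDS", 13, 36, "+", "gX", "tX"))
  f <- write_toy_gtf(lines, c(other = seq))
  expect_error(parse_annotation(f$gtf, f$fasta, verbose = FALSE), "tX")
})

test_that("landmark scan matches a brute-force oracle on random 3'UTRs", {
  set.seed(101)
  for (i in 1:300) {
    utr3 <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1),
                         replace = TRUE), collapse = "")
    seq <- paste0("AAAA", "ATG", "GCTGCA", "TAA", utr3)
    cds_end <- 4L + 13L
    got <- riboscr:::first_inframe_stop(seq, cds_end, nchar(seq))
    expect_identical(got, brute_first_stop(seq, cds_end))
  }
})

make_iso_gtf <- function() {
  # one gene, three isoforms sharing the same (3'-most) stop codon:
  #   tA: APPRIS principal, long 3'UTR; tB: CCDS only; tC: untagged
  core <- paste0("ATG", strrep("GCT", 10), "TAA")           # 36 nt CDS
  genome <- c(chrI = paste0(strrep("A", 50), core, strrep("C", 120)))
  cs <- 51L; ce <- 86L                                       # genomic CDS
  mk <- function(tx, s, e, extra) c(
    gtf_line("chrI", "exon", s, e, "+", "gI", tx, extra = extra),
    gtf_line("chrI", "CDS", cs, ce - 3L, "+", "gI", tx, extra = extra),
    gtf_line("chrI", "stop_codon", ce - 2L, ce, "+", "gI", tx, extra = extra))
  lines <- c(
    mk("tA", 31, 160, ' tag "appris_principal_1";'),
    mk("tB", 31, 120, ' tag "CCDS"; ccdsid "CCDS1.1";'),
    mk("tC", 31, 120, ""))
  write_toy_gtf(lines, genome)
}

test_that("selection cascade prefers APPRIS primary over CCDS and untagged", {
  f <- make_iso_gtf()
  ts <- parse_annotation(f$gtf, f$fasta, verbose = FALSE)
  expect_setequal(ts$table$transcript_id, c("tA", "tB", "tC"))
  expect_equal(ts$table[ts$table$transcript_id == "tA"]$appris, "primary")
  expect_true(ts$table[ts$table$transcript_id == "tB"]$is_ccds)
  sel <- select_transcripts(ts, verbose = FALSE)
  expect_equal(sel$table$transcript_id, "tA")
})

test_that("selection is order-independent and one transcript per gene", {
  f <- make_iso_gtf()
  ts <- parse_annotation(f$gtf, f$fasta, verbose = FALSE)
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    ts2 <- ts
    ts2$table <- ts$table[perm]
    ts2$seq <- ts$seq[perm]
    sel <- select_transcripts(ts2, verbose = FALSE)
    expect_equal(sel$table$transcript_id, "tA")
  }
  sel <- select_transcripts(ts, verbose = FALSE)
  expect_equal(anyDuplicated(sel$table$gene_id), 0L)
})

test_that("selected transcript overlapping the nearest same-strand gene is discarded", {
  core <- paste0("ATG", strrep("GCT", 10), "TAA")
  genome <- c(chrO = paste0(strrep("A", 50), core, strrep("C", 60),
                            strrep("A", 20), core, strrep("C", 60)))
  # gene 1 at 31..150; gene 2 exon overlaps gene 1's 3' exon region
  mk <- function(g, tx, s, e, cs, ce) c(
    gtf_line("chrO", "exon", s, e, "+", g, tx),
    gtf_line("chrO", "CDS", cs, ce - 3L, "+", g, tx),
    gtf_line("chrO", "stop_codon", ce - 2L, ce, "+", g, tx))
  lines <- c(mk("g1", "t1", 31, 150, 51, 86),
             mk("g2", "t2", 140, 262, 167, 202))
  f <- write_toy_gtf(lines, genome)
  ts <- parse_annotation(f$gtf, f$fasta, verbose = FALSE)
  sel <- select_transcripts(ts, verbose = FALSE)
  expect_equal(nrow(sel$table), 0L)  # mutual exon overlap removes both
})

test_that("UTR overlap with a pseudogene disqualifies the transcript", {
  core <- paste0("ATG", strrep("GCT", 10), "TAA")
  genome <- c(chrP = paste0(strrep("A", 50), core, strrep("C", 120)))
  lines <- c(
    gtf_line("chrP", "gene", 100, 140, "+", "pg1", "pg1t",
             gene_type = "processed_pseudogene"),
    gtf_line("chrP", "exon", 31, 160, "+", "gP", "tP"),
    gtf_line("chrP", "CDS", 51, 83, "+", "gP", "tP"),
    gtf_line("chrP", "stop_codon", 84, 86, "+", "gP", "tP"))
  f <- write_toy_gtf(lines, genome)
  ts <- parse_annotation(f$gtf, f$fasta, verbose = FALSE)
  expect_equal(nrow(ts$table), 1L)
  sel <- select_transcripts(ts, verbose = FALSE)
  expect_equal(nrow(sel$table), 0L)
})

test_that("find_landmarks agrees with the table and handles missing 3'TC", {
  ts <- toy_transcript(tc3 = FALSE)
  lm <- find_landmarks(ts, "TX1")
  expect_true(is.na(lm$tc3_pos))
  ts2 <- toy_transcript(inter_codons = 1L)
  lm2 <- find_landmarks(ts2, "TX1")
  expect_equal(lm2$tc3_pos, ts2$table$cds_end + 4L)  # one codon between
})
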