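# Footprint ingestion: projection, offset calibration, density tracks.

two_exon_ts <- function(strand = "+") {
  # 60 nt transcript: exon1 = 24 nt, exon2 = 36 nt, intron 20 nt
  tx <- paste0(strrep("A", 12), "ATG", strrep("GCT", 8), "TAA", strrep("C", 18))
  stopifnot(nchar(tx) == 60)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  if (strand == "+") {
    exons <- data.table::data.table(transcript_id = "tx", rank = 1:2,
                                    gstart = c(101L, 145L),
                                    gend = c(124L, 180L))
  } else {
    # transcript 5' exon (24 nt) is the genomic RIGHT exon on minus strand
    exons <- data.table::data.table(transcript_id = "tx", rank = 1:2,
                                    gstart = c(157L, 101L),
                                    gend = c(180L, 136L))
  }
  tab <- data.table::data.table(transcript_id = "tx", gene_id = "g",
                                chrom = "chrT", strand = strand, length = 60L,
                                cds_start = 13L, cds_end = 42L)
  transcript_set(tab, c(tx = tx), exons = exons)
}

test_that("genomic 5' ends project through splice junctions", {
  ts <- two_exon_ts("+")
  # 5' end at the first base of exon 2 -> transcript position 25
  hit <- project_to_transcript(ts, "tx", pos = 145L, cigar = "28M",
                               strand = "+", read_length = 28L)
  expect_equal(hit$five_prime, 25L)
  # intronic 5' end -> absent
  expect_null(project_to_transcript(ts, "tx", pos = 130L, cigar = "28M",
                                    strand = "+", read_length = 28L))
  # strand mismatch -> absent
  expect_null(project_to_transcript(ts, "tx", pos = 145L, cigar = "28M",
                                    strand = "-", read_length = 28L))
})

test_that("minus-strand 5' ends come from the rightmost aligned base", {
  ts <- two_exon_ts("-")
  # a 28-mer whose rightmost base is the genomic end of the right exon
  # (transcript position 1); spliced alignment 24M20N4M starting at 133
  hit <- project_to_transcript(ts, "tx", pos = 133L, cigar = "4M20N24M",
                               strand = "-", read_length = 28L)
  expect_equal(hit$five_prime, 1L)
})

test_that("transcript<->genome projection round-trips all exonic positions", {
  for (strand in c("+", "-")) {
    ts <- two_exon_ts(strand)
    g <- transcript_to_genome(ts, "tx", 1:60)
    back <- genome_to_transcript(ts, rep("chrT", 60), g, rep(strand, 60))
    expect_equal(back$tpos[order(back$idx)], 1:60)
  }
})

test_that("offset calibration recovers constructed shifts and breaks ties low", {
  ts <- toy_transcript(utr5 = 40L, n_codons = 60L)
  cs <- ts$table$cds_start
  # 28-mers with 5' ends exactly 12 nt upstream of the start codon -> 16
  fp <- data.table::data.table(transcript_id = "TX1",
                               five_prime = rep(cs - 12L, 250),
                               read_length = 28L)
  off <- calibrate_offsets(fp, ts, lengths = 28, min_reads = 200)
  expect_equal(unname(off["28"]), 16L)
  # two equally frequent shifts -> smaller chosen, with a warning
  fp2 <- data.table::data.table(transcript_id = "TX1",
                                five_prime = rep(c(cs - 12L, cs - 13L), 150),
                                read_length = 29L)
  expect_warning(off2 <- calibrate_offsets(fp2, ts, lengths = 29,
                                           min_reads = 200), "tie")
  expect_equal(unname(off2["29"]), 16L)
  # under the minimum -> fallback table
  fp3 <- fp[1:50]
  off3 <- calibrate_offsets(fp3, ts, lengths = 28, min_reads = 200)
  expect_equal(unname(off3["28"]), unname(default_offsets()["28"]))
  expect_error(calibrate_offsets(fp3, ts, lengths = 28, min_reads = 200,
                                 fallback = NULL))
})

test_that("offset calibration recovers an injected table exactly from reads", {
  spec <- simulation_spec(n_transcripts = 120, n_reads = 3e5)
  tx <- simulate_transcriptome(spec, 5)
  fp <- simulate_footprints(tx, 6)
  off <- calibrate_offsets(fp, tx$ts)
  expect_equal(off, spec$offsets)
})

test_that("density tracks place every read at its A-site centre", {
  ts <- toy_transcript(utr5 = 40L, n_codons = 60L)
  cs <- ts$table$cds_start
  # 10 identical 28-mers -> one position with raw 10
  fp <- data.table::data.table(transcript_id = "TX1",
                               five_prime = rep(cs - 12L, 10),
                               read_length = 28L)
  tr <- build_tracks(fp, ts, default_offsets())
  expect_equal(tr$raw$TX1[cs + 4L], 10)
  expect_equal(sum(tr$raw$TX1), 10)
  # mixed lengths over one codon land on the same nucleotide
  offs <- default_offsets()
  fp2 <- data.table::data.table(
    transcript_id = "TX1",
    five_prime = cs + 4L - unname(offs[as.character(28:35)]),
    read_length = 28:35)
  tr2 <- build_tracks(fp2, ts, offs)
  expect_equal(tr2$raw$TX1[cs + 4L], 8)
  expect_equal(sum(tr2$raw$TX1 != 0), 1L)
})

test_that("read conservation and off-transcript drops are accounted", {
  spec <- simulation_spec(n_transcripts = 50, n_reads = 5e4)
  tx <- simulate_transcriptome(spec, 9)
  fp <- simulate_footprints(tx, 10)
  tr <- build_tracks(fp, tx$ts, spec$offsets)
  cnt <- tr$counters
  expect_equal(sum(tr$total_reads), cnt[["assigned"]])
  expect_equal(cnt[["input"]],
               cnt[["length_excluded"]] + cnt[["off_transcript"]] +
                 cnt[["assigned"]])
})

test_that("global normalization gives rpm == raw at one million reads scale", {
  ts <- toy_transcript(utr5 = 40L, n_codons = 60L)
  cs <- ts$table$cds_start
  n <- 5000L
  fp <- data.table::data.table(transcript_id = "TX1",
                               five_prime = rep(cs - 12L, n),
                               read_length = 28L)
  tr <- build_tracks(fp, ts, default_offsets(), normalization = "global")
  expect_equal(tr$rpm$TX1[cs + 4L], n * 1e6 / n)
  # per-length mode: each length's counts scaled by its own total
  fp2 <- data.table::data.table(transcript_id = "TX1",
                                five_prime = c(rep(cs - 12L, 300),
                                               rep(cs - 13L, 100)),
                                read_length = rep(c(28L, 31L), c(300, 100)))
  tr2 <- build_tracks(fp2, ts, default_offsets(), normalization = "per_length")
  expect_equal(tr2$rpm$TX1[cs + 4L], 300 * 1e6 / 300 + 100 * 1e6 / 100)
})

test_that("SAM round trip preserves the footprint table", {
  spec <- simulation_spec(n_transcripts = 20, n_reads = 2000)
  tx <- simulate_transcriptome(spec, 21)
  fp <- simulate_footprints(tx, 22)
  sam <- tempfile(fileext = ".sam")
  write_sam(fp, tx, sam)
  fp2 <- read_alignments(sam, tx$ts, space = "transcript")
  setkey(fp, transcript_id, five_prime, read_length)
  k1 <- fp[order(transcript_id, five_prime, read_length)]
  k2 <- fp2[order(transcript_id, five_prime, read_length)]
  expect_equal(k1$transcript_id, k2$transcript_id)
  expect_equal(k1$five_prime, k2$five_prime)
  expect_equal(k1$read_length, k2$read_length)
})

test_that("genome-space SAM ingestion matches transcript-space ingestion", {
  spec <- simulation_spec(n_transcripts = 15, n_reads = 3000)
  tx <- simulate_transcriptome(spec, 31)
  gtf <- tempfile(fileext = ".gtf"); fa <- tempfile(fileext = ".fa")
  write_annotation(tx, gtf, fa, mode = "genome")
  ts_g <- parse_annotation(gtf, fa, verbose = FALSE)
  fp <- simulate_footprints(tx, 32)
  # project each footprint to the genome by hand and re-ingest
  sam <- tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6", "@SQ\tSN:chrS\tLN:100000")
  recs <- lapply(seq_len(nrow(fp)), function(i) {
    tid <- fp$transcript_id[i]
    g <- sort(transcript_to_genome(ts_g, tid,
                                   fp$five_prime[i]:(fp$five_prime[i] +
                                                       fp$read_length[i] - 1L)))
    brk <- c(0L, which(diff(g) != 1L), length(g))
    lens <- diff(brk)
    cig <- if (length(lens) == 1L) sprintf("%dM", lens) else
      paste0(lens[1], "M", g[brk[2] + 1L] - g[brk[2]] - 1L, "N", lens[2], "M")
    strand <- ts_g$table[ts_g$table$transcript_id == tid]$strand
    flag <- if (strand == "+") 0L else 16L
    sprintf("r%d\t%d\tchrS\t%d\t255\t%s\t*\t0\t0\t%s\t*", i, flag, g[1], cig,
            strrep("A", fp$read_length[i]))
  })
  writeLines(c(lines, unlist(recs)), sam)
  fp_g <- read_alignments(sam, ts_g, space = "genome")
  k1 <- as.data.table(fp)[order(transcript_id, five_prime, read_length)]
  k2 <- as.data.table(fp_g)[order(transcript_id, five_prime, read_length)]
  expect_equal(k1$transcript_id, k2$transcript_id)
  expect_equal(k1$five_prime, k2$five_prime)
})
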