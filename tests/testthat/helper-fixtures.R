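# Fixtures are built in code: hand-sized transcripts with exactly known
# landmarks, plus constructors for density tracks filled with chosen counts.

# a single transcript with a chosen 5'UTR, CDS codon count, inter-stop
# distance (codons strictly between NTC and planted 3'TC) and 3'UTR tail
toy_transcript <- function(id = "TX1", utr5 = 30L, n_codons = 40L,
                           inter_codons = 10L, tail_nt = 40L,
                           stop_codon = "TAA", tc3 = TRUE, plus4 = "G") {
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste,
                         collapse = ""), c("TAA", "TAG", "TGA"))
  cds <- c("ATG", rep("GCT", n_codons - 2L), stop_codon)
  inter <- rep("CCA", inter_codons)
  if (inter_codons > 0) inter[1] <- paste0(plus4, "CA")
  utr3 <- if (tc3) paste0(paste(inter, collapse = ""), "TGA",
                          paste(rep("C", tail_nt), collapse = ""))
          else paste(rep("C", tail_nt), collapse = "")
  seq <- paste0(paste(rep("A", utr5), collapse = ""),
                paste(cds, collapse = ""), utr3)
  tab <- data.table::data.table(
    transcript_id = id, gene_id = paste0("G", id), chrom = id, strand = "+",
    length = nchar(seq), cds_start = utr5 + 1L,
    cds_end = utr5 + 3L * n_codons)
  transcript_set(tab, stats::setNames(seq, id))
}

# DensityTrackSet with per-transcript raw vectors supplied (or a constant)
make_tracks <- function(ts, raw = NULL, value = 1) {
  lens <- stats::setNames(ts$table$length, ts$table$transcript_id)
  if (is.null(raw))
    raw <- lapply(lens, function(L) rep(value, L))
  rpm <- raw
  structure(list(raw = raw, rpm = rpm,
                 total_reads = vapply(raw, sum, 0),
                 counters = c(assigned = sum(vapply(raw, sum, 0))),
                 offsets = default_offsets(), normalization = "per_length"),
            class = "DensityTrackSet")
}

# minimal GENCODE-flavoured GTF + FASTA pair written to tempfiles
write_toy_gtf <- function(lines, genome) {
  gtf <- tempfile(fileext = ".gtf")
  fa <- tempfile(fileext = ".fa")
  writeLines(lines, gtf)
  seqs <- Biostrings::DNAStringSet(genome)
  names(seqs) <- names(genome)
  Biostrings::writeXStringSet(seqs, fa)
  list(gtf = gtf, fasta = fa)
}

gtf_line <- function(chrom, type, s, e, strand, gene, tx,
                     gene_type = "protein_coding", extra = "") {
  attrs <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; ',
                          'gene_type "%s"; transcript_type "%s";%s'),
                   gene, tx, gene_type, gene_type, extra)
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, s, e, strand, attrs)
}

# brute-force scan for the first in-frame 3'UTR stop (independent oracle)
brute_first_stop <- function(seq, cds_end) {
  stops <- c("TAA", "TAG", "TGA")
  cand <- integer(0)
  for (p in seq_len(nchar(seq) - 2L)) {
    if (substr(seq, p, p + 2L) %in% stops &&
        p > cds_end && (p - cds_end - 1L) %% 3L == 0L)
      cand <- c(cand, p)
  }
  if (length(cand)) min(cand) else NA_integer_
}
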