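#' Transcript model container
#'
#' A `TranscriptSet` bundles one row per transcript (coordinates, CDS bounds,
#' selection attributes, stop-codon landmarks), the spliced transcript
#' sequences, and (for genome-space sets) the exon chains needed to project
#' genomic positions onto transcripts.
#'
#' All coordinates are 1-based and closed, the R/Bioconductor convention:
#' `cds_start` is the first nucleotide of the start codon and `cds_end` the
#' last nucleotide of the stop codon, both in transcript space. Landmarks are
#' derived eagerly: `ntc_pos = cds_end - 2` (first nucleotide of the normal
#' termination codon, NTC), `plus4` the nucleotide immediately 3' of the stop,
#' and `tc3_pos` the first nucleotide of the first in-frame stop codon in the
#' 3'UTR (NA when the 3'UTR contains none).
#'
#' @param table data.table/data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `length`, `cds_start`, `cds_end` and optionally
#'   `appris` ("primary"/"alternative"/"none") and `is_ccds`.
#' @param seq named character vector of transcript sequences (DNA alphabet,
#'   transcript orientation), names matching `transcript_id`.
#' @param exons optional data.table with columns `transcript_id`, `rank`
#'   (1 = 5'-most exon along the transcript), `gstart`, `gend` (1-based closed
#'   genomic coordinates). NULL for transcript-space-only sets.
#' @param pseudogenes optional `GRanges` of pseudogene loci (used by the
#'   UTR-overlap filter in [select_transcripts()]).
#' @return object of class `TranscriptSet`.
#' @export
transcript_set <- function(table, seq, exons = NULL, pseudogenes = NULL) {
  tab <- as.data.table(table)
  need <- c("transcript_id", "gene_id", "chrom", "strand", "length",
            "cds_start", "cds_end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("transcript table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"appris" %in% names(tab)) tab[, appris := "none"]
  if (!"is_ccds" %in% names(tab)) tab[, is_ccds := FALSE]
  if (anyDuplicated(tab$transcript_id))
    stop("duplicated transcript_id in transcript table")
  if (!all(tab$transcript_id %in% names(seq)))
    stop("sequences missing for some transcripts")
  seq <- toupper(seq[tab$transcript_id])

  bad <- tab[!(cds_start >= 1 & cds_start < cds_end & cds_end <= length)]
  if (nrow(bad)) stop("invalid CDS bounds for: ",
                      paste(head(bad$transcript_id, 5), collapse = ", "))
  cl <- tab$cds_end - tab$cds_start + 1L
  if (any(cl %% 3L != 0L | cl < 6L))
    stop("CDS length must be a positive multiple of 3 (>= 6)")
  if (any(nchar(seq) != tab$length))
    stop("sequence length disagrees with transcript length")
  stop_cod <- substr(seq, tab$cds_end - 2L, tab$cds_end)
  if (!all(stop_cod %in% STOP_CODONS))
    stop("CDS does not end in a stop codon for: ",
         paste(head(tab$transcript_id[!stop_cod %in% STOP_CODONS], 5),
               collapse = ", "))

  if (!is.null(exons)) {
    exons <- as.data.table(exons)[, .(transcript_id, rank, gstart, gend)]
    wsum <- exons[, .(w = sum(gend - gstart + 1L)), by = transcript_id]
    chk <- merge(tab[, .(transcript_id, length)], wsum, by = "transcript_id")
    if (!all(chk$w == chk$length))
      stop("exon widths do not sum to transcript length")
    setorder(exons, transcript_id, rank)
    exons[, cumlen := cumsum(data.table::shift(gend - gstart + 1L, fill = 0L)),
          by = transcript_id]
  }

  obj <- structure(list(table = tab, seq = seq, exons = exons,
                        pseudogenes = pseudogenes),
                   class = "TranscriptSet")
  drop <- intersect(names(tab), names(LANDMARK_COLS))
  base <- if (length(drop)) tab[, setdiff(names(tab), drop), with = FALSE] else tab
  obj$table <- cbind(base, stop_landmarks(obj))
  obj
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
LANDMARK_COLS <- c(ntc_pos = 0L, stop_codon = "", plus4 = "", tc3_pos = 0L,
                   utr3_len = 0L, utr5_len = 0L)

#' Stop-codon landmarks for every transcript
#'
#' Locates, per transcript, the NTC, the +4 nucleotide and the first in-frame
#' stop codon of the 3'UTR (3'TC), scanning codons downstream of the CDS in
#' steps of 3 nt.
#'
#' @param ts TranscriptSet (or the bare list passed during construction).
#' @return data.table with columns `ntc_pos`, `stop_codon`, `plus4`,
#'   `tc3_pos` (NA if the 3'UTR has no in-frame stop), `utr3_len`, `utr5_len`.
#' @export
stop_landmarks <- function(ts) {
  tab <- ts$table
  seq <- ts$seq
  ntc <- tab$cds_end - 2L
  data.table(
    ntc_pos = ntc,
    stop_codon = substr(seq, ntc, tab$cds_end),
    plus4 = ifelse(tab$cds_end < tab$length,
                   substr(seq, tab$cds_end + 1L, tab$cds_end + 1L), NA_character_),
    tc3_pos = mapply(first_inframe_stop, seq, tab$cds_end, tab$length,
                     USE.NAMES = FALSE),
    utr3_len = tab$length - tab$cds_end,
    utr5_len = tab$cds_start - 1L
  )
}

# first in-frame stop codon start strictly 3' of the CDS; NA when none fits
first_inframe_stop <- function(seq, cds_end, len) {
  p <- cds_end + 1L
  while (p + 2L <= len) {
    if (substr(seq, p, p + 2L) %in% STOP_CODONS) return(p)
    p <- p + 3L
  }
  NA_integer_
}

#' Landmarks for a single transcript
#'
#' @param ts TranscriptSet.
#' @param transcript_id transcript identifier.
#' @return named list with `ntc_pos`, `stop_codon`, `plus4`, `tc3_pos`,
#'   `utr3_len`.
#' @export
find_landmarks <- function(ts, transcript_id) {
  row <- ts$table[transcript_id, on = "transcript_id", nomatch = NULL]
  if (!nrow(row)) stop("unknown transcript: ", transcript_id)
  as.list(row[, .(ntc_pos, stop_codon, plus4, tc3_pos, utr3_len)])
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat(sprintf("TranscriptSet: %d transcripts, %d genes%s\n",
              nrow(x$table), data.table::uniqueN(x$table$gene_id),
              if (is.null(x$exons)) " (transcript space)" else ""))
  cat(sprintf("  with in-frame 3'TC: %d (%.1f%%)\n",
              sum(!is.na(x$table$tc3_pos)),
              100 * mean(!is.na(x$table$tc3_pos))))
  invisible(x)
}

#' @export
`[.TranscriptSet` <- function(x, i, ...) {
  ids <- if (is.character(i)) i else x$table$transcript_id[i]
  structure(list(
    table = x$table[ids, on = "transcript_id"],
    seq = x$seq[ids],
    exons = if (is.null(x$exons)) NULL else
      x$exons[ids, on = "transcript_id", nomatch = NULL],
    pseudogenes = x$pseudogenes
  ), class = "TranscriptSet")
}

# ---- coordinate projection -------------------------------------------------

#' Map a transcript coordinate to the genome
#'
#' @param ts TranscriptSet with exon chains.
#' @param transcript_id single transcript identifier.
#' @param tpos vector of 1-based transcript coordinates.
#' @return integer vector of genomic coordinates.
#' @export
transcript_to_genome <- function(ts, transcript_id, tpos) {
  if (is.null(ts$exons)) stop("TranscriptSet has no exon chains")
  ex <- ts$exons[transcript_id, on = "transcript_id", nomatch = NULL]
  if (!nrow(ex)) stop("unknown transcript: ", transcript_id)
  strand <- ts$table[transcript_id, on = "transcript_id"]$strand
  idx <- findInterval(tpos - 1L, ex$cumlen)
  if (any(idx < 1L | tpos > sum(ex$gend - ex$gstart + 1L)))
    stop("transcript coordinate outside transcript")
  off <- tpos - ex$cumlen[idx]  # 1-based offset within exon, 5'->3'
  if (strand == "+") ex$gstart[idx] + off - 1L else ex$gend[idx] - off + 1L
}

#' Map genomic 5' ends onto transcripts
#'
#' Projects genomic positions through exon chains onto transcript coordinates.
#' A position projects only onto transcripts on the matching chromosome and
#' strand whose exons contain it; intronic/intergenic positions are dropped.
#'
#' @param ts TranscriptSet with exon chains.
#' @param chrom,gpos,strand parallel vectors describing genomic positions.
#' @return data.table with columns `idx` (index into the input vectors),
#'   `transcript_id`, `tpos`.
#' @export
genome_to_transcript <- function(ts, chrom, gpos, strand) {
  if (is.null(ts$exons)) stop("TranscriptSet has no exon chains")
  ex <- merge(ts$exons,
              ts$table[, .(transcript_id, chrom, strand)],
              by = "transcript_id")
  ex_gr <- GenomicRanges::GRanges(ex$chrom,
                                  IRanges::IRanges(ex$gstart, ex$gend),
                                  strand = ex$strand)
  q_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(gpos, gpos),
                                 strand = strand)
  hits <- GenomicRanges::findOverlaps(q_gr, ex_gr)
  qi <- S4Vectors::queryHits(hits); ei <- S4Vectors::subjectHits(hits)
  off <- ifelse(ex$strand[ei] == "+",
                gpos[qi] - ex$gstart[ei] + 1L,
                ex$gend[ei] - gpos[qi] + 1L)
  data.table(idx = qi,
             transcript_id = ex$transcript_id[ei],
             tpos = ex$cumlen[ei] + off)
}
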