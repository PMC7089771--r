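#' Default A-site offset tables
#'
#' Read-length-specific shifts from a footprint's 5' end to the nucleotide at
#' the centre of the A-site codon. `default_offsets()` covers full-length
#' ribosome-protected fragments (28-35 nt); `short_read_offsets()` covers the
#' empty-A-site 20-23 nt class, which is ingestible but excluded from all
#' analyses by default.
#'
#' @return named integer vector (names = read lengths).
#' @export
default_offsets <- function() {
  c(`28` = 16L, `29` = 16L, `30` = 16L, `31` = 17L,
    `32` = 17L, `33` = 17L, `34` = 17L, `35` = 17L)
}

#' @rdname default_offsets
#' @export
short_read_offsets <- function() {
  c(`20` = 16L, `21` = 16L, `22` = 17L, `23` = 17L)
}

#' Read aligned footprints from SAM/BAM
#'
#' Loads primary alignments (secondary and unmapped records are discarded)
#' and reduces each to its 5' end. For transcript-space alignments
#' (`space = "transcript"`, references are transcript ids) minus-strand
#' records are dropped with a counter. For genome-space alignments the
#' genomic 5' end (alignment start on `+`, alignment end on `-`) is projected
#' through the exon chains of `ts` onto transcript coordinates; reads whose
#' 5' end falls outside exons, or on the wrong strand, are dropped.
#'
#' @param path SAM or BAM file.
#' @param ts TranscriptSet (required for `space = "genome"`).
#' @param space `"transcript"` or `"genome"`.
#' @param min_len,max_len read-length bounds for assignment (the 15-40 nt
#'   assignment window; analysis windows are narrowed later).
#' @param min_mapq drop reads below this MAPQ (0 keeps all primary records).
#' @return `footprints` object: data.table (`transcript_id`, `five_prime`,
#'   `read_length`) with a `counters` attribute.
#' @export
read_alignments <- function(path, ts = NULL, space = c("transcript", "genome"),
                            min_len = 15L, max_len = 40L, min_mapq = 0L) {
  space <- match.arg(space)
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag,
                               what = c("rname", "strand", "pos", "cigar",
                                        "qwidth", "mapq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  dt <- data.table(rname = as.character(x$rname), strand = as.character(x$strand),
                   pos = x$pos, cigar = x$cigar, read_length = x$qwidth,
                   mapq = x$mapq)
  counters <- c(total = nrow(dt))
  dt <- dt[!is.na(pos)]
  if (min_mapq > 0L) {
    n0 <- nrow(dt); dt <- dt[is.na(mapq) | mapq >= min_mapq]
    counters["low_mapq"] <- n0 - nrow(dt)
  }
  n0 <- nrow(dt)
  dt <- dt[read_length >= min_len & read_length <= max_len]
  counters["length_out_of_range"] <- n0 - nrow(dt)

  if (space == "transcript") {
    n0 <- nrow(dt)
    dt <- dt[strand == "+"]
    counters["wrong_strand"] <- n0 - nrow(dt)
    fp <- dt[, .(transcript_id = rname, five_prime = pos, read_length)]
    if (!is.null(ts)) {
      n0 <- nrow(fp)
      fp <- fp[transcript_id %in% ts$table$transcript_id]
      counters["unknown_reference"] <- n0 - nrow(fp)
    }
  } else {
    if (is.null(ts)) stop("genome-space input requires a TranscriptSet")
    ref_w <- cigar_ref_width(dt$cigar)
    g5 <- ifelse(dt$strand == "+", dt$pos, dt$pos + ref_w - 1L)
    hits <- genome_to_transcript(ts, dt$rname, g5, dt$strand)
    counters["unassigned_5p"] <- nrow(dt) - uniqueN(hits$idx)
    counters["multi_transcript"] <- nrow(hits) - uniqueN(hits$idx)
    fp <- data.table(transcript_id = hits$transcript_id,
                     five_prime = hits$tpos,
                     read_length = dt$read_length[hits$idx])
  }
  counters["assigned"] <- nrow(fp)
  structure(fp, counters = counters, class = c("footprints", class(fp)))
}

# reference-space width of a CIGAR string (M/D/N/=/X consume the reference)
cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(ops) {
    n <- as.integer(sub("[A-Z=]$", "", ops))
    sum(n[grepl("[MDN=X]$", ops)])
  }, 0L)
}

#' Project one genome-space alignment onto a transcript
#'
#' Single-read convenience around the vectorized projection used by
#' [read_alignments()]: maps the genomic 5' end of an alignment through a
#' transcript's exon chain.
#'
#' @param ts TranscriptSet with exon chains.
#' @param transcript_id target transcript.
#' @param pos 1-based leftmost genomic alignment position.
#' @param cigar CIGAR string.
#' @param strand alignment strand ("+"/"-").
#' @param read_length read (query) length.
#' @return list(`transcript_id`, `five_prime`, `read_length`) or NULL when the
#'   5' end is not exonic or strands disagree.
#' @export
project_to_transcript <- function(ts, transcript_id, pos, cigar, strand,
                                  read_length) {
  row <- ts$table[transcript_id, on = "transcript_id", nomatch = NULL]
  if (!nrow(row) || row$strand != strand) return(NULL)
  g5 <- if (strand == "+") pos else pos + cigar_ref_width(cigar) - 1L
  hits <- genome_to_transcript(ts[transcript_id], row$chrom, g5, strand)
  if (!nrow(hits)) return(NULL)
  list(transcript_id = transcript_id, five_prime = hits$tpos[1],
       read_length = read_length)
}

#' Calibrate length-specific A-site offsets at start codons
#'
#' Footprints whose 5' ends fall within `window` nt upstream of an annotated
#' start codon are used as calibration reads. For each read length the offset
#' is the mode over calibration reads of `cds_start + 4 - five_prime`: the
#' shift that places the start codon in the P site and therefore the A-site
#' codon centre at `cds_start + 4`. Candidate shifts are restricted to
#' 10-20 nt; equal-frequency ties resolve to the smaller shift with a
#' warning. Lengths with fewer than `min_reads` calibration reads fall back
#' to `fallback` (an error if `fallback` is NULL).
#'
#' @param fp footprints table from [read_alignments()] or
#'   [simulate_footprints()].
#' @param ts TranscriptSet supplying `cds_start` per transcript.
#' @param lengths read lengths to calibrate.
#' @param min_reads minimum calibration reads per length.
#' @param window how far upstream of the start codon 5' ends may fall.
#' @param fallback named offset vector used for uncalibratable lengths.
#' @return named integer offset vector over `lengths`.
#' @export
calibrate_offsets <- function(fp, ts, lengths = 28:35, min_reads = 200L,
                              window = 40L, fallback = default_offsets()) {
  cal <- merge(as.data.table(fp),
               ts$table[, .(transcript_id, cds_start)], by = "transcript_id")
  cal <- cal[five_prime >= cds_start - window & five_prime < cds_start]
  cal[, shift_nt := cds_start + 4L - five_prime]
  cal <- cal[shift_nt >= 10L & shift_nt <= 20L]
  out <- setNames(integer(length(lengths)), as.character(lengths))
  for (L in lengths) {
    sh <- cal[read_length == L, shift_nt]
    if (length(sh) < min_reads) {
      fb <- fallback[as.character(L)]
      if (is.null(fallback) || is.na(fb))
        stop("length ", L, " has too few calibration reads and no fallback")
      out[as.character(L)] <- fb
      next
    }
    tt <- table(sh)
    best <- as.integer(names(tt)[tt == max(tt)])
    if (length(best) > 1L)
      warning("offset tie for length ", L, " (",
              paste(best, collapse = ","), "); using smallest")
    out[as.character(L)] <- min(best)
  }
  out
}

#' Build per-transcript A-site density tracks
#'
#' Each footprint contributes one count at its A-site codon centre,
#' `five_prime + offset[read_length]` (the A-site codon start is the centre
#' minus 1). Reads outside `lengths`, or whose shifted A-site falls beyond
#' the transcript 3' end, are dropped with counters. Depth-normalised
#' densities (RPM) divide raw counts by millions of assigned reads either
#' per read length (`"per_length"`, the default) or over all lengths
#' (`"global"`); ratio statistics downstream are invariant to this choice
#' within a single library.
#'
#' @param fp footprints table.
#' @param ts TranscriptSet.
#' @param offsets named offset vector covering `lengths`.
#' @param lengths read lengths retained for analysis (full-length RPFs).
#' @param normalization `"per_length"` or `"global"`.
#' @return `DensityTrackSet`: list with `raw` and `rpm` (named lists of
#'   per-nucleotide numeric vectors), `total_reads` (named vector), plus
#'   `counters`, `offsets`, `normalization`.
#' @export
build_tracks <- function(fp, ts, offsets = default_offsets(),
                         lengths = 28:35,
                         normalization = c("per_length", "global")) {
  normalization <- match.arg(normalization)
  if (!all(as.character(lengths) %in% names(offsets)))
    stop("offsets do not cover all requested read lengths")
  dt <- as.data.table(fp)
  counters <- c(input = nrow(dt))
  dt <- dt[read_length %in% lengths]
  counters["length_excluded"] <- counters[["input"]] - nrow(dt)
  dt <- merge(dt, ts$table[, .(transcript_id, length)], by = "transcript_id")
  dt[, a_center := five_prime + offsets[as.character(read_length)]]
  n0 <- nrow(dt)
  dt <- dt[a_center >= 1L & a_center <= length]
  counters["off_transcript"] <- n0 - nrow(dt)
  counters["assigned"] <- nrow(dt)

  per_len <- dt[, .N, by = read_length]
  wt <- if (normalization == "per_length") {
    setNames(1e6 / per_len$N, as.character(per_len$read_length))
  } else setNames(rep(1e6 / nrow(dt), nrow(per_len)),
                  as.character(per_len$read_length))
  dt[, rpm := wt[as.character(read_length)]]

  tx_len <- setNames(ts$table$length, ts$table$transcript_id)
  raw_l <- rpm_l <- setNames(vector("list", length(tx_len)), names(tx_len))
  for (tid in names(tx_len)) {
    raw_l[[tid]] <- numeric(tx_len[[tid]])
    rpm_l[[tid]] <- numeric(tx_len[[tid]])
  }
  if (nrow(dt)) {
    agg <- dt[, .(n = .N, w = sum(rpm)), by = .(transcript_id, a_center)]
    for (tid in unique(agg$transcript_id)) {
      a <- agg[transcript_id == tid]
      raw_l[[tid]][a$a_center] <- a$n
      rpm_l[[tid]][a$a_center] <- a$w
    }
  }
  totals <- vapply(raw_l, sum, 0)
  structure(list(raw = raw_l, rpm = rpm_l, total_reads = totals,
                 counters = counters, offsets = offsets[as.character(lengths)],
                 normalization = normalization),
            class = "DensityTrackSet")
}

#' @export
print.DensityTrackSet <- function(x, ...) {
  cat(sprintf("DensityTrackSet: %d transcripts, %.0f assigned reads (%s RPM)\n",
              length(x$raw), sum(x$total_reads), x$normalization))
  invisible(x)
}

#' Export density tracks as a wiggle-like TSV
#'
#' One row per non-zero position: `transcript_id`, `position`, `raw`, `rpm`.
#'
#' @param tracks DensityTrackSet.
#' @param path output TSV path.
#' @param report_path optional JSON run-report path (counters, offsets,
#'   normalization mode).
#' @return invisibly, the exported table.
#' @export
export_tracks <- function(tracks, path, report_path = NULL) {
  out <- rbindlist(lapply(names(tracks$raw), function(tid) {
    nz <- which(tracks$raw[[tid]] != 0)
    if (!length(nz)) return(NULL)
    data.table(transcript_id = tid, position = nz,
               raw = tracks$raw[[tid]][nz], rpm = tracks$rpm[[tid]][nz])
  }))
  write_tsv(out, path)
  if (!is.null(report_path)) {
    jsonlite::write_json(
      list(counters = as.list(tracks$counters),
           offsets = as.list(tracks$offsets),
           normalization = tracks$normalization),
      report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
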