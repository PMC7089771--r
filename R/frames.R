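#' Reading-frame composition of A-site density
#'
#' Assigns every A-site count to a reading frame relative to the annotated
#' CDS start: a count stored at codon-centre position `c` has A-site codon
#' start `p = c - 1` and frame `(p - cds_start) mod 3`, with residue classes
#' {0, 1, 2} reported as frames {0, +1, -1}. Densities are CDS-normalized
#' per transcript before summation, so fractions are invariant to
#' expression differences.
#'
#' @param tracks DensityTrackSet.
#' @param ts TranscriptSet.
#' @param region `"CDS"` (codon starts within the CDS) or `"UTR3"` (codon
#'   starts 3' of the stop codon).
#' @return data.table (`region`, `frame` in c("0","+1","-1"), `fraction`);
#'   fractions sum to 1.
#' @export
frame_fractions <- function(tracks, ts, region = c("CDS", "UTR3")) {
  region <- match.arg(region)
  sums <- c(`0` = 0, `1` = 0, `2` = 0)
  used <- 0L
  for (i in seq_len(nrow(ts$table))) {
    r <- ts$table[i]
    raw <- tracks$raw[[r$transcript_id]]
    cds_mean <- mean(raw[r$cds_start:r$cds_end])
    if (cds_mean <= 0) next
    p_range <- if (region == "CDS") r$cds_start:r$cds_end else {
      if (r$cds_end + 1L > r$length - 1L) next
      (r$cds_end + 1L):(r$length - 1L)
    }
    centers <- p_range + 1L
    vals <- raw[centers] / cds_mean
    fr <- (p_range - r$cds_start) %% 3L
    s <- vapply(0:2, function(f) sum(vals[fr == f]), 0)
    sums <- sums + s
    used <- used + 1L
  }
  if (used == 0L || sum(sums) <= 0) stop("no density in region ", region)
  data.table(region = region, frame = c("0", "+1", "-1"),
             fraction = as.numeric(sums / sum(sums)))
}

#' Frame-resolved metagene around the first 3'UTR stop codon
#'
#' Transcripts are classed by the reading frame (0, +1, -1 relative to the
#' CDS) of the first stop codon encountered in their 3'UTR in that frame;
#' the search is run independently per frame. For each class,
#' depth-normalized (RPM) densities are summed per position over a window
#' from 12 nt upstream to 12 nt downstream of the stop (position 0 = first
#' nucleotide of the stop). Transcripts with additional same-frame stop
#' codons inside the window are discarded, as are transcripts whose window
#' extends beyond the transcript.
#'
#' @param tracks DensityTrackSet.
#' @param ts TranscriptSet.
#' @param flank window half-width in nt.
#' @return data.table (`frame`, `position`, `density`, `n_transcripts`).
#' @export
tc3_frame_metagene <- function(tracks, ts, flank = 12L) {
  out <- list()
  for (fl in c("0", "+1", "-1")) {
    res <- c(`0` = 0L, `+1` = 1L, `-1` = 2L)[[fl]]
    acc <- numeric(2L * flank + 1L)
    n <- 0L
    for (i in seq_len(nrow(ts$table))) {
      r <- ts$table[i]
      seq <- ts$seq[[r$transcript_id]]
      # first position > cds_end in residue class `res` w.r.t. cds_start
      p <- r$cds_end + 1L
      p <- p + (res - (p - r$cds_start)) %% 3L
      anchor <- NA_integer_
      while (p + 2L <= r$length) {
        if (substr(seq, p, p + 2L) %in% STOP_CODONS) { anchor <- p; break }
        p <- p + 3L
      }
      if (is.na(anchor)) next
      if (anchor - flank < 1L || anchor + flank > r$length) next
      # discard on additional same-frame stops inside the window
      extra <- FALSE
      for (q in seq(anchor - flank, anchor + flank, by = 3L)) {
        if (q == anchor || q < 1L || q + 2L > r$length) next
        if (substr(seq, q, q + 2L) %in% STOP_CODONS) { extra <- TRUE; break }
      }
      if (extra) next
      acc <- acc + tracks$rpm[[r$transcript_id]][(anchor - flank):(anchor + flank)]
      n <- n + 1L
    }
    out[[fl]] <- data.table(frame = fl, position = -flank:flank,
                            density = acc, n_transcripts = n)
  }
  rbindlist(out)
}

#' Per-codon A-site occupancy (pause scores)
#'
#' For every occurrence of each of the 61 sense codons (skipping the first
#' and last two codons of each CDS), the raw A-site density within the
#' codon's 3-nt window is divided by the transcript's mean CDS density
#' (computed excluding the first and last 15 nt of the CDS). The occupancy
#' of a codon is the mean of this ratio over all its occurrences.
#'
#' @param tracks DensityTrackSet.
#' @param ts TranscriptSet.
#' @return data.table (`codon` (RNA alphabet), `amino_acid`, `occupancy`,
#'   `n`), one row per sense codon; codons never observed get `n = 0` and
#'   `occupancy = NA`.
#' @export
codon_occupancy <- function(tracks, ts) {
  per_tx <- lapply(seq_len(nrow(ts$table)), function(i) {
    r <- ts$table[i]
    raw <- tracks$raw[[r$transcript_id]]
    trim <- (r$cds_start + 15L):(r$cds_end - 15L)
    if (length(trim) < 3L) return(NULL)
    cds_mean <- mean(raw[trim])
    if (cds_mean <= 0) return(NULL)
    n_codons <- (r$cds_end - r$cds_start + 1L) %/% 3L
    if (n_codons < 5L) return(NULL)
    idx <- seq(3L, n_codons - 2L)      # skip first/last two codons
    starts <- r$cds_start + 3L * (idx - 1L)
    cods <- substring(ts$seq[[r$transcript_id]], starts, starts + 2L)
    cnt <- raw[starts] + raw[starts + 1L] + raw[starts + 2L]
    data.table(codon = cods, ratio = (cnt / 3) / cds_mean)
  })
  occ <- rbindlist(per_tx)
  if (!nrow(occ)) stop("no transcript with positive trimmed CDS density")
  occ <- occ[!codon %in% STOP_CODONS,
             .(occupancy = mean(ratio), n = .N), by = codon]
  out <- merge(data.table(codon = sense_codons()), occ,
               by = "codon", all.x = TRUE)
  out[is.na(n), n := 0L]
  out[, amino_acid := unlist(GENETIC_CODE_1[codon])]
  out[, codon := dna_to_rna(codon)]
  out[order(codon), .(codon, amino_acid, occupancy, n)]
}

sense_codons <- function() {
  all <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                           c("T", "C", "A", "G"), stringsAsFactors = FALSE),
               1, paste, collapse = "")
  setdiff(all, STOP_CODONS)
}

GENETIC_CODE_1 <- as.list(Biostrings::GENETIC_CODE)
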