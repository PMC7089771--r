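#' Ribosome ReadThrough Score (RRTS)
#'
#' For every transcript, RRTS is the ribosome density (counts per nt) in the
#' 3'UTR between the normal termination codon (NTC) and the first in-frame
#' 3'UTR stop codon (3'TC), divided by the density over the coding sequence.
#' The CDS window excludes the first 18 and last 15 nt of the CDS (start /
#' stop-codon peaks); the extension window starts 6 nt after the NTC and ends
#' at the nucleotide before the 3'TC.
#'
#' Transcripts are excluded (with exactly one reason, checked in this order)
#' when: fewer than `min_reads` reads map anywhere on the transcript
#' (`low_reads`); the 3'UTR has no in-frame stop (`no_3tc`); fewer than
#' `min_codons` complete codons lie between the NTC and the 3'TC
#' (`short_extension`); or the CDS window has zero density (`zero_cds`).
#'
#' @param tracks DensityTrackSet (raw counts are used; RRTS is invariant to
#'   depth normalization).
#' @param ts TranscriptSet.
#' @param min_reads minimum reads mapped to the transcript (default 128).
#' @param min_codons minimum complete codons strictly between NTC and 3'TC.
#' @return data.table, one row per transcript: `transcript_id`,
#'   `total_reads`, `cds_density`, `ext_density`, `rrts`, `status`
#'   ("included"/"excluded"), `reason`.
#' @export
compute_rrts <- function(tracks, ts, min_reads = 128L, min_codons = 5L) {
  tab <- ts$table
  res <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i]
    raw <- tracks$raw[[r$transcript_id]]
    total <- sum(raw)
    rec <- data.table(transcript_id = r$transcript_id, total_reads = total,
                      cds_density = NA_real_, ext_density = NA_real_,
                      rrts = NA_real_, status = "excluded", reason = NA_character_)
    if (total < min_reads) { rec$reason <- "low_reads"; return(rec) }
    if (is.na(r$tc3_pos)) { rec$reason <- "no_3tc"; return(rec) }
    if (r$tc3_pos - r$cds_end < 3L * min_codons + 1L) {
      rec$reason <- "short_extension"; return(rec)
    }
    cds_win <- (r$cds_start + 18L):(r$cds_end - 15L)
    cds_den <- mean(raw[cds_win])
    if (cds_den <= 0) { rec$reason <- "zero_cds"; return(rec) }
    ext_win <- (r$cds_end + 7L):(r$tc3_pos - 1L)
    rec$cds_density <- cds_den
    rec$ext_density <- mean(raw[ext_win])
    rec$rrts <- rec$ext_density / cds_den
    rec$status <- "included"
    rec
  })
  rbindlist(res)
}

#' Log2-transform RRTS values for plotting
#'
#' Zero scores are assigned the arbitrarily small value 2^-15 so they can be
#' displayed on a log scale; `drop_zeros = TRUE` returns the transform with
#' zeros removed instead (as used for correlation statistics).
#'
#' @param rrts numeric RRTS values (included records).
#' @param floor replacement for zeros.
#' @param drop_zeros drop zeros rather than flooring them.
#' @return numeric vector of log2 values.
#' @export
log_transform_rrts <- function(rrts, floor = 2^-15, drop_zeros = FALSE) {
  if (drop_zeros) return(log2(rrts[rrts > 0]))
  log2(ifelse(rrts == 0, floor, rrts))
}

#' Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()] with the policy used
#' throughout the package: exact enumeration when both groups have fewer
#' than `exact_below` observations and there are no ties, otherwise the
#' normal approximation with continuity and tie correction.
#'
#' @param x,y numeric samples.
#' @param alternative "two.sided", "greater" (x tends larger), or "less".
#' @param exact_below exact p-values when both n's are below this.
#' @return list(`U`, `p`, `n1`, `n2`, `method`).
#' @export
mw_u_test <- function(x, y, alternative = "two.sided", exact_below = 8L) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) < exact_below && length(y) < exact_below && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y),
       method = if (exact) "exact" else "normal")
}

#' Compare RRTS distributions by stop-codon identity
#'
#' Groups included RRTS records by the 3-nt stop codon (`grouping =
#' "stop3"`; all pairwise two-sided Mann-Whitney U tests) or by the 4-nt
#' stop signal (`"stop4"`; per-group summaries plus, within each 3-nt stop
#' codon, a one-sided test of whether a C at the +4 position increases
#' RRTS relative to all other +4 nucleotides).
#'
#' @param records RRTS table from [compute_rrts()].
#' @param ts TranscriptSet supplying `stop_codon` and `plus4`.
#' @param grouping "stop3" or "stop4".
#' @return list(`summary` = per-group n/median/quartiles, `tests` =
#'   pairwise comparison table with U and p).
#' @export
compare_rrts_by_stop <- function(records, ts, grouping = c("stop3", "stop4")) {
  grouping <- match.arg(grouping)
  d <- merge(records[status == "included", .(transcript_id, rrts)],
             ts$table[, .(transcript_id, stop_codon, plus4)],
             by = "transcript_id")
  d[, group := if (grouping == "stop3") dna_to_rna(stop_codon) else
    paste0(dna_to_rna(stop_codon), dna_to_rna(plus4))]
  empty <- d[, .N, by = group][N < 2L, group]
  if (length(empty)) {
    warning("omitting groups with <2 records: ", paste(empty, collapse = ", "))
    d <- d[!group %in% empty]
  }
  summ <- d[, .(n = .N, median = median(rrts),
                q1 = quantile(rrts, 0.25), q3 = quantile(rrts, 0.75)),
            by = group][order(group)]
  tests <- if (grouping == "stop3") {
    prs <- utils::combn(sort(unique(d$group)), 2, simplify = FALSE)
    rbindlist(lapply(prs, function(pr) {
      tt <- mw_u_test(d[group == pr[1], rrts], d[group == pr[2], rrts],
                      "two.sided")
      data.table(group1 = pr[1], group2 = pr[2], U = tt$U, p = tt$p,
                 alternative = "two.sided")
    }))
  } else {
    rbindlist(lapply(sort(unique(dna_to_rna(d$stop_codon))), function(sc) {
      dd <- d[dna_to_rna(stop_codon) == sc]
      x <- dd[plus4 == "C", rrts]; y <- dd[plus4 != "C", rrts]
      if (length(x) < 2L || length(y) < 2L) return(NULL)
      tt <- mw_u_test(x, y, "greater")
      data.table(group1 = paste0(sc, "C"), group2 = paste0(sc, "-other"),
                 U = tt$U, p = tt$p, alternative = "greater")
    }))
  }
  list(summary = summ, tests = tests)
}

#' Relative readthrough of NTCs versus first in-frame 3'TCs
#'
#' For each eligible transcript and each anchor (the NTC and the first
#' in-frame 3'UTR stop codon), computes the ratio of mean CDS-normalized
#' density over the 27-nt flank downstream of the stop (positions +6..+32
#' relative to the stop's first nucleotide, excluding the codon immediately
#' after the stop) to the 27-nt flank upstream (-30..-4, excluding the codon
#' immediately before). Transcripts are excluded when they (1) lack an
#' in-frame 3'TC, (2) have the 3'TC within the first 30 nt of the 3'UTR,
#' (3) have fewer than 30 nt downstream of the 3'TC, or (4) carry additional
#' in-frame 3'TCs within the 30-nt window downstream of the first one.
#' Non-finite ratios (zero upstream density) are dropped with a counter.
#'
#' With two or more replicate track sets, a paired t-test across replicates
#' compares the per-replicate mean TC3 ratio against the mean NTC ratio.
#'
#' @param track_list DensityTrackSet, or list of them (replicates).
#' @param ts TranscriptSet.
#' @return list(`records` = per-transcript ratios, `anchor_means` =
#'   per-replicate per-anchor mean ratios, `test` = paired t-test result or
#'   NULL, `n_dropped_nonfinite`).
#' @export
relative_readthrough <- function(track_list, ts) {
  if (inherits(track_list, "DensityTrackSet")) track_list <- list(track_list)
  tab <- ts$table
  elig <- eligible_tc3_transcripts(ts)
  dropped <- 0L
  recs <- rbindlist(lapply(seq_along(track_list), function(ri) {
    tracks <- track_list[[ri]]
    rbindlist(lapply(elig, function(tid) {
      r <- tab[tid, on = "transcript_id"]
      raw <- tracks$raw[[tid]]
      cds_mean <- mean(raw[r$cds_start:r$cds_end])
      if (cds_mean <= 0) return(NULL)
      out <- rbindlist(lapply(c(NTC = r$ntc_pos, TC3 = r$tc3_pos), function(s) {
        up <- (s - 30L):(s - 4L)
        dn <- (s + 6L):(s + 32L)
        if (up[1] < 1L || dn[27] > r$length) return(NULL)
        data.table(up_density = mean(raw[up]) / cds_mean,
                   down_density = mean(raw[dn]) / cds_mean)
      }), idcol = "anchor")
      if (nrow(out) < 2L) return(NULL)
      out[, `:=`(transcript_id = tid, replicate = ri,
                 ratio = down_density / up_density)]
      if (any(!is.finite(out$ratio))) {
        dropped <<- dropped + 1L
        return(NULL)
      }
      out
    }))
  }))
  if (!nrow(recs)) stop("no eligible transcript with finite flank ratios")
  means <- recs[, .(mean_ratio = mean(ratio), n = .N), by = .(replicate, anchor)]
  test <- NULL
  if (length(track_list) >= 2L) {
    w <- data.table::dcast(means, replicate ~ anchor, value.var = "mean_ratio")
    test <- t.test(w$TC3, w$NTC, paired = TRUE)
  }
  list(records = recs[, .(replicate, transcript_id, anchor, up_density,
                          down_density, ratio)],
       anchor_means = means, test = test, n_dropped_nonfinite = dropped)
}

# transcripts passing the four 3'TC-flank eligibility rules
eligible_tc3_transcripts <- function(ts) {
  tab <- ts$table
  ok <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i]
    if (is.na(r$tc3_pos)) return(FALSE)                       # (1)
    if (r$tc3_pos - r$cds_end <= 30L) return(FALSE)           # (2)
    if (r$length - (r$tc3_pos + 2L) < 30L) return(FALSE)      # (3)
    p <- r$tc3_pos + 3L                                       # (4)
    while (p + 2L <= min(r$tc3_pos + 2L + 30L, r$length)) {
      if (substr(ts$seq[[r$transcript_id]], p, p + 2L) %in% STOP_CODONS)
        return(FALSE)
      p <- p + 3L
    }
    TRUE
  }, TRUE)
  tab$transcript_id[ok]
}
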