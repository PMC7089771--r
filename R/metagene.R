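#' Per-transcript normalized density profile around an anchor
#'
#' Ribosome density at every position is divided by the mean density over the
#' transcript's coding sequence; the profile is reported over a fixed window
#' around the anchor. Position 0 is the first nucleotide of the stop codon
#' (stop anchor) or of the start codon (start anchor), so the stop codon
#' occupies positions 0..2. Transcripts that cannot accommodate the full
#' window, or whose CDS density is zero, are excluded.
#'
#' @param track numeric per-nucleotide density vector for one transcript.
#' @param model one-row data.table from a TranscriptSet table.
#' @param anchor `"stop"` or `"start"`.
#' @param window integer positions relative to the anchor (defaults:
#'   stop -150..100, start -100..150).
#' @return named numeric vector over `window`, or NULL when excluded.
#' @export
normalized_profile <- function(track, model, anchor = c("stop", "start"),
                               window = NULL) {
  anchor <- match.arg(anchor)
  if (is.null(window))
    window <- if (anchor == "stop") -150:100 else -100:150
  anchor_pos <- if (anchor == "stop") model$ntc_pos else model$cds_start
  pos <- anchor_pos + window
  if (pos[1] < 1L || pos[length(pos)] > model$length) return(NULL)
  cds_mean <- mean(track[model$cds_start:model$cds_end])
  if (cds_mean <= 0) return(NULL)
  setNames(track[pos] / cds_mean, window)
}

#' Average-gene (metagene) profile
#'
#' Unweighted per-position mean of per-transcript normalized density
#' profiles: every transcript counts once, since the per-transcript CDS
#' normalization already removes expression differences.
#'
#' @param tracks DensityTrackSet.
#' @param ts TranscriptSet.
#' @param anchor `"stop"` or `"start"`.
#' @param window see [normalized_profile()].
#' @return data.table (`position`, `mean_norm_density`) with attributes
#'   `n_transcripts` (contributing) and `n_excluded`.
#' @export
metagene_profile <- function(tracks, ts, anchor = c("stop", "start"),
                             window = NULL) {
  anchor <- match.arg(anchor)
  profs <- lapply(ts$table$transcript_id, function(tid)
    normalized_profile(tracks$raw[[tid]],
                       ts$table[tid, on = "transcript_id"], anchor, window))
  keep <- !vapply(profs, is.null, TRUE)
  if (!any(keep)) stop("no transcript accommodates the metagene window")
  avg <- average_profiles(profs[keep])
  data.table::setattr(avg, "n_excluded", sum(!keep))
  avg
}

#' Average a list of positional profiles
#'
#' @param profiles list of equal-length named numeric vectors (positions as
#'   names), e.g. from [normalized_profile()].
#' @return data.table (`position`, `mean_norm_density`) with attribute
#'   `n_transcripts`.
#' @export
average_profiles <- function(profiles) {
  if (!length(profiles)) stop("no profiles to average")
  m <- do.call(rbind, profiles)
  out <- data.table(position = as.integer(colnames(m)),
                    mean_norm_density = colMeans(m))
  data.table::setattr(out, "n_transcripts", nrow(m))
  out
}

#' 3'UTR / CDS density ratio (percent)
#'
#' Ratio of the stop-anchored average-profile density over positions
#' +5..+100 (3'UTR, clear of the stop-codon peak) to the density over
#' -147..-16 (CDS), expressed as a percent. By default the ratio is computed
#' on the averaged profile; `per_transcript = TRUE` instead averages
#' per-transcript ratios.
#'
#' @param tracks DensityTrackSet.
#' @param ts TranscriptSet.
#' @param utr_window,cds_window position ranges relative to the stop.
#' @param per_transcript compute per-transcript ratios and average them.
#' @return percent (single numeric).
#' @export
utr_cds_ratio <- function(tracks, ts, utr_window = 5:100,
                          cds_window = -147:-16, per_transcript = FALSE) {
  if (per_transcript) {
    profs <- lapply(ts$table$transcript_id, function(tid)
      normalized_profile(tracks$raw[[tid]],
                         ts$table[tid, on = "transcript_id"], "stop"))
    profs <- profs[!vapply(profs, is.null, TRUE)]
    r <- vapply(profs, function(p) {
      cd <- mean(p[as.character(cds_window)])
      if (cd <= 0) return(NA_real_)
      mean(p[as.character(utr_window)]) / cd
    }, 0)
    return(100 * mean(r, na.rm = TRUE))
  }
  prof <- metagene_profile(tracks, ts, "stop")
  cds <- prof[position %in% cds_window, mean(mean_norm_density)]
  if (cds <= 0) stop("zero CDS-window density in averaged profile")
  100 * prof[position %in% utr_window, mean(mean_norm_density)] / cds
}
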