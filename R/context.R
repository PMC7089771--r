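#' Extract stop-codon sequence contexts with RRTS weights
#'
#' The context is the 30-nt region spanning the footprint of a terminating
#' ribosome: 15 nt upstream of the stop codon, the 3-nt stop codon, and
#' 12 nt downstream (the +4..+15 positions). Transcripts with 3'UTRs shorter
#' than 12 nt, or without 15 nt of CDS-side sequence upstream of the stop,
#' are discarded. Weights are the transcripts' RRTS values; zeros are
#' retained by default since they carry signal.
#'
#' @param ts TranscriptSet.
#' @param rrts_records table from [compute_rrts()]; only included records
#'   are used.
#' @param drop_zero_weights drop records with RRTS == 0.
#' @return data.table (`transcript_id`, `context` (DNA alphabet),
#'   `stop_codon`, `weight`).
#' @export
extract_contexts <- function(ts, rrts_records, drop_zero_weights = FALSE) {
  d <- merge(rrts_records[status == "included", .(transcript_id, weight = rrts)],
             ts$table[, .(transcript_id, ntc_pos, utr3_len, stop_codon)],
             by = "transcript_id")
  d <- d[utr3_len >= 12L & ntc_pos >= 16L]
  if (drop_zero_weights) d <- d[weight > 0]
  d[, context := substr(ts$seq[transcript_id], ntc_pos - 15L, ntc_pos + 14L)]
  d[, .(transcript_id, context, stop_codon, weight)]
}

# positions tested around the stop: 15 upstream, 12 downstream (+4..+15)
CONTEXT_POSITIONS <- c(-15:-1, 4:15)
# column in the 30-nt context string for each tested position:
# -15..-1 -> 1..15, stop codon -> 16..18, +4..+15 -> 19..30
context_col <- function(position) ifelse(position < 0, position + 16L,
                                         position + 15L)

#' RRTS-weighted positional nucleotide tests
#'
#' For every tested position (-15..-1 and +4..+15 relative to the stop
#' codon, whose three bases are collapsed and tested as a 3-level factor)
#' and every nucleotide, a pooled-variance two-sample Student's t-test
#' compares the RRTS weights of contexts carrying that nucleotide at that
#' position against all others. The one-sided p-value is taken in the
#' direction of the observed mean difference; Benjamini-Hochberg adjustment
#' is applied jointly over all tested cells (positional cells plus the three
#' stop-codon cells). Cells with fewer than 2 records on either side, or
#' zero pooled variance, are reported untested.
#'
#' @param contexts table from [extract_contexts()].
#' @param welch use Welch's t instead of the pooled-variance test.
#' @return data.table (`label`, `position` (NA for stop cells),
#'   `nucleotide` (RNA alphabet; stop cells carry the codon), `n_with`,
#'   `n_without`, `t_stat`, `df`, `p_raw`, `p_adj`, `direction`, `tested`).
#' @export
weighted_position_tests <- function(contexts, welch = FALSE) {
  w <- contexts$weight
  chars <- do.call(rbind, strsplit(contexts$context, ""))
  cells <- rbindlist(c(
    lapply(CONTEXT_POSITIONS, function(pos) {
      col <- context_col(pos)
      rbindlist(lapply(c("A", "C", "G", "T"), function(nt) {
        cell_test(w, chars[, col] == nt,
                  label = as.character(pos), position = pos,
                  nucleotide = dna_to_rna(nt), welch = welch)
      }))
    }),
    list(rbindlist(lapply(STOP_CODONS, function(sc) {
      cell_test(w, contexts$stop_codon == sc,
                label = "stop", position = NA_integer_,
                nucleotide = dna_to_rna(sc), welch = welch)
    })))
  ))
  cells[tested == TRUE, p_adj := bh_adjust(p_raw)]
  cells[]
}

cell_test <- function(w, in_group, label, position, nucleotide, welch = FALSE) {
  base <- data.table(label = label, position = position,
                     nucleotide = nucleotide,
                     n_with = sum(in_group), n_without = sum(!in_group),
                     t_stat = NA_real_, df = NA_real_, p_raw = NA_real_,
                     p_adj = NA_real_, direction = NA_character_,
                     tested = FALSE)
  x <- w[in_group]; y <- w[!in_group]
  if (length(x) < 2L || length(y) < 2L) return(base)
  if (welch) {
    tt <- tryCatch(t.test(x, y), error = function(e) NULL)
    if (is.null(tt)) return(base)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
  } else {
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    df <- length(x) + length(y) - 2
    if (!is.finite(sp2)) return(base)
    if (sp2 <= 0) {
      # all weights identical on both sides: no evidence either way
      if (mean(x) == mean(y)) {
        base$t_stat <- 0; base$df <- df; base$p_raw <- 0.5
        base$direction <- "increases"; base$tested <- TRUE
      }
      return(base)  # zero variance with a mean difference: untestable
    }
    t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }
  base$t_stat <- t_stat
  base$df <- df
  base$p_raw <- pt(abs(t_stat), df, lower.tail = FALSE)  # one-sided, observed direction
  base$direction <- if (t_stat >= 0) "increases" else "decreases"
  base$tested <- TRUE
  base
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, order-preserving);
#' wraps [stats::p.adjust()] with input validation.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' One-hot encoding of stop-codon contexts
#'
#' 111 binary features: 27 flanking positions (-15..-1, +4..+15) times four
#' nucleotides, plus three stop-codon indicators (UAA, UAG, UGA).
#'
#' @param contexts table from [extract_contexts()].
#' @return numeric matrix, one row per context, 111 named columns.
#' @export
encode_context_matrix <- function(contexts) {
  chars <- do.call(rbind, strsplit(contexts$context, ""))
  cols <- list()
  for (pos in CONTEXT_POSITIONS) {
    col <- context_col(pos)
    for (nt in c("A", "C", "G", "T")) {
      cols[[paste0(ifelse(pos > 0, "+", ""), pos, ":", dna_to_rna(nt))]] <-
        as.numeric(chars[, col] == nt)
    }
  }
  for (sc in STOP_CODONS)
    cols[[paste0("stop:", dna_to_rna(sc))]] <-
      as.numeric(contexts$stop_codon == sc)
  m <- do.call(cbind, cols)
  rownames(m) <- contexts$transcript_id
  m
}

#' Ridge regression of RRTS on one-hot stop-codon context
#'
#' Fits a regularized least-squares model of RRTS weights on the 111-feature
#' one-hot context encoding, with an unpenalized intercept and no feature
#' standardization (the design is binary). Coefficients solve the penalized
#' normal equations on the centred design,
#' `(Xc'Xc + alpha I) beta = Xc' yc`.
#'
#' @param contexts table from [extract_contexts()].
#' @param alpha ridge penalty (default 10^3).
#' @param min_records refuse to fit below this many records.
#' @return object of class `ridge_context_model`: list(`coefficients` (named,
#'   length 111), `intercept`, `alpha`, `n`).
#' @export
fit_context_ridge <- function(contexts, alpha = 1e3, min_records = 200L) {
  if (nrow(contexts) < min_records)
    stop("need at least ", min_records, " records to fit the context model")
  X <- encode_context_matrix(contexts)
  fit <- ridge_fit(X, contexts$weight, alpha)
  structure(c(fit, list(alpha = alpha, n = nrow(X))),
            class = "ridge_context_model")
}

#' Ridge solution with unpenalized intercept
#'
#' Minimizes `||y - b0 - X beta||^2 + alpha ||beta||^2` via the penalized
#' normal equations on the centred design (no feature standardization); at
#' `alpha = 0` on a full-rank design this reduces to ordinary least squares.
#'
#' @param X numeric design matrix.
#' @param y response vector.
#' @param alpha ridge penalty (>= 0).
#' @return list(`coefficients` (named as X's columns), `intercept`).
#' @export
ridge_fit <- function(X, y, alpha) {
  stopifnot(nrow(X) == length(y), alpha >= 0)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  beta <- solve(crossprod(Xc) + diag(alpha, ncol(X)), crossprod(Xc, y - ym))
  list(coefficients = setNames(as.numeric(beta), colnames(X)),
       intercept = ym - sum(xm * beta))
}

#' @export
print.ridge_context_model <- function(x, ...) {
  cat(sprintf("ridge context model: 111 features, alpha = %g, n = %d\n",
              x$alpha, x$n))
  top <- sort(abs(x$coefficients), decreasing = TRUE)[1:5]
  cat("  largest |coef|:",
      paste(sprintf("%s=%.3g", names(top), x$coefficients[names(top)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @param object ridge_context_model.
#' @param newdata contexts table to predict for.
#' @param ... unused.
#' @rdname fit_context_ridge
#' @export
predict.ridge_context_model <- function(object, newdata, ...) {
  X <- encode_context_matrix(newdata)
  as.numeric(object$intercept + X %*% object$coefficients)
}

#' Positional nucleotide frequencies around stop codons
#'
#' For the NTC anchor, frequencies are computed over a window 40 nt upstream
#' to 60 nt downstream of the stop codon (transcripts with 3'UTRs shorter
#' than 60 nt, or with fewer than 40 nt upstream, are discarded). For the
#' TC3 anchor the window is 12 nt up/downstream of the first in-frame 3'UTR
#' stop, discarding transcripts with fewer than 12 nt downstream of it or
#' with other in-frame 3'TCs inside the window. The stop codon is collapsed
#' to a single position reported separately as codon frequencies; downstream
#' positions are labelled from +4.
#'
#' @param ts TranscriptSet.
#' @param anchor `"NTC"` or `"TC3"`.
#' @return list(`nuc` = data.table(`label`, `A`,`C`,`G`,`U`) with rows
#'   summing to 1, `stop` = named codon-frequency vector,
#'   `n_transcripts`).
#' @export
nucleotide_frequencies <- function(ts, anchor = c("NTC", "TC3")) {
  anchor <- match.arg(anchor)
  tab <- ts$table
  if (anchor == "NTC") {
    up <- 40L; down <- 60L
    keep <- tab$utr3_len >= down & tab$ntc_pos > up
    apos <- tab$ntc_pos[keep]
  } else {
    up <- 12L; down <- 12L
    keep <- !is.na(tab$tc3_pos) &
      (tab$length - (tab$tc3_pos + 2L)) >= down &
      tab$tc3_pos > up
    apos <- tab$tc3_pos[keep]
    ids <- tab$transcript_id[keep]
    # drop transcripts with other in-frame stops inside the window
    clean <- vapply(seq_along(ids), function(i) {
      s <- apos[i]; seq <- ts$seq[[ids[i]]]
      for (q in seq(s - up, s + 2L + down - 2L, by = 3L)) {
        if (q == s) next
        if (substr(seq, q, q + 2L) %in% STOP_CODONS) return(FALSE)
      }
      TRUE
    }, TRUE)
    keep[keep] <- clean
    apos <- apos[clean]
  }
  if (!any(keep)) stop("no transcript eligible for anchor ", anchor)
  ids <- tab$transcript_id[keep]
  seqs <- ts$seq[ids]

  labels <- c(-up:-1, paste0("+", 3L + seq_len(down)))
  counts <- matrix(0L, nrow = up + down, ncol = 4,
                   dimnames = list(labels, c("A", "C", "G", "T")))
  stop_counts <- setNames(integer(3), STOP_CODONS)
  for (i in seq_along(ids)) {
    s <- apos[i]
    win <- strsplit(substr(seqs[[i]], s - up, s + 2L + down), "")[[1]]
    nts <- c(win[1:up], win[(up + 4L):(up + 3L + down)])
    hit <- match(nts, c("A", "C", "G", "T"))
    ok <- !is.na(hit)
    counts[cbind(which(ok), hit[ok])] <- counts[cbind(which(ok), hit[ok])] + 1L
    sc <- paste(win[(up + 1L):(up + 3L)], collapse = "")
    if (sc %in% STOP_CODONS) stop_counts[sc] <- stop_counts[sc] + 1L
  }
  freq <- counts / rowSums(counts)
  nuc <- data.table(label = labels, A = freq[, "A"], C = freq[, "C"],
                    G = freq[, "G"], U = freq[, "T"])
  list(nuc = nuc, stop = setNames(as.numeric(stop_counts / sum(stop_counts)),
                                  dna_to_rna(names(stop_counts))),
       n_transcripts = length(ids))
}
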