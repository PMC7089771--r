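#' Specification for the synthetic Ribo-seq generator
#'
#' Collects every tunable of the generator in one validated list. Defaults
#' describe a plausible deeply-sequenced mammalian Ribo-seq library: a few
#' hundred transcripts with log-normal expression, 28-35 nt footprints
#' peaking at 31 nt with the canonical length-specific A-site offsets,
#' strong 3-nt periodicity, pausing at initiation and termination, and rare
#' basal readthrough of the normal termination codon.
#'
#' @param n_transcripts number of transcripts.
#' @param utr5_range,cds_codon_range,tc3_codon_range,utr3_tail_range integer
#'   ranges (nt, codons, codons strictly between NTC and planted 3'TC, nt of
#'   3'UTR after the 3'TC) sampled uniformly per transcript.
#' @param base_probs background nucleotide probabilities (A,C,G,T).
#' @param stop_probs probabilities of the NTC identity (TAA, TAG, TGA);
#'   defaults approximate the human protein-coding stop usage.
#' @param plus4_probs distribution of the +4 nucleotide (first 3'UTR base).
#' @param expr_meanlog,expr_sdlog log-normal expression parameters.
#' @param n_reads footprints to draw.
#' @param read_length_probs named probabilities over read lengths.
#' @param offsets true 5'-end-to-A-site-centre offset table.
#' @param frame_fidelity probability an A-site lands in frame; off-frame
#'   counts split evenly between +/- 1 nt.
#' @param init_peak,stop_pause dwell multipliers at the codon after the start
#'   codon (A-site at initiation) and at stop codons where termination
#'   occurs (NTC and in-frame 3'UTR stops).
#' @param codon_dwell optional named per-codon dwell multipliers (DNA codons).
#' @param readthrough_pi per-transcript probability of reading through the
#'   NTC (scalar); ignored when `context_coefs` is given.
#' @param context_base_logit,context_coefs logistic readthrough model on the
#'   111-feature one-hot context encoding: `pi = plogis(base + x . coefs)`
#'   with `context_coefs` a named vector over feature names from
#'   [encode_context_matrix()].
#' @param tc3_readthrough probability of reading through each in-frame
#'   3'UTR stop codon.
#' @param clean_downstream scrub in-frame stop codons from the 30 nt after
#'   the planted 3'TC (keeps transcripts eligible for the flank analysis).
#' @return validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_transcripts = 500L,
                            utr5_range = c(60L, 180L),
                            cds_codon_range = c(150L, 400L),
                            tc3_codon_range = c(12L, 40L),
                            utr3_tail_range = c(60L, 150L),
                            base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            stop_probs = c(TAA = 0.30, TAG = 0.24, TGA = 0.46),
                            plus4_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            expr_meanlog = 0, expr_sdlog = 0.75,
                            n_reads = 1e6,
                            read_length_probs = c(`28` = 0.05, `29` = 0.10,
                                                  `30` = 0.20, `31` = 0.25,
                                                  `32` = 0.20, `33` = 0.10,
                                                  `34` = 0.05, `35` = 0.05),
                            offsets = default_offsets(),
                            frame_fidelity = 0.95,
                            init_peak = 5, stop_pause = 5,
                            codon_dwell = NULL,
                            readthrough_pi = 0.01,
                            context_base_logit = NULL, context_coefs = NULL,
                            tc3_readthrough = 0.1,
                            clean_downstream = TRUE) {
  spec <- as.list(environment())
  stopifnot(n_transcripts >= 1,
            all(base_probs >= 0), abs(sum(base_probs) - 1) < 1e-8,
            abs(sum(stop_probs) - 1) < 1e-8,
            abs(sum(plus4_probs) - 1) < 1e-8,
            abs(sum(read_length_probs) - 1) < 1e-8,
            frame_fidelity >= 0, frame_fidelity <= 1,
            readthrough_pi >= 0, readthrough_pi <= 1,
            tc3_readthrough >= 0, tc3_readthrough <= 1,
            init_peak > 0, stop_pause > 0)
  if (tc3_codon_range[1] < 6L)
    stop("tc3_codon_range below the minimum distance supported by the RRTS filters")
  class(spec) <- "simulation_spec"
  spec
}

sample_nt <- function(n, probs) sample(names(probs), n, replace = TRUE,
                                       prob = probs)

# uniform over an inclusive integer range, safe for degenerate ranges
# (sample(x, ...) with scalar x would sample from 1:x)
sample_range <- function(rng, n) {
  if (rng[1] == rng[2]) rep(as.integer(rng[1]), n)
  else sample(rng[1]:rng[2], n, replace = TRUE)
}

# random non-stop codons
sample_sense_codons <- function(n, base_probs) {
  if (n == 0L) return(character(0))
  m <- matrix(sample_nt(3L * n, base_probs), ncol = 3)
  cod <- paste0(m[, 1], m[, 2], m[, 3])
  while (any(bad <- cod %in% STOP_CODONS)) {
    m <- matrix(sample_nt(3L * sum(bad), base_probs), ncol = 3)
    cod[bad] <- paste0(m[, 1], m[, 2], m[, 3])
  }
  cod
}

#' Simulate a transcriptome with known stop-codon landmarks
#'
#' Generates `n_transcripts` transcripts, each with a 5'UTR, a CDS starting
#' with ATG and ending in a stop codon drawn from `stop_probs`, and a 3'UTR
#' whose first in-frame stop codon (the 3'TC) is planted at a controlled
#' codon distance; the sequence between NTC and 3'TC is guaranteed free of
#' in-frame stops. The per-transcript readthrough probability is either the
#' fixed `readthrough_pi` or, when `context_coefs` is set, a logistic
#' function of the transcript's own 111-feature stop-codon context.
#'
#' @param spec [simulation_spec()].
#' @param seed integer seed (mandatory; the generator is deterministic given
#'   `spec` and `seed`).
#' @return list(`ts` = TranscriptSet (transcript space), `truth` =
#'   data.table(per-transcript expression, `pi_true`, landmarks), `spec`,
#'   `seed`).
#' @export
simulate_transcriptome <- function(spec, seed) {
  stopifnot(inherits(spec, "simulation_spec"), is.numeric(seed))
  set.seed(seed)
  n <- spec$n_transcripts
  ids <- sprintf("SIMT%04d", seq_len(n))
  utr5 <- sample_range(spec$utr5_range, n)
  ncod <- sample_range(spec$cds_codon_range, n)
  tc3_cod <- sample_range(spec$tc3_codon_range, n)
  tail_nt <- sample_range(spec$utr3_tail_range, n)
  ntc <- sample_nt(n, spec$stop_probs)
  tc3_stop <- sample_nt(n, spec$stop_probs)
  plus4 <- sample_nt(n, spec$plus4_probs)

  seqs <- character(n)
  for (i in seq_len(n)) {
    cds <- c("ATG", sample_sense_codons(ncod[i] - 2L, spec$base_probs), ntc[i])
    inter <- sample_sense_codons(tc3_cod[i], spec$base_probs)
    # force the +4 nucleotide (first base of the first 3'UTR codon)
    first <- inter[1]
    repeat {
      cand <- paste0(plus4[i], substr(first, 2, 3))
      if (!cand %in% STOP_CODONS) { inter[1] <- cand; break }
      first <- sample_sense_codons(1L, spec$base_probs)
    }
    tail_seq <- paste(sample_nt(tail_nt[i], spec$base_probs), collapse = "")
    if (spec$clean_downstream) {
      k <- min(10L, tail_nt[i] %/% 3L)
      if (k > 0L) {
        clean <- paste(sample_sense_codons(k, spec$base_probs), collapse = "")
        tail_seq <- paste0(clean, substr(tail_seq, 3L * k + 1L, tail_nt[i]))
      }
    }
    seqs[i] <- paste0(
      paste(sample_nt(utr5[i], spec$base_probs), collapse = ""),
      paste(cds, collapse = ""),
      paste(inter, collapse = ""), tc3_stop[i], tail_seq)
  }
  tab <- data.table(
    transcript_id = ids, gene_id = sub("SIMT", "SIMG", ids),
    chrom = ids, strand = "+",
    length = nchar(seqs),
    cds_start = utr5 + 1L,
    cds_end = utr5 + 3L * ncod)
  ts <- transcript_set(tab, setNames(seqs, ids))

  expression <- rlnorm(n, spec$expr_meanlog, spec$expr_sdlog)
  pi_true <- if (!is.null(spec$context_coefs)) {
    rr <- data.table(transcript_id = ids, status = "included", rrts = 0)
    ctx <- extract_contexts(ts, data.table(transcript_id = ids,
                                           status = "included", rrts = 0))
    X <- encode_context_matrix(ctx)
    beta <- setNames(numeric(ncol(X)), colnames(X))
    beta[names(spec$context_coefs)] <- spec$context_coefs
    plogis((spec$context_base_logit %||% qlogis(spec$readthrough_pi)) +
             as.numeric(X %*% beta))[match(ids, ctx$transcript_id)]
  } else rep(spec$readthrough_pi, n)

  truth <- cbind(
    data.table(transcript_id = ids, expression = expression / sum(expression),
               pi_true = pi_true),
    ts$table[, .(stop_codon, plus4, tc3_pos, utr3_len)])
  list(ts = ts, truth = truth, spec = spec, seed = seed)
}

#' Simulate ribosome footprints over a synthetic transcriptome
#'
#' Draws reads transcript-by-transcript proportionally to expression.
#' Within a transcript, the A-site codon is drawn from a dwell-weighted
#' distribution over codon starts: CDS codons from the second codon (the
#' initiation A-site, weighted by `init_peak`) to the NTC (weighted by
#' `stop_pause`), then 3'UTR codons whose ribosome flux is the transcript's
#' readthrough probability, further multiplied by `tc3_readthrough` past
#' each in-frame 3'UTR stop codon (each such stop also carries
#' `stop_pause`). With probability `1 - frame_fidelity` the A-site is
#' jittered +/- 1 nt (evenly). The 5' end is the A-site codon centre minus
#' the true offset for the read's sampled length; reads extending beyond
#' either transcript end are rejected and counted.
#'
#' @param txome result of [simulate_transcriptome()].
#' @param seed integer seed.
#' @param n_reads override `spec$n_reads`.
#' @return `footprints` data.table (`transcript_id`, `five_prime`,
#'   `read_length`) with a `counters` attribute.
#' @export
simulate_footprints <- function(txome, seed, n_reads = NULL) {
  spec <- txome$spec
  set.seed(seed)
  n_reads <- as.integer(n_reads %||% spec$n_reads)
  tab <- txome$ts$table
  truth <- txome$truth
  lens <- as.integer(names(spec$read_length_probs))
  offs <- spec$offsets[names(spec$read_length_probs)]

  n_per_tx <- as.integer(stats::rmultinom(1, n_reads, truth$expression))
  out <- vector("list", nrow(tab))
  rejected <- 0L
  for (i in seq_len(nrow(tab))) {
    m <- n_per_tx[i]
    if (m == 0L) next
    r <- tab[i]
    pw <- codon_weights(r, txome$ts$seq[[r$transcript_id]],
                        truth$pi_true[i], spec)
    starts <- sample(pw$starts, m, replace = TRUE, prob = pw$w)
    jit_on <- runif(m) > spec$frame_fidelity
    jit <- integer(m)
    jit[jit_on] <- sample(c(-1L, 1L), sum(jit_on), replace = TRUE)
    center <- starts + 1L + jit
    L <- sample(lens, m, replace = TRUE, prob = spec$read_length_probs)
    fp5 <- center - as.integer(offs[as.character(L)])
    keep <- fp5 >= 1L & fp5 + L - 1L <= r$length
    rejected <- rejected + sum(!keep)
    out[[i]] <- data.table(transcript_id = r$transcript_id,
                           five_prime = fp5[keep], read_length = L[keep])
  }
  fp <- rbindlist(out)
  structure(fp, counters = c(requested = n_reads, emitted = nrow(fp),
                             rejected_off_transcript = rejected),
            class = c("footprints", class(fp)))
}

# dwell-weighted A-site codon-start distribution for one transcript
codon_weights <- function(r, seq, pi_t, spec) {
  cds_starts <- seq(r$cds_start + 3L, r$ntc_pos, by = 3L)  # codons 2..NTC
  flux <- rep(1, length(cds_starts))
  dwell <- rep(1, length(cds_starts))
  dwell[1] <- spec$init_peak
  dwell[length(dwell)] <- spec$stop_pause
  starts <- cds_starts
  # 3'UTR: flux pi_t, dropping by tc3_readthrough past each in-frame stop
  p <- r$cds_end + 1L
  f <- pi_t
  utr_starts <- integer(0); utr_flux <- numeric(0); utr_dwell <- numeric(0)
  while (p + 2L <= r$length && f > 0) {
    cod <- substr(seq, p, p + 2L)
    is_stop <- cod %in% STOP_CODONS
    utr_starts <- c(utr_starts, p)
    utr_flux <- c(utr_flux, f)
    utr_dwell <- c(utr_dwell, if (is_stop) spec$stop_pause else 1)
    if (is_stop) f <- f * spec$tc3_readthrough
    p <- p + 3L
  }
  starts <- c(starts, utr_starts)
  w <- c(flux * dwell, utr_flux * utr_dwell)
  if (!is.null(spec$codon_dwell)) {
    cods <- substring(seq, starts, starts + 2L)
    mult <- spec$codon_dwell[cods]
    mult[is.na(mult)] <- 1
    w <- w * mult
  }
  list(starts = starts, w = w)
}

#' Simulate noisy RRTS observations from ground truth
#'
#' Emulates the measurement noise of RRTS estimation without drawing reads:
#' each transcript's observed score is its true readthrough probability
#' times a multiplicative log-normal noise term with unit mean and the
#' given coefficient of variation. Used to validate the context statistics
#' at scales where full read simulation is unnecessary.
#'
#' @param txome result of [simulate_transcriptome()].
#' @param cv coefficient of variation of the noise.
#' @param seed integer seed.
#' @return data.table shaped like [compute_rrts()] output (all records
#'   included).
#' @export
simulate_rrts_weights <- function(txome, cv = 0.3, seed) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  noise <- rlnorm(nrow(txome$truth), -sdlog^2 / 2, sdlog)
  data.table(transcript_id = txome$truth$transcript_id,
             total_reads = NA_real_, cds_density = NA_real_,
             ext_density = NA_real_,
             rrts = txome$truth$pi_true * noise,
             status = "included", reason = NA_character_)
}

#' Write simulated annotation and sequence to GTF + FASTA
#'
#' `mode = "transcript"` writes each transcript as a single-exon plus-strand
#' gene on its own reference (references = transcript ids), the canonical
#' simulation output. `mode = "genome"` embeds all transcripts in one toy
#' chromosome, inserting a 50-nt intron in the middle of each and placing
#' alternate transcripts on the minus strand, to exercise the genome-space
#' projection path end to end.
#'
#' @param txome result of [simulate_transcriptome()].
#' @param gtf_path,fasta_path output paths.
#' @param mode `"transcript"` or `"genome"`.
#' @return invisibly, NULL.
#' @export
write_annotation <- function(txome, gtf_path, fasta_path,
                             mode = c("transcript", "genome")) {
  mode <- match.arg(mode)
  tab <- txome$ts$table
  seqs <- txome$ts$seq
  lines <- character(0)
  gtf_rec <- function(chrom, src, type, s, e, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type, s, e,
            strand, attrs)
  }
  at <- function(r, extra = "") sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_type "protein_coding"; transcript_type "protein_coding";%s',
    r$gene_id, r$transcript_id, extra)

  if (mode == "transcript") {
    fa_names <- tab$transcript_id
    fa_seqs <- unname(seqs[tab$transcript_id])
    for (i in seq_len(nrow(tab))) {
      r <- tab[i]
      lines <- c(lines,
        gtf_rec(r$transcript_id, "sim", "gene", 1L, r$length, "+", at(r)),
        gtf_rec(r$transcript_id, "sim", "transcript", 1L, r$length, "+", at(r)),
        gtf_rec(r$transcript_id, "sim", "exon", 1L, r$length, "+", at(r)),
        gtf_rec(r$transcript_id, "sim", "CDS", r$cds_start, r$cds_end - 3L,
                "+", at(r)),
        gtf_rec(r$transcript_id, "sim", "stop_codon", r$cds_end - 2L,
                r$cds_end, "+", at(r)))
    }
  } else {
    gap <- 300L; intron <- 50L
    chrom_parts <- character(0)
    cursor <- 0L
    for (i in seq_len(nrow(tab))) {
      r <- tab[i]
      s <- seqs[[r$transcript_id]]
      minus <- i %% 2L == 0L
      half <- r$length %/% 2L
      gseq <- if (!minus) s else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      # insert intron between the transcript halves (genomic orientation)
      h <- if (!minus) half else r$length - half
      gseq <- paste0(substr(gseq, 1L, h),
                     paste(rep("G", intron), collapse = ""),
                     substr(gseq, h + 1L, r$length))
      g0 <- cursor + gap  # 0-based offset of the transcript's first base
      ex1 <- c(g0 + 1L, g0 + h)
      ex2 <- c(g0 + h + intron + 1L, g0 + r$length + intron)
      strand <- if (minus) "-" else "+"
      # exon ranks follow transcript orientation
      exons <- if (minus) list(ex2, ex1) else list(ex1, ex2)
      tg <- function(tpos) {  # transcript -> genome for CDS bounds
        if (!minus) {
          if (tpos <= half) g0 + tpos else g0 + tpos + intron
        } else {
          gt <- r$length - tpos + 1L
          if (gt <= h) g0 + gt else g0 + gt + intron
        }
      }
      # CDS may straddle the intron: emit per-exon CDS pieces
      cds_tpos <- r$cds_start:(r$cds_end - 3L)
      stop_tpos <- (r$cds_end - 2L):r$cds_end
      gpos <- vapply(cds_tpos, tg, 0L)
      spos <- vapply(stop_tpos, tg, 0L)
      runs <- function(g) {
        g <- sort(g)
        brk <- c(0L, which(diff(g) != 1L), length(g))
        cbind(g[head(brk, -1) + 1L], g[brk[-1]])
      }
      lines <- c(lines,
        gtf_rec("chrS", "sim", "gene", ex1[1], ex2[2], strand, at(r)),
        gtf_rec("chrS", "sim", "transcript", ex1[1], ex2[2], strand, at(r)))
      for (e in exons)
        lines <- c(lines, gtf_rec("chrS", "sim", "exon", e[1], e[2], strand, at(r)))
      for (k in seq_len(nrow(runs(gpos))))
        lines <- c(lines, gtf_rec("chrS", "sim", "CDS", runs(gpos)[k, 1],
                                  runs(gpos)[k, 2], strand, at(r)))
      for (k in seq_len(nrow(runs(spos))))
        lines <- c(lines, gtf_rec("chrS", "sim", "stop_codon", runs(spos)[k, 1],
                                  runs(spos)[k, 2], strand, at(r)))
      chrom_parts <- c(chrom_parts,
                       paste(rep("N", gap), collapse = ""), gseq)
      cursor <- g0 + r$length + intron
    }
    fa_names <- "chrS"
    fa_seqs <- paste(chrom_parts, collapse = "")
  }
  writeLines(lines, gtf_path)
  fa <- Biostrings::DNAStringSet(fa_seqs)
  names(fa) <- fa_names
  Biostrings::writeXStringSet(fa, fasta_path)
  invisible(NULL)
}

#' Write footprints as a transcript-space SAM file
#'
#' Emits primary plus-strand alignments against the transcript references
#' (CIGAR `<len>M`, MAPQ 255), with sequences copied from the transcript.
#'
#' @param fp footprints table.
#' @param txome result of [simulate_transcriptome()] (supplies reference
#'   lengths and sequences).
#' @param path output SAM path.
#' @return invisibly, the path.
#' @export
write_sam <- function(fp, txome, path) {
  tab <- txome$ts$table
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", tab$transcript_id, tab$length))
  fp <- as.data.table(fp)
  seqs <- txome$ts$seq
  body <- sprintf("r%07d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                  seq_len(nrow(fp)), fp$transcript_id, fp$five_prime,
                  fp$read_length,
                  substr(seqs[fp$transcript_id], fp$five_prime,
                         fp$five_prime + fp$read_length - 1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}
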