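#' Run the full readthrough analysis pipeline
#'
#' Chains every stage on one library: annotation parsing and single-isoform
#' selection, footprint ingestion, offset calibration, density tracks, and
#' all downstream analyses (metagene + 3'UTR/CDS ratio, RRTS with stop-codon
#' comparisons, frame and codon-occupancy summaries, 3'TC analyses,
#' sequence-context statistics). Writes one TSV per analysis plus a JSON
#' manifest into `cfg$outdir`.
#'
#' @param cfg [run_config()] with `gtf`, `fasta` and `alignments` set.
#' @param ts optional pre-built TranscriptSet (skips parsing/selection).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(cfg, ts = NULL) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(ts)) {
    if (is.null(cfg$gtf) || is.null(cfg$fasta))
      stop("run_pipeline needs gtf and fasta (or a pre-built TranscriptSet)")
    ts <- select_transcripts(parse_annotation(cfg$gtf, cfg$fasta))
  }
  export_transcripts(ts, file.path(cfg$outdir, "transcripts.tsv"))

  if (is.null(cfg$alignments)) stop("run_pipeline needs alignments")
  fp <- read_alignments(cfg$alignments, ts, space = cfg$space)
  offsets <- if (cfg$offset_mode == "calibrate") {
    calibrate_offsets(fp, ts, lengths = cfg$lengths,
                      min_reads = cfg$calibration_min, fallback = cfg$offsets)
  } else cfg$offsets
  tracks <- build_tracks(fp, ts, offsets, lengths = cfg$lengths,
                         normalization = cfg$normalization)
  export_tracks(tracks, file.path(cfg$outdir, "density.tsv"),
                file.path(cfg$outdir, "run_report.json"))

  prof <- metagene_profile(tracks, ts, "stop")
  prof[, n_transcripts := attr(prof, "n_transcripts")]
  write_tsv(prof, file.path(cfg$outdir, "metagene_stop.tsv"))
  ratio <- utr_cds_ratio(tracks, ts)

  rrts <- compute_rrts(tracks, ts, min_reads = cfg$min_reads,
                       min_codons = cfg$min_codons)
  write_tsv(rrts, file.path(cfg$outdir, "rrts.tsv"))
  cmp <- compare_rrts_by_stop(rrts, ts, "stop3")
  write_tsv(cmp$tests, file.path(cfg$outdir, "rrts_stop3_tests.tsv"))
  write_tsv(cmp$summary, file.path(cfg$outdir, "rrts_stop3_summary.tsv"))

  fr <- rbind(frame_fractions(tracks, ts, "CDS"),
              tryCatch(frame_fractions(tracks, ts, "UTR3"),
                       error = function(e) NULL))
  write_tsv(fr, file.path(cfg$outdir, "frames.tsv"))
  occ <- codon_occupancy(tracks, ts)
  write_tsv(occ, file.path(cfg$outdir, "codon_occupancy.tsv"))
  tc3m <- tc3_frame_metagene(tracks, ts)
  write_tsv(tc3m, file.path(cfg$outdir, "tc3_frame_metagene.tsv"))
  rel <- relative_readthrough(tracks, ts)
  write_tsv(rel$records, file.path(cfg$outdir, "relative_readthrough.tsv"))

  ctx <- extract_contexts(ts, rrts)
  context <- NULL
  if (nrow(ctx) >= 8L) {
    tests <- weighted_position_tests(ctx)
    write_tsv(tests, file.path(cfg$outdir, "context_tests.tsv"))
    ridge <- if (nrow(ctx) >= 200L)
      fit_context_ridge(ctx, alpha = cfg$alpha) else NULL
    if (!is.null(ridge))
      write_tsv(data.table(feature = names(ridge$coefficients),
                           coefficient = ridge$coefficients),
                file.path(cfg$outdir, "context_ridge.tsv"))
    context <- list(tests = tests, ridge = ridge)
  }
  freq <- nucleotide_frequencies(ts, "NTC")
  write_tsv(freq$nuc, file.path(cfg$outdir, "ntc_frequencies.tsv"))

  write_manifest(cfg, cfg$outdir,
                 inputs = unlist(cfg[c("gtf", "fasta", "alignments")]))
  invisible(list(ts = ts, tracks = tracks, offsets = offsets,
                 metagene = prof, utr_cds_ratio = ratio, rrts = rrts,
                 stop3 = cmp, frames = fr, occupancy = occ,
                 tc3_metagene = tc3m, relative_readthrough = rel,
                 contexts = ctx, context = context, frequencies = freq))
}

#' Simulate a complete toy data set to disk
#'
#' Writes GTF, FASTA, transcript-space SAM, truth table and spec JSON into
#' `outdir`; the set round-trips through [run_pipeline()].
#'
#' @param spec [simulation_spec()].
#' @param seed integer seed.
#' @param outdir output directory.
#' @return invisibly, paths of the written files.
#' @export
simulate_dataset <- function(spec, seed, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  txome <- simulate_transcriptome(spec, seed)
  fp <- simulate_footprints(txome, seed + 1L)
  paths <- list(gtf = file.path(outdir, "sim.gtf"),
                fasta = file.path(outdir, "sim.fa"),
                sam = file.path(outdir, "sim.sam"),
                truth = file.path(outdir, "truth.tsv"),
                spec = file.path(outdir, "spec.json"))
  write_annotation(txome, paths$gtf, paths$fasta, mode = "transcript")
  write_sam(fp, txome, paths$sam)
  write_tsv(txome$truth, paths$truth)
  sp <- unclass(spec)
  sp <- sp[!vapply(sp, is.null, TRUE)]
  jsonlite::write_json(c(sp, list(seed = seed)), paths$spec,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
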