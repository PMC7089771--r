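#' Write a diff-stable TSV
#'
#' UTF-8, '\n' newlines, '.' decimal separator, floating-point columns at 6
#' significant digits.
#'
#' @param dt data.frame/data.table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(dt, path) {
  out <- as.data.table(dt)
  for (cl in names(out)) {
    if (is.double(out[[cl]]))
      out[[cl]] <- signif(out[[cl]], 6)
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA",
                     eol = "\n")
  invisible(path)
}

#' Run configuration
#'
#' Bundles paths and thresholds shared by the pipeline stages; serialized as
#' JSON next to every output set.
#'
#' @param gtf,fasta,alignments,outdir input paths and output directory.
#' @param space alignment space ("transcript"/"genome").
#' @param lengths analysis read lengths.
#' @param offset_mode "calibrate" or "fixed".
#' @param offsets fixed offset table (used when `offset_mode = "fixed"` and
#'   as calibration fallback).
#' @param normalization RPM mode ("per_length"/"global").
#' @param min_reads,min_codons,calibration_min RRTS and calibration
#'   thresholds.
#' @param alpha ridge penalty.
#' @param seed seed recorded in the manifest.
#' @return `run_config` list.
#' @export
run_config <- function(gtf = NULL, fasta = NULL, alignments = NULL,
                       outdir = ".", space = "transcript",
                       lengths = 28:35, offset_mode = "calibrate",
                       offsets = default_offsets(),
                       normalization = "per_length",
                       min_reads = 128L, min_codons = 5L,
                       calibration_min = 200L, alpha = 1e3, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(min_reads > 0, min_codons > 0, calibration_min > 0, alpha > 0)
  class(cfg) <- "run_config"
  cfg
}

write_manifest <- function(cfg, outdir, inputs = character(0)) {
  hashes <- lapply(inputs[file.exists(inputs)], function(f)
    unname(tools::md5sum(f)))
  jsonlite::write_json(
    list(config = unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
         input_md5 = hashes,
         package_version = as.character(utils::packageVersion("riboscr"))),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
}
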