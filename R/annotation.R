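#' Parse a GENCODE-style GTF plus genome FASTA into transcript models
#'
#' Reads protein-coding transcripts, splices and strand-corrects their
#' sequences, converts CDS bounds to transcript coordinates, and keeps only
#' transcripts with a complete CDS (multiple of 3, ending in a stop codon)
#' and both UTRs present. The internal CDS convention includes the stop
#' codon: when the GTF's CDS feature excludes it (GENCODE does), the bounds
#' are extended by the `stop_codon` feature when present, otherwise by 3 nt
#' with a sequence check.
#'
#' APPRIS level and CCDS membership are read from GENCODE `tag`/`ccdsid`
#' attributes and drive [select_transcripts()]. Pseudogene loci (any
#' `gene_type` containing "pseudogene") are retained for the UTR-overlap
#' filter.
#'
#' @param gtf path to a GTF file (GENCODE dialect).
#' @param fasta path to the genome FASTA (a .fai index is created if absent).
#' @param verbose log per-class drop counts.
#' @return [transcript_set()] of protein-coding transcript models.
#' @export
parse_annotation <- function(gtf, fasta, verbose = TRUE) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  gene_type <- as.character(if ("gene_type" %in% names(mc)) mc$gene_type
                            else mc$gene_biotype)
  tx_type <- as.character(if ("transcript_type" %in% names(mc)) mc$transcript_type
                          else mc$transcript_biotype)

  pseudo <- gr[mc$type == "gene" & grepl("pseudogene", gene_type %||% "")]

  keep <- !is.na(tx_type) & tx_type == "protein_coding" &
    mc$type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  if (!length(gr)) stop("no protein-coding exon/CDS records in ", gtf)

  feat <- data.table(
    type = as.character(mc$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    gstart = GenomicRanges::start(gr),
    gend = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id)
  )

  # per-transcript selection attributes from GENCODE tags
  tags <- if ("tag" %in% names(mc)) mc$tag else NULL
  tag_str <- if (is.null(tags)) rep("", nrow(feat)) else
    vapply(as.list(tags), function(v) paste(v, collapse = ","), "")
  ccds_attr <- if ("ccdsid" %in% names(mc)) !is.na(mc$ccdsid) else
    rep(FALSE, nrow(feat))
  attr_dt <- data.table(transcript_id = feat$transcript_id,
                        tag = tag_str, ccds = ccds_attr)
  attr_dt <- attr_dt[, .(
    appris = if (any(grepl("appris_principal", tag))) "primary"
             else if (any(grepl("appris_alternative", tag))) "alternative"
             else "none",
    is_ccds = any(ccds) || any(grepl("(^|,)CCDS($|,)", tag))
  ), by = transcript_id]

  exons <- feat[type == "exon"]
  cds <- feat[type == "CDS"]
  stopc <- feat[type == "stop_codon"]
  tx_ids <- intersect(unique(exons$transcript_id), unique(cds$transcript_id))

  fa <- Rsamtools::FaFile(fasta)
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  fa_chroms <- as.character(GenomicRanges::seqnames(
    Rsamtools::seqinfo(fa)))

  drops <- c(cds_not_triplet = 0L, no_stop_codon = 0L, missing_utr = 0L)
  rows <- vector("list", length(tx_ids))
  seqs <- character(length(tx_ids))
  exon_list <- vector("list", length(tx_ids))

  exons_by_tx <- split(exons, exons$transcript_id)
  cds_by_tx <- split(cds, cds$transcript_id)
  stop_by_tx <- split(stopc, stopc$transcript_id)

  for (i in seq_along(tx_ids)) {
    tid <- tx_ids[i]
    ex <- exons_by_tx[[tid]]
    strand <- ex$strand[1]; chr <- ex$chrom[1]
    if (!chr %in% fa_chroms)
      stop("chromosome ", chr, " for transcript ", tid, " missing from FASTA")
    setorder(ex, gstart)
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex)))]
    ex[, rank := seq_len(.N)]
    w <- ex$gend - ex$gstart + 1L
    ex[, cumlen := cumsum(data.table::shift(w, fill = 0L))]
    len <- sum(w)

    seq_parts <- Biostrings::getSeq(
      fa, GenomicRanges::GRanges(chr, IRanges::IRanges(ex$gstart, ex$gend)))
    seq_parts <- as.character(seq_parts)
    if (strand == "-")
      seq_parts <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seq_parts)))
    seq <- paste(seq_parts, collapse = "")

    # CDS genomic extremes -> transcript coordinates
    cd <- cds_by_tx[[tid]]
    sc <- stop_by_tx[[tid]]
    g5 <- if (strand == "+") min(cd$gstart) else max(cd$gend)
    g3 <- if (strand == "+") max(cd$gend) else min(cd$gstart)
    if (!is.null(sc)) {
      g3 <- if (strand == "+") max(c(cd$gend, sc$gend)) else
        min(c(cd$gstart, sc$gstart))
    }
    t5 <- g2t_one(ex, strand, g5)
    t3 <- g2t_one(ex, strand, g3)
    if (is.na(t5) || is.na(t3)) { drops["no_stop_codon"] <- drops["no_stop_codon"] + 1L; next }
    cs <- min(t5, t3); ce <- max(t5, t3)
    if (is.null(sc) &&
        !substr(seq, ce - 2L, ce) %in% STOP_CODONS &&
        ce + 3L <= len &&
        substr(seq, ce + 1L, ce + 3L) %in% STOP_CODONS) {
      ce <- ce + 3L  # GTF CDS excludes the stop codon: extend by 3 nt
    }
    if ((ce - cs + 1L) %% 3L != 0L || ce - cs + 1L < 6L) {
      drops["cds_not_triplet"] <- drops["cds_not_triplet"] + 1L; next
    }
    if (!substr(seq, ce - 2L, ce) %in% STOP_CODONS) {
      drops["no_stop_codon"] <- drops["no_stop_codon"] + 1L; next
    }
    if (cs <= 1L || ce >= len) {  # require both UTRs
      drops["missing_utr"] <- drops["missing_utr"] + 1L; next
    }
    rows[[i]] <- data.table(transcript_id = tid, gene_id = ex$gene_id[1],
                            chrom = chr, strand = strand, length = len,
                            cds_start = cs, cds_end = ce)
    seqs[i] <- seq
    exon_list[[i]] <- ex[, .(transcript_id, rank, gstart, gend)]
  }

  keep_i <- !vapply(rows, is.null, TRUE)
  if (!any(keep_i)) stop("no transcript passed the completeness filters")
  tab <- rbindlist(rows[keep_i])
  tab <- merge(tab, attr_dt, by = "transcript_id", all.x = TRUE)
  tab[is.na(appris), appris := "none"]
  tab[is.na(is_ccds), is_ccds := FALSE]
  seqv <- setNames(seqs[keep_i], rbindlist(rows[keep_i])$transcript_id)
  if (verbose && sum(drops) > 0)
    message("parse_annotation: dropped ",
            paste(sprintf("%s=%d", names(drops), drops), collapse = ", "))
  transcript_set(tab, seqv, exons = rbindlist(exon_list[keep_i]),
                 pseudogenes = pseudo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genomic position -> transcript coordinate for one exon chain (NA if outside)
g2t_one <- function(ex, strand, g) {
  hit <- which(ex$gstart <= g & g <= ex$gend)
  if (!length(hit)) return(NA_integer_)
  off <- if (strand == "+") g - ex$gstart[hit] + 1L else ex$gend[hit] - g + 1L
  ex$cumlen[hit] + off
}

#' Select a single transcript isoform per gene
#'
#' Applies, per gene, the rule cascade: (1) keep transcripts whose stop codon
#' is 3'-most in genomic orientation (largest genomic stop position on `+`,
#' smallest on `-`); (2) APPRIS primary, else APPRIS alternative; (3) CCDS
#' membership; (4) longest CDS; (5) shortest 3'UTR; (6) shortest 5'UTR;
#' (7) lexicographically smallest `transcript_id` as the deterministic final
#' tie-break. Selected transcripts overlapping (exon-level) any transcript of
#' the nearest same-strand neighbouring gene, or whose UTR exons overlap
#' annotated pseudogenes, are then discarded.
#'
#' @param ts TranscriptSet from [parse_annotation()] (or any set with exon
#'   chains; the neighbour/pseudogene filters are skipped for
#'   transcript-space sets).
#' @param verbose log counts of transcripts removed by each filter.
#' @return TranscriptSet with exactly one transcript per surviving gene.
#' @export
select_transcripts <- function(ts, verbose = TRUE) {
  tab <- copy(ts$table)
  if (is.null(ts$exons)) {
    # transcript space: genomic stop position unavailable; rules 2..7 only
    tab[, stop_gpos := cds_end]
    tab[, stop_rank := -stop_gpos]
  } else {
    tab[, stop_gpos := mapply(function(id, ce)
      transcript_to_genome(ts, id, ce), transcript_id, cds_end)]
    tab[, stop_rank := ifelse(strand == "+", -stop_gpos, stop_gpos)]
  }
  tab[, cds_len := cds_end - cds_start + 1L]
  appris_rank <- c(primary = 1L, alternative = 2L, none = 3L)

  pick <- tab[, {
    s <- .SD[stop_rank == min(stop_rank)]
    ar <- appris_rank[s$appris]
    if (any(ar < 3L)) s <- s[ar == min(ar)]
    if (any(s$is_ccds)) s <- s[is_ccds == TRUE]
    s <- s[cds_len == max(cds_len)]
    s <- s[utr3_len == min(utr3_len)]
    s <- s[utr5_len == min(utr5_len)]
    s[order(transcript_id)][1]
  }, by = gene_id]

  sel_ids <- pick$transcript_id
  n_sel <- length(sel_ids)

  removed <- c(neighbor_overlap = 0L, pseudogene_utr = 0L)
  if (!is.null(ts$exons)) {
    ex <- merge(ts$exons, ts$table[, .(transcript_id, gene_id, chrom, strand)],
                by = "transcript_id")
    genes <- ex[, .(gstart = min(gstart), gend = max(gend)),
                by = .(gene_id, chrom, strand)]
    keep <- vapply(sel_ids, function(tid) {
      row <- tab[transcript_id == tid]
      g <- genes[gene_id == row$gene_id]
      nb <- genes[chrom == g$chrom & strand == g$strand & gene_id != g$gene_id]
      ok <- TRUE
      if (nrow(nb)) {
        # nearest neighbour upstream and downstream by genomic distance
        up <- nb[gend < g$gstart][which.max(gend)]
        dn <- nb[gstart > g$gend][which.min(gstart)]
        ov <- nb[gend >= g$gstart & gstart <= g$gend]  # overlapping spans
        near <- rbindlist(list(up, dn, ov))
        if (nrow(near)) {
          my_ex <- ex[transcript_id == tid]
          their_ex <- ex[gene_id %in% near$gene_id]
          ok <- !any_overlap(my_ex$gstart, my_ex$gend,
                             their_ex$gstart, their_ex$gend)
        }
      }
      if (!ok) removed["neighbor_overlap"] <<- removed["neighbor_overlap"] + 1L
      ok
    }, TRUE)
    sel_ids <- sel_ids[keep]

    if (!is.null(ts$pseudogenes) && length(ts$pseudogenes)) {
      keep <- vapply(sel_ids, function(tid) {
        row <- tab[transcript_id == tid]
        utr_iv <- utr_exon_intervals(ts, tid, row$cds_start, row$cds_end)
        if (!nrow(utr_iv)) return(TRUE)
        gr <- GenomicRanges::GRanges(row$chrom,
                                     IRanges::IRanges(utr_iv$gstart, utr_iv$gend))
        ok <- !any(IRanges::overlapsAny(gr, ts$pseudogenes, ignore.strand = TRUE))
        if (!ok) removed["pseudogene_utr"] <<- removed["pseudogene_utr"] + 1L
        ok
      }, TRUE)
      sel_ids <- sel_ids[keep]
    }
  }

  if (verbose)
    message(sprintf(
      "select_transcripts: %d genes -> %d selected (neighbor_overlap=%d, pseudogene_utr=%d)",
      uniqueN(ts$table$gene_id), length(sel_ids),
      removed["neighbor_overlap"], removed["pseudogene_utr"]))
  ts[sel_ids]
}

any_overlap <- function(s1, e1, s2, e2) {
  if (!length(s1) || !length(s2)) return(FALSE)
  any(IRanges::overlapsAny(IRanges::IRanges(s1, e1), IRanges::IRanges(s2, e2)))
}

# genomic intervals covered by the UTR portions of a transcript
utr_exon_intervals <- function(ts, tid, cds_start, cds_end) {
  len <- ts$table[transcript_id == tid]$length
  iv <- list()
  if (cds_start > 1L) iv <- c(iv, list(c(1L, cds_start - 1L)))
  if (cds_end < len) iv <- c(iv, list(c(cds_end + 1L, len)))
  out <- lapply(iv, function(r) {
    g <- transcript_to_genome(ts, tid, r[1]:r[2])
    # contiguous genomic runs -> intervals
    g <- sort(g)
    brk <- c(0L, which(diff(g) != 1L), length(g))
    data.table(gstart = g[head(brk, -1) + 1L], gend = g[brk[-1]])
  })
  rbindlist(out)
}

#' Write the selected-transcript table and transcript FASTA
#'
#' @param ts TranscriptSet.
#' @param table_path TSV output path (NULL to skip).
#' @param fasta_path transcript FASTA output path (NULL to skip).
#' @return invisibly, the exported table.
#' @export
export_transcripts <- function(ts, table_path = NULL, fasta_path = NULL) {
  out <- ts$table[, .(transcript_id, gene_id, chrom, strand, length,
                      cds_start, cds_end, utr3_len,
                      stop_codon = dna_to_rna(stop_codon),
                      plus4 = dna_to_rna(plus4), tc3_pos)]
  if (!is.null(table_path)) write_tsv(out, table_path)
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ts$seq), fasta_path)
  }
  invisible(out)
}

# report in RNA alphabet (sequences are stored with T)
dna_to_rna <- function(x) chartr("T", "U", x)
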