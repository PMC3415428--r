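# Minimal GFF3 (1-based, inclusive) output for gene models and precursor
# annotations. Only writing is supported; nothing in the pipeline reads
# GFF3 back.

.gff3_line <- function(seqid, source, type, start, end, score = ".",
                       strand = "+", phase = ".", attributes = ".") {
  paste(seqid, source, type, start, end, score, strand, phase, attributes,
        sep = "\t")
}

# Map 1-based cDNA positions to genomic positions through a gene model.
cdna_to_genomic <- function(model, pos) {
  exon_lens <- model$exons[, "end"] - model$exons[, "start"] + 1L
  ends <- cumsum(exon_lens)
  starts <- ends - exon_lens + 1L
  vapply(pos, function(p) {
    e <- which(p >= starts & p <= ends)
    if (length(e) == 0L) stop("cDNA position ", p, " outside the transcript")
    model$exons[e, "start"] + (p - starts[e])
  }, integer(1))
}

# Split a cDNA interval into genomic intervals (one per overlapped exon).
.cdna_interval_to_genomic <- function(model, nt_start, nt_end) {
  exon_lens <- model$exons[, "end"] - model$exons[, "start"] + 1L
  ends <- cumsum(exon_lens)
  starts <- ends - exon_lens + 1L
  out <- list()
  for (e in seq_len(nrow(model$exons))) {
    s <- max(nt_start, starts[e])
    t0 <- min(nt_end, ends[e])
    if (s <= t0) {
      out[[length(out) + 1L]] <- c(model$exons[e, "start"] + (s - starts[e]),
                                   model$exons[e, "start"] + (t0 - starts[e]))
    }
  }
  out
}

#' Write a locus bundle as GFF3
#'
#' Emits gene, mRNA, exon and CDS features on the genomic sequence, plus
#' custom child features (`signal_peptide`, `propeptide`, `mature_peptide`,
#' `spacer`, `cleavage_site`) derived from the truth annotation, each with a
#' `Note` attribute naming its role.
#'
#' @param bundle A `locus_bundle`.
#' @param path Output path.
#' @param seq_name Genomic sequence identifier.
#' @param gene_id Feature ID prefix.
#' @export
write_locus_gff3 <- function(bundle, path, seq_name = "locus",
                             gene_id = "gene1") {
  m <- bundle$truth_gene_model
  src <- "ampstruct"
  lines <- c("##gff-version 3",
             .gff3_line(seq_name, src, "gene", 1L, m$genomic_len,
                        attributes = paste0("ID=", gene_id)),
             .gff3_line(seq_name, src, "mRNA", m$exons[1L, "start"],
                        m$exons[nrow(m$exons), "end"],
                        attributes = paste0("ID=", gene_id, ".t1;Parent=", gene_id)))
  for (e in seq_len(nrow(m$exons))) {
    lines <- c(lines, .gff3_line(seq_name, src, "exon", m$exons[e, "start"],
                                 m$exons[e, "end"],
                                 attributes = paste0("Parent=", gene_id, ".t1")))
  }
  if (!is.na(m$cds_start_on_cdna)) {
    cds_parts <- .cdna_interval_to_genomic(m, m$cds_start_on_cdna,
                                           m$cds_start_on_cdna + m$cds_len_nt - 1L)
    for (p in cds_parts) {
      lines <- c(lines, .gff3_line(seq_name, src, "CDS", p[1L], p[2L], phase = "0",
                                   attributes = paste0("Parent=", gene_id, ".t1")))
    }
    ann <- bundle$truth_annotation
    type_of <- c(signal = "signal_peptide", pro = "propeptide",
                 cleavage = "cleavage_site", HLD = "mature_peptide",
                 HD = "mature_peptide", spacer = "spacer",
                 mature = "mature_peptide", trailing = "propeptide")
    for (i in seq_len(nrow(ann))) {
      nt0 <- m$cds_start_on_cdna + 3L * (ann$start[i] - 1L)
      nt1 <- m$cds_start_on_cdna + 3L * ann$end[i] - 1L
      for (p in .cdna_interval_to_genomic(m, nt0, nt1)) {
        lines <- c(lines, .gff3_line(
          seq_name, src, type_of[[ann$role[i]]], p[1L], p[2L],
          attributes = paste0("Parent=", gene_id, ".t1;Note=", ann$role[i])))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the truth records of a bundle as a key-value sidecar
#' @param bundle A `locus_bundle`.
#' @param path Output path.
#' @export
write_truth_sidecar <- function(bundle, path) {
  m <- bundle$truth_gene_model
  ann <- bundle$truth_annotation
  lines <- c(
    paste0("seed=", bundle$seed),
    paste0("genomic_len=", nchar(bundle$genomic_seq)),
    paste0("cdna_len=", nchar(bundle$cdna_seq)),
    paste0("protein_len=", nchar(bundle$protein_seq)),
    paste0("cds_start_on_cdna=", m$cds_start_on_cdna),
    paste0("cds_len_nt=", m$cds_len_nt),
    paste0("exons=", paste(sprintf("%d-%d", m$exons[, "start"], m$exons[, "end"]),
                           collapse = ",")),
    paste0("introns=", if (nrow(m$introns) > 0L) {
      paste(sprintf("%d-%d", m$introns[, "start"], m$introns[, "end"]),
            collapse = ",")
    } else ""),
    paste0("segments=", paste(sprintf("%s:%d-%d", ann$role, ann$start, ann$end),
                              collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}
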