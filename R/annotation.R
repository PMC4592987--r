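#' Load gene models from a genome FASTA and GFF3 annotation
#'
#' Parses exon features grouped by transcript, converts coordinates from
#' GFF3 1-based inclusive to internal 0-based half-open, and derives each
#' transcript's spliced sequence: exons are ordered 5'-to-3' in transcript
#' orientation and minus-strand models carry the reverse-complemented
#' sequence. Exon-exon junction positions on the spliced sequence drive the
#' intron-aware primer region rules.
#'
#' @param fasta Path to the genome FASTA; sequence names must match GFF3
#'   seqids (descriptions after the first whitespace are ignored).
#' @param gff3 Path to the annotation. `exon` features are used, grouped by
#'   their `Parent` (falling back to `ID` for single-feature transcripts);
#'   when a file has no `exon` features, `CDS` features are used instead.
#' @return A named list of `gene_model` objects, each a list with
#'   `gene_id`, `chrom`, `strand`, `exons` (genomic 0-based half-open, in
#'   transcript orientation), `introns` (genomic), `genomic_span`,
#'   `spliced_seq` (character), `junctions` (0-based positions on the spliced
#'   sequence) and `n_exons`. Transcripts without exons are skipped; their
#'   IDs are recorded in the `skipped` attribute.
#' @export
load_annotation <- function(fasta, gff3) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- rtracklayer::import(gff3)
  feat_type <- as.character(ann$type)
  use_type <- if (any(feat_type == "exon")) "exon" else "CDS"
  exons <- ann[feat_type == use_type]
  tx_of <- function(gr) {
    parent <- gr$Parent
    ids <- vapply(seq_along(gr), function(i) {
      p <- parent[[i]]
      if (length(p) > 0) as.character(p[1])
      else if (!is.null(gr$ID) && !is.na(gr$ID[i])) as.character(gr$ID[i])
      else NA_character_
    }, character(1))
    ids
  }
  tx_ids <- tx_of(exons)
  if (anyNA(tx_ids))
    stop("exon/CDS feature without Parent or ID in ", gff3)
  # transcripts annotated but lacking exon features are skipped with a reason
  tx_feats <- ann[feat_type %in% c("mRNA", "transcript")]
  declared <- if (length(tx_feats) > 0) as.character(tx_feats$ID) else character(0)
  skipped <- setdiff(declared, unique(tx_ids))

  models <- list()
  for (tx in unique(tx_ids)) {
    ex <- exons[tx_ids == tx]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    if (!chrom %in% names(genome))
      stop("seqid ", chrom, " of transcript ", tx, " not in FASTA")
    strand <- as.character(GenomicRanges::strand(ex))[1]
    if (!strand %in% c("+", "-"))
      stop("transcript ", tx, " has no strand")
    st <- GenomicRanges::start(ex) - 1L   # to 0-based half-open
    en <- GenomicRanges::end(ex)
    ord <- order(st)
    st <- st[ord]; en <- en[ord]
    contig_len <- Biostrings::width(genome[chrom])
    if (any(st < 0) || any(en > contig_len))
      stop("exon of transcript ", tx, " outside contig ", chrom, " bounds")
    if (length(st) > 1 && any(st[-1] < en[-length(en)]))
      stop("overlapping exons in transcript ", tx)
    pieces <- Biostrings::DNAStringSet(genome[[chrom]],
                                       start = st + 1L, end = en)
    spliced <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
    exon_list <- cbind(start = st, end = en)
    intr <- NULL
    if (length(st) > 1)
      intr <- cbind(start = en[-length(en)], end = st[-1])
    if (strand == "-") {
      spliced <- Biostrings::reverseComplement(spliced)
      exon_list <- exon_list[rev(seq_len(nrow(exon_list))), , drop = FALSE]
      if (!is.null(intr)) intr <- intr[rev(seq_len(nrow(intr))), , drop = FALSE]
    }
    widths <- exon_list[, "end"] - exon_list[, "start"]
    junctions <- if (length(widths) > 1) cumsum(widths)[-length(widths)] else integer(0)
    models[[tx]] <- structure(list(
      gene_id = tx, chrom = chrom, strand = strand,
      exons = exon_list, introns = intr,
      genomic_span = c(start = min(st), end = max(en)),
      spliced_seq = as.character(spliced),
      junctions = as.integer(junctions),
      n_exons = nrow(exon_list)), class = "gene_model")
  }
  attr(models, "skipped") <- skipped
  models
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s: %s:%d-%d (%s), %d exon(s), spliced %d bp\n",
              x$gene_id, x$chrom, x$genomic_span["start"],
              x$genomic_span["end"], x$strand, x$n_exons,
              nchar(x$spliced_seq)))
  invisible(x)
}

#' Write gene models back to GFF3
#'
#' Emits gene/mRNA/exon features (1-based inclusive) so that a
#' [load_annotation()] round-trip recovers the same models.
#'
#' @param models List of `gene_model` objects.
#' @param path Output GFF3 path.
#' @return Invisibly, `path`.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    span1 <- m$genomic_span["start"] + 1L
    span2 <- m$genomic_span["end"]
    lines <- c(lines,
      sprintf("%s\trefprimer\tgene\t%d\t%d\t.\t%s\t.\tID=%s_gene",
              m$chrom, span1, span2, m$strand, m$gene_id),
      sprintf("%s\trefprimer\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s_gene",
              m$chrom, span1, span2, m$strand, m$gene_id, m$gene_id))
    ex <- m$exons[order(m$exons[, "start"]), , drop = FALSE]
    for (k in seq_len(nrow(ex)))
      lines <- c(lines,
        sprintf("%s\trefprimer\texon\t%d\t%d\t.\t%s\t.\tID=%s_exon%d;Parent=%s",
                m$chrom, ex[k, "start"] + 1L, ex[k, "end"], m$strand,
                m$gene_id, k, m$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}
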