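# CDS extraction from a GFF3 annotation plus genome FASTA.

#' Extract per-gene CDS from GFF3 and genome FASTA
#'
#' Joins CDS features per gene in genomic order, honours strand (reverse
#' complement for `-`) and the phase of the first CDS segment.
#'
#' @param gff3 Path to a GFF3 file with `gene`/`mRNA`/`CDS` features.
#' @param fasta Path to the genome FASTA (or a named character vector /
#'   `DNAStringSet` of chromosome sequences).
#' @return Named character vector of CDS keyed by gene id.
#' @export
extract_cds <- function(gff3, fasta) {
  gr <- rtracklayer::import(gff3)
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    fasta <- Biostrings::readDNAStringSet(fasta)
  if (is.character(fasta)) fasta <- Biostrings::DNAStringSet(fasta)
  names(fasta) <- sub("\\s.*", "", names(fasta))
  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) stop("no CDS features in ", gff3)
  # map CDS -> gene through Parent (mRNA) ids: <gene>.t1 convention or
  # direct gene parents
  parent <- vapply(as.list(cds$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  mrna <- gr[gr$type == "mRNA"]
  mrna_gene <- stats::setNames(
    vapply(as.list(mrna$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1)),
    mrna$ID)
  gene_of <- ifelse(parent %in% names(mrna_gene), mrna_gene[parent], parent)
  out <- character(0)
  for (g in unique(gene_of)) {
    seg <- cds[gene_of == g]
    seg <- seg[order(GenomicRanges::start(seg))]
    ch <- as.character(GenomicRanges::seqnames(seg))[1]
    if (!ch %in% names(fasta)) stop("chromosome ", ch, " absent from FASTA")
    pieces <- vapply(seq_along(seg), function(i)
      as.character(Biostrings::subseq(fasta[[ch]],
                                      GenomicRanges::start(seg)[i],
                                      GenomicRanges::end(seg)[i])),
      character(1))
    minus <- as.character(GenomicRanges::strand(seg))[1] == "-"
    s <- if (minus)
      revcomp(paste(rev(pieces), collapse = "")) else
        paste(pieces, collapse = "")
    ph <- seg$phase
    first_phase <- if (minus) ph[length(ph)] else ph[1]
    if (!is.na(first_phase) && first_phase > 0)
      s <- substring(s, first_phase + 1)
    out[g] <- substring(s, 1, nchar(s) - nchar(s) %% 3)
  }
  out
}
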