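#' Per-bin GC content
#'
#' Fraction (G+C)/(A+C+G+T) of each bin's sequence. Bins with no non-N bases
#' (or lying beyond the end of the sequence) are masked (`NA`). Used, together
#' with gene density, to pick the compartment-tracking principal component and
#' to orient its sign (positive = A = GC-rich).
#'
#' @param fasta path to a genome FASTA; record names are truncated at the
#'   first whitespace.
#' @param bins a [genome_bins()] object.
#' @return numeric vector in `[0, 1]` of length `nrow(bins)`, `NA` = masked.
#' @export
gc_track <- function(fasta, bins) {
  if (!file.exists(fasta)) stop_config("FASTA not found: ", fasta)
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- rep(NA_real_, nrow(bins))
  for (ch in unique(bins$chrom)) {
    if (!ch %in% names(seqs))
      stop_format("chromosome missing from FASTA: ", ch)
    s <- seqs[[ch]]
    len <- length(s)
    sel <- which(bins$chrom == ch)
    st <- pmin(bins$start[sel] + 1L, len + 1L)
    en <- pmin(bins$end[sel], len)
    ok <- st <= en
    if (!any(ok)) next
    v <- Biostrings::Views(s, start = st[ok], end = en[ok])
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    tot <- rowSums(f)
    gc <- ifelse(tot > 0, (f[, "G"] + f[, "C"]) / tot, NA_real_)
    out[sel[ok]] <- gc
  }
  out
}

#' Per-bin gene density
#'
#' Counts, for each bin, the gene bodies overlapping it by at least 1 bp; a
#' gene spanning k bins contributes to all k. Annotation may be BED (gene
#' bodies) or GTF/GFF (records with `type == "gene"`, or all records if none
#' are typed "gene").
#'
#' @param annotation path to a BED or GTF/GFF file.
#' @param bins a [genome_bins()] object.
#' @return nonnegative integer vector of length `nrow(bins)`.
#' @export
gene_density_track <- function(annotation, bins) {
  if (!file.exists(annotation)) stop_config("annotation not found: ", annotation)
  gr <- read_gene_ranges(annotation)
  as.numeric(GenomicRanges::countOverlaps(bins_granges(bins), gr,
                                          minoverlap = 1L))
}

read_gene_ranges <- function(annotation) {
  lower <- tolower(annotation)
  if (grepl("\\.(gtf|gff3?|gff)$", lower)) {
    gr <- rtracklayer::import(annotation)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene"))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    gr
  } else {
    rtracklayer::import(annotation, format = "BED")
  }
}

# gene names for annotate_genes(); falls back to coordinates when unnamed
gene_labels <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  for (col in c("gene_name", "name", "gene_id", "ID"))
    if (col %in% names(mc) && !all(is.na(mc[[col]])))
      return(as.character(mc[[col]]))
  paste0(GenomeInfoDb::seqnames(gr), ":", GenomicRanges::start(gr))
}
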