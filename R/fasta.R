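#' Read gene sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file into the tidy gene table used across
#' the package: one row per CDS, strand-normalised to coding orientation.
#' Record ids are taken up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @param source_accession Free-text provenance recorded on every record
#'   (defaults to the file name).
#' @return A tibble with columns `gene_id`, `seq`, `source_accession`,
#'   `frame_offset`.
#' @seealso [write_gene_fasta()]
#' @export
read_gene_fasta <- function(path, source_accession = basename(path)) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  validate_genes(tibble(
    gene_id = ids,
    seq = as.character(ss),
    source_accession = source_accession,
    frame_offset = 0L
  ))
}

#' Write a gene table to FASTA
#'
#' @param genes A gene tibble (columns `gene_id`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genes, path) {
  genes <- validate_genes(genes)
  ss <- Biostrings::DNAStringSet(setNames(genes$seq, genes$gene_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
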