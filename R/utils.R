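# Shared internal helpers.

# Round half away from zero (commercial rounding). base::round() rounds
# half to even, which never produces e.g. 47.76 from 47.755.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Split a string into single characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Render DNA bases in RNA alphabet for reporting (T -> U).
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

is_scalar_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

# Validate and normalise a gene table (tidy GeneRecord collection).
# Required: gene_id, seq. Optional columns get defaults.
validate_genes <- function(genes, arg = "genes") {
  if (!is.data.frame(genes) || !all(c("gene_id", "seq") %in% names(genes))) {
    abort(sprintf("`%s` must be a data frame with columns gene_id and seq", arg))
  }
  genes <- as_tibble(genes)
  if (!"source_accession" %in% names(genes)) genes$source_accession <- NA_character_
  if (!"frame_offset" %in% names(genes)) genes$frame_offset <- 0L
  genes$seq <- str_to_upper(genes$seq)
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("duplicate gene_id in `%s`: %s", arg,
                  paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")))
  }
  if (any(!nzchar(genes$gene_id)) || any(is.na(genes$gene_id))) {
    abort(sprintf("empty gene_id in `%s`", arg))
  }
  bad <- !grepl("^[ACGTN]+$", genes$seq)
  if (any(bad)) {
    abort(sprintf("`%s` sequences contain characters outside {A,C,G,T,N}: %s",
                  arg, paste(genes$gene_id[bad], collapse = ", ")))
  }
  if (any(nchar(genes$seq) < 3)) {
    abort(sprintf("`%s` sequences must be at least 3 nt long", arg))
  }
  genes
}
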