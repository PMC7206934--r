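#' Plastid codon table
#'
#' The 64-codon translation table used throughout the package. Plastid genes
#' use the bacterial-style code, whose amino-acid assignments are identical
#' to the standard genetic code (the tables differ only in which codons may
#' initiate translation); `ATG` is the canonical start.
#'
#' @return A named character vector of length 64 mapping codons (DNA
#'   alphabet, e.g. `"TCA"`) to one-letter amino acids, with `"*"` for the
#'   three stop codons.
#' @examples
#' codon_table()[["TCA"]] # "S"
#' @export
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16),
                   rep(rep(bases, each = 4), times = 4),
                   rep(bases, times = 16))
  aa <- chars("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG")
  setNames(aa, codons)
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation in reading frame 1. Internal stop codons are
#' kept in the output as `"*"` rather than truncating the protein, so a
#' premature stop introduced by RNA editing is visible to downstream
#' analyses. Codons containing any base outside `{A,C,G,T}` (e.g. `N`)
#' translate to `"X"`.
#'
#' @param cds A single DNA string.
#' @param allow_partial If `TRUE`, a trailing partial codon is silently
#'   dropped; if `FALSE` (default) a length not divisible by 3 is an error.
#' @param table Codon table, as from [codon_table()].
#' @return A single protein string, one letter per codon.
#' @examples
#' translate("ATGGCTTAA") # "MA*"
#' @export
translate <- function(cds, allow_partial = FALSE, table = codon_table()) {
  if (!is_scalar_string(cds)) abort("`cds` must be a single string")
  cds <- toupper(cds)
  if (!grepl("^[A-Z]*$", cds)) abort("`cds` must contain only letters")
  nrem <- nchar(cds) %% 3
  if (nrem != 0) {
    if (!allow_partial) {
      abort(sprintf("sequence length %d is not divisible by 3 (set allow_partial = TRUE to drop the trailing %d nt)",
                    nchar(cds), nrem))
    }
    cds <- substr(cds, 1, nchar(cds) - nrem)
  }
  if (nchar(cds) == 0) return("")
  starts <- seq(1, nchar(cds), by = 3)
  codons <- substring(cds, starts, starts + 2)
  aa <- unname(table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param seq A single DNA string over `{A,C,G,T,N}` (case preserved as
#'   upper case).
#' @return The reverse complement.
#' @examples
#' reverse_complement("ATGC") # "GCAT"
#' @export
reverse_complement <- function(seq) {
  if (!is_scalar_string(seq)) abort("`seq` must be a single string")
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq)) abort("`seq` must be over {A,C,G,T,N}")
  paste(rev(chars(chartr("ACGT", "TGCA", seq))), collapse = "")
}
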