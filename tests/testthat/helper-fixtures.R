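# Shared helpers for building fixtures in code.

ACGT <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(ACGT, n, replace = TRUE), collapse = "")

# random CDS of n_codons codons: ATG + sense codons + stop
random_cds <- function(n_codons) {
  sense <- setdiff(names(cpedit::codon_table()), c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

# a small GenBank flat file written to a temp path
write_toy_genbank <- function(path = tempfile(fileext = ".gb")) {
  writeLines(c(
    "LOCUS       TOYREC                    24 bp    DNA     linear   PLN 01-JAN-2000",
    "ACCESSION   TOYREC",
    "FEATURES             Location/Qualifiers",
    "     source          1..24",
    "     CDS             1..9",
    '                     /gene="fwd"',
    "     CDS             complement(1..9)",
    '                     /gene="rev"',
    "     CDS             join(1..6,10..15)",
    '                     /gene="spliced"',
    "     CDS             join(1..3,complement(5..7))",
    '                     /gene="mixed"',
    "ORIGIN",
    "        1 atgaaatagg ctgatcagta gacc",
    "//"
  ), path)
  path
}

toy_genbank_seq <- "ATGAAATAGGCTGATCAGTAGACC"

# independent affine-gap alignment score via Biostrings (gapOpening = 4,
# gapExtension = 1 reproduces open -5 / extend -1 for a length-L gap:
# -(4 + L) = -(5 + (L - 1)))
biostrings_score <- function(ref, alt) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(alt), Biostrings::DNAString(ref),
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 1,
    type = "global", scoreOnly = TRUE
  )
}

# exhaustive-enumeration alignment score (compiled oracle, no DP)
enum_score <- function(ref, alt) {
  cpedit:::nw_enum_score_cpp(ref, alt, 2, -1, -5, -1)
}

# brute-force PIC oracle: a column is informative iff its parsimony score
# varies across all unrooted topologies for those taxa. phyDat compresses
# duplicate site patterns, so per-pattern scores are expanded back through
# attr(, "index").
fitch_varies <- function(columns_mat) {
  ntax <- nrow(columns_mat)
  trees <- phangorn::allTrees(ntax, rooted = FALSE,
                              tip.label = rownames(columns_mat))
  pd <- phangorn::phyDat(tolower(columns_mat), type = "DNA")
  scores <- sapply(trees, function(tr) phangorn::fitch(tr, pd, site = "site"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  varies_pattern <- apply(scores, 1, function(s) any(s != s[1]))
  unname(varies_pattern[attr(pd, "index")])
}

# independent half-up rounding for summary oracles
round_half_up_oracle <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
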