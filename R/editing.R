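#' Call RNA editing sites from transcript-vs-gene comparison
#'
#' Aligns each transcript globally against its genomic CDS and reports one
#' editing site per substitution column. Indel columns never produce sites,
#' but a site whose codon also contains an indel is flagged
#' `frame_disrupted` instead of being dropped. Columns involving `N` never
#' call an edit. Substitutions other than C-to-U are retained with
#' `edit_type` `"U-to-C"` or `"other"` (possible sequencing error) rather
#' than silently discarded.
#'
#' Coordinates are 1-based CDS positions; `codon_index = ceiling(pos / 3)`
#' and `codon_pos = ((pos - 1) %% 3) + 1` after subtracting the gene's
#' `frame_offset`. Each site's codon consequence is annotated by changing
#' that single base within its reference codon (two edits falling in one
#' codon are each annotated independently).
#'
#' @param genes Gene tibble (`gene_id`, `seq`, optional `frame_offset`),
#'   strand-normalised to coding orientation.
#' @param transcripts Transcript tibble with matching `gene_id`s (DNA
#'   alphabet: edited positions carry `T`, not `U`).
#' @param params Alignment scoring from [alignment_params()].
#' @param scheme Amino-acid property scheme from [property_scheme()].
#' @param table Codon table from [codon_table()].
#' @return A tibble of editing sites sorted by gene and CDS position, with
#'   columns `gene_id`, `cds_pos`, `codon_index`, `codon_pos`, `ref_base`,
#'   `alt_base`, `edit_type`, `site_name`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `kind`, `ref_class`, `alt_class`,
#'   `frame_disrupted`.
#' @examples
#' genes <- tibble::tibble(gene_id = "toy", seq = "TCAGGG")
#' cdna <- tibble::tibble(gene_id = "toy", seq = "TTAGGG")
#' detect_editing_sites(genes, cdna)
#' @export
detect_editing_sites <- function(genes, transcripts,
                                 params = alignment_params(),
                                 scheme = property_scheme(),
                                 table = codon_table()) {
  genes <- validate_genes(genes, "genes")
  transcripts <- validate_genes(transcripts, "transcripts")
  shared <- intersect(genes$gene_id, transcripts$gene_id)
  missing_tx <- setdiff(genes$gene_id, shared)
  if (length(missing_tx)) {
    warn(sprintf("no transcript for %d gene(s): %s",
                 length(missing_tx), paste(head(missing_tx, 5), collapse = ", ")))
  }
  if (!length(shared)) return(empty_sites())

  tx <- setNames(transcripts$seq, transcripts$gene_id)
  out <- map(shared, function(g) {
    row <- genes[genes$gene_id == g, ]
    aln <- align_pair(row$seq, tx[[g]], params = params)
    sites_from_alignment(aln, row, scheme = scheme, table = table)
  })
  arrange(list_rbind(out), gene_id, cds_pos)
}

# One editing-site row per substitution column of a pairwise alignment.
sites_from_alignment <- function(aln, gene, scheme = property_scheme(),
                                 table = codon_table()) {
  stopifnot(inherits(aln, "cp_alignment"), nrow(gene) == 1)
  rc <- chars(aln$ref_aln)
  ac <- chars(aln$alt_aln)
  if (paste(rc[rc != "-"], collapse = "") != gene$seq) {
    abort(sprintf("alignment reference does not match gene sequence for \"%s\"",
                  gene$gene_id))
  }
  refpos <- cumsum(rc != "-")
  acgt <- c("A", "C", "G", "T")
  sub_cols <- which(rc != "-" & ac != "-" & rc != ac & rc %in% acgt & ac %in% acgt)
  if (!length(sub_cols)) return(empty_sites())

  # reference positions adjacent to any indel column
  disrupted <- integer(0)
  del_cols <- which(ac == "-")
  ins_cols <- which(rc == "-")
  if (length(del_cols)) disrupted <- c(disrupted, refpos[del_cols])
  if (length(ins_cols)) disrupted <- c(disrupted, refpos[ins_cols], refpos[ins_cols] + 1L)
  disrupted <- unique(disrupted)

  fo <- gene$frame_offset %||% 0L
  cds_pos <- refpos[sub_cols]
  pos_eff <- cds_pos - fo
  in_frame <- pos_eff >= 1
  codon_index <- ifelse(in_frame, ceiling(pos_eff / 3), NA_integer_)
  codon_pos <- ifelse(in_frame, ((pos_eff - 1) %% 3) + 1, NA_integer_)
  codon_start <- fo + 3L * (codon_index - 1L) + 1L
  codon_ok <- in_frame & !is.na(codon_index) & (codon_start + 2L) <= nchar(gene$seq)

  ref_base <- rc[sub_cols]
  alt_base <- ac[sub_cols]
  ref_codon <- ifelse(codon_ok, substring(gene$seq, codon_start, codon_start + 2L), NA)
  offset <- cds_pos - codon_start + 1L
  alt_codon <- ref_codon
  has_codon <- !is.na(ref_codon)
  if (any(has_codon)) {
    alt_codon[has_codon] <- mapply(function(cod, off, b) {
      substr(cod, off, off) <- b
      cod
    }, ref_codon[has_codon], offset[has_codon], alt_base[has_codon], USE.NAMES = FALSE)
  }

  cons <- classify_codons(ref_codon, alt_codon, codon_index,
                          scheme = scheme, table = table)
  frame_disrupted <- vapply(seq_along(sub_cols), function(i) {
    if (!codon_ok[i]) return(FALSE)
    any(disrupted >= codon_start[i] & disrupted <= codon_start[i] + 2L)
  }, logical(1))

  tibble(
    gene_id = gene$gene_id,
    cds_pos = as.integer(cds_pos),
    codon_index = as.integer(codon_index),
    codon_pos = as.integer(codon_pos),
    ref_base = ref_base,
    alt_base = alt_base,
    edit_type = dplyr::case_when(
      ref_base == "C" & alt_base == "T" ~ "C-to-U",
      ref_base == "T" & alt_base == "C" ~ "U-to-C",
      TRUE ~ "other"
    ),
    site_name = name_site(gene$gene_id, codon_index, cons$ref_aa, cons$alt_aa),
    ref_codon = cons$ref_codon,
    alt_codon = cons$alt_codon,
    ref_aa = cons$ref_aa,
    alt_aa = cons$alt_aa,
    kind = cons$kind,
    ref_class = cons$ref_class,
    alt_class = cons$alt_class,
    frame_disrupted = frame_disrupted
  )
}

empty_sites <- function() {
  tibble(
    gene_id = character(), cds_pos = integer(), codon_index = integer(),
    codon_pos = integer(), ref_base = character(), alt_base = character(),
    edit_type = character(), site_name = character(), ref_codon = character(),
    alt_codon = character(), ref_aa = character(), alt_aa = character(),
    kind = character(), ref_class = character(), alt_class = character(),
    frame_disrupted = logical()
  )
}

#' Canonical editing-site label
#'
#' Builds the site name `<gene>_<codonIndex><refAA><altAA>`, the
#' codon-indexed convention used for cross-species site tables (e.g.
#' `ndhB_50SL` for a serine-to-leucine change at codon 50). Silent edits
#' repeat the amino acid (`rpl2_10GG`); a premature stop uses `*`.
#'
#' @param gene_id Gene name(s).
#' @param codon_index 1-based codon index(es).
#' @param ref_aa,alt_aa One-letter amino acids (or `"*"`).
#' @return Character vector of site names (`NA` where any field is `NA`).
#' @seealso [parse_site_name()] which also accepts the
#'   `<gene>_<refAA><codonIndex><altAA>` variant sometimes seen in the
#'   literature.
#' @export
name_site <- function(gene_id, codon_index, ref_aa, alt_aa) {
  out <- paste0(gene_id, "_", codon_index, ref_aa, alt_aa)
  out[is.na(gene_id) | is.na(codon_index) | is.na(ref_aa) | is.na(alt_aa)] <- NA_character_
  out
}

#' Parse editing-site labels
#'
#' Accepts both label orders found in site tables — `ndhB_50SL`
#' (codon index first, the canonical form here) and `ndhA_S159L` — with
#' `_` or `-` separators, plus the separator-free `matK426HY` style.
#'
#' @param x Character vector of site labels.
#' @return A tibble with columns `site_name`, `gene_id`, `codon_index`,
#'   `ref_aa`, `alt_aa`.
#' @export
parse_site_name <- function(x) {
  if (!is.character(x)) abort("`x` must be a character vector")
  m1 <- str_match(x, "^(.+)[_-](\\d+)([A-Z*])([A-Z*])$")
  m2 <- str_match(x, "^(.+)[_-]([A-Z*])(\\d+)([A-Z*])$")
  m3 <- str_match(x, "^([A-Za-z][A-Za-z0-9]*?[A-Za-z])(\\d+)([A-Z*])([A-Z*])$")
  gene <- dplyr::coalesce(m1[, 2], m2[, 2], m3[, 2])
  idx <- dplyr::coalesce(m1[, 3], m2[, 4], m3[, 3])
  ref <- dplyr::coalesce(m1[, 4], m2[, 3], m3[, 4])
  alt <- dplyr::coalesce(m1[, 5], m2[, 5], m3[, 5])
  bad <- is.na(gene) & !is.na(x)
  if (any(bad)) {
    abort(sprintf("cannot parse site name(s): %s",
                  paste(unique(x[bad]), collapse = ", ")))
  }
  tibble(site_name = x, gene_id = gene, codon_index = as.integer(idx),
         ref_aa = ref, alt_aa = alt)
}

#' Summarise editing sites by codon position
#'
#' Tallies sites at the first, second and third codon base and reports
#' percentages rounded half-up to two decimals. In seed-plant plastids the
#' second base dominates because second-position C-to-U changes are almost
#' always nonsynonymous and restore conserved hydrophobic residues.
#'
#' @param sites A site tibble from [detect_editing_sites()] (or any data
#'   frame with a `codon_pos` column); sites with `NA` codon position are
#'   ignored.
#' @return A tibble (`codon_pos`, `n`, `pct`) of class
#'   `cp_position_summary`, with the total as attribute `total`. With zero
#'   usable sites the percentages are `NA`.
#' @export
summarise_codon_positions <- function(sites) {
  cp <- sites$codon_pos
  cp <- cp[!is.na(cp)]
  counts <- vapply(1:3, function(k) sum(cp == k), integer(1))
  position_summary(counts)
}

#' Codon-position summary from raw counts
#'
#' Low-level constructor for the codon-position summary, taking the three
#' counts directly — useful for published tables where only the counts are
#' available.
#'
#' @param counts Numeric vector of length 3: sites at codon positions
#'   1, 2, 3.
#' @return See [summarise_codon_positions()].
#' @examples
#' position_summary(c(7, 37, 2))
#' @export
position_summary <- function(counts) {
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 0)) {
    abort("`counts` must be three non-negative numbers")
  }
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 2) else rep(NA_real_, 3)
  out <- tibble(codon_pos = 1:3, n = as.integer(counts), pct = pct)
  class(out) <- c("cp_position_summary", class(out))
  attr(out, "total") <- as.integer(total)
  out
}

#' Read/write editing-site tables as TSV
#'
#' The on-disk interchange format for site tables: one row per site with
#' the full column layout of [detect_editing_sites()].
#'
#' @param sites A site tibble.
#' @param path TSV path.
#' @return `path` invisibly (writer); a site tibble (reader).
#' @export
write_sites_tsv <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = readr::col_character(),
                    cds_pos = readr::col_integer(),
                    codon_index = readr::col_integer(),
                    codon_pos = readr::col_integer(),
                    ref_base = readr::col_character(),
                    alt_base = readr::col_character(),
                    ref_codon = readr::col_character(),
                    alt_codon = readr::col_character(),
                    ref_aa = readr::col_character(),
                    alt_aa = readr::col_character(),
                    frame_disrupted = readr::col_logical()
                  ))
}
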