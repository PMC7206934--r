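#' Amino-acid property scheme
#'
#' Three-class hydropathy grouping of the 20 amino acids used to describe
#' what editing does to a protein: most plastid C-to-U edits convert
#' neutral or hydrophilic residues to hydrophobic ones (typically S-to-L
#' and P-to-L). The default grouping is
#' hydrophobic \{A, V, L, I, M, F, W\}, hydrophilic \{R, K, D, E, N, Q, H,
#' P\}, neutral \{G, S, T, C, Y\}; it can be overridden wholesale, e.g.
#' from an edited JSON file.
#'
#' @param hydrophobic,hydrophilic,neutral Character vectors partitioning
#'   the 20 standard amino acids.
#' @return Named character vector mapping each amino acid to its class.
#' @export
property_scheme <- function(hydrophobic = c("A", "V", "L", "I", "M", "F", "W"),
                            hydrophilic = c("R", "K", "D", "E", "N", "Q", "H", "P"),
                            neutral = c("G", "S", "T", "C", "Y")) {
  all_aa <- c(hydrophobic, hydrophilic, neutral)
  if (length(all_aa) != 20 || anyDuplicated(all_aa) ||
      !setequal(all_aa, chars("ACDEFGHIKLMNPQRSTVWY"))) {
    abort("scheme must partition the 20 standard amino acids")
  }
  c(setNames(rep("hydrophobic", length(hydrophobic)), hydrophobic),
    setNames(rep("hydrophilic", length(hydrophilic)), hydrophilic),
    setNames(rep("neutral", length(neutral)), neutral))
}

# Vectorised codon-change classification; NA codons give NA rows.
classify_codons <- function(ref_codon, alt_codon, codon_index = NA_integer_,
                            scheme = property_scheme(), table = codon_table()) {
  n <- length(ref_codon)
  codon_index <- rep_len(codon_index, n)
  ref_aa <- unname(table[ref_codon])
  alt_aa <- unname(table[alt_codon])
  ref_aa[!is.na(ref_codon) & is.na(ref_aa)] <- "X"
  alt_aa[!is.na(alt_codon) & is.na(alt_aa)] <- "X"
  kind <- dplyr::case_when(
    is.na(ref_aa) | is.na(alt_aa) ~ NA_character_,
    codon_index == 1 & ref_codon == "ACG" & alt_codon == "ATG" ~ "start_gain",
    codon_index == 1 & ref_codon == "ATG" & alt_codon != "ATG" ~ "start_loss_candidate",
    ref_aa == "*" & alt_aa == "*" ~ "stop_retained",
    ref_aa != "*" & alt_aa == "*" ~ "stop_gain",
    ref_aa == "*" & alt_aa != "*" ~ "stop_loss",
    ref_aa == alt_aa ~ "silent",
    TRUE ~ "missense"
  )
  cls <- function(aa) {
    out <- unname(scheme[aa])
    out[is.na(aa) | aa %in% c("*", "X")] <- NA_character_
    out
  }
  tibble(ref_codon = ref_codon, alt_codon = alt_codon,
         ref_aa = ref_aa, alt_aa = alt_aa, kind = kind,
         ref_class = cls(ref_aa), alt_class = cls(alt_aa))
}

#' Classify the consequence of a codon change
#'
#' Translates the reference and edited codon and assigns a consequence
#' kind: `silent`, `missense`, `stop_gain`, `stop_loss`, `stop_retained`,
#' `start_gain` (ACG edited to ATG at codon 1, creating a canonical
#' initiator) or `start_loss_candidate` (codon 1 ATG destroyed). Both
#' residues are also mapped to hydropathy classes under `scheme`.
#'
#' @param ref_codon,alt_codon Single codons that differ in at least one
#'   base.
#' @param codon_index 1-based codon index of the change; index 1 activates
#'   start-codon logic. `NA` treats the codon as internal.
#' @param protein_length Optional protein length in residues; for a
#'   `stop_gain` this adds `truncation_aa`, the number of residues lost
#'   (see [truncation_length()]).
#' @param scheme Property scheme from [property_scheme()].
#' @param table Codon table from [codon_table()].
#' @return A one-row tibble: `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `kind`, `ref_class`, `alt_class`, `truncation_aa`.
#' @examples
#' classify_codon_change("TCA", "TTA") # S -> L, neutral -> hydrophobic
#' @export
classify_codon_change <- function(ref_codon, alt_codon, codon_index = NA_integer_,
                                  protein_length = NULL,
                                  scheme = property_scheme(),
                                  table = codon_table()) {
  if (!is_scalar_string(ref_codon) || !is_scalar_string(alt_codon)) {
    abort("`ref_codon` and `alt_codon` must be single codons")
  }
  ref_codon <- toupper(ref_codon)
  alt_codon <- toupper(alt_codon)
  if (!ref_codon %in% names(table) || !alt_codon %in% names(table)) {
    abort("codons must be one of the 64 DNA codons")
  }
  if (ref_codon == alt_codon) abort("`ref_codon` and `alt_codon` are identical")
  out <- classify_codons(ref_codon, alt_codon, codon_index,
                         scheme = scheme, table = table)
  out$truncation_aa <- if (out$kind == "stop_gain" && !is.null(protein_length)) {
    truncation_length(as.integer(codon_index), as.integer(protein_length))
  } else {
    NA_integer_
  }
  out
}

#' Residues lost to a premature stop
#'
#' Number of amino acids deleted from the C-terminus when editing converts
#' the codon at `stop_codon_index` into a stop, counting the converted
#' codon itself: `protein_length - stop_codon_index + 1`.
#'
#' @param stop_codon_index 1-based codon index that became a stop.
#' @param protein_length Length of the unedited protein in residues
#'   (excluding the terminal stop).
#' @return Integer count of residues lost.
#' @examples
#' truncation_length(93, 100) # 8
#' @export
truncation_length <- function(stop_codon_index, protein_length) {
  stopifnot(is.numeric(stop_codon_index), is.numeric(protein_length))
  if (stop_codon_index < 1 || stop_codon_index > protein_length) {
    abort(sprintf("stop_codon_index %d outside [1, %d]",
                  as.integer(stop_codon_index), as.integer(protein_length)))
  }
  as.integer(protein_length - stop_codon_index + 1)
}

#' Tally consequence kinds and property-class transitions
#'
#' @param sites A site tibble carrying `kind`, `ref_class`, `alt_class`
#'   columns (as produced by [detect_editing_sites()]).
#' @return A list of class `cp_consequence_summary`: `kinds` (tibble
#'   `kind`, `n`) and `transitions` (tibble `ref_class`, `alt_class`, `n`
#'   over the full 3 x 3 class grid, counting sites where both residues
#'   have a defined class). Both tallies are invariant to row order.
#' @export
consequence_summary <- function(sites) {
  stopifnot(all(c("kind", "ref_class", "alt_class") %in% names(sites)))
  kinds <- sites %>%
    filter(!is.na(kind)) %>%
    count(kind, name = "n") %>%
    arrange(kind)
  classes <- c("hydrophobic", "hydrophilic", "neutral")
  grid <- tidyr::expand_grid(ref_class = classes, alt_class = classes)
  transitions <- sites %>%
    filter(!is.na(ref_class), !is.na(alt_class)) %>%
    count(ref_class, alt_class, name = "n")
  transitions <- grid %>%
    left_join(transitions, by = c("ref_class", "alt_class")) %>%
    mutate(n = dplyr::coalesce(n, 0L))
  structure(list(kinds = kinds, transitions = transitions),
            class = "cp_consequence_summary")
}

#' @export
print.cp_consequence_summary <- function(x, ...) {
  cat("Editing consequences\n\nKinds:\n")
  print(as.data.frame(x$kinds), row.names = FALSE)
  cat("\nProperty-class transitions (ref -> alt):\n")
  wide <- tidyr::pivot_wider(x$transitions, names_from = alt_class, values_from = n)
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Screen start codons for ACG editing candidates
#'
#' Many angiosperm plastid genes gain a canonical AUG initiator by editing
#' an ACG start codon. This reports, per gene, whether codon 1 is ACG and
#' whether any observed editing site falls inside codon 1 — genes with an
#' ACG start and no such site have "lost" (or never had) start-codon
#' editing.
#'
#' @param genes Gene tibble.
#' @param sites Observed site tibble.
#' @return A tibble `gene_id`, `first_codon`, `acg_start`,
#'   `codon1_edited`.
#' @export
acg_start_report <- function(genes, sites) {
  genes <- validate_genes(genes)
  edited1 <- sites %>%
    filter(!is.na(codon_index), codon_index == 1) %>%
    pull(gene_id) %>%
    unique()
  genes %>%
    mutate(first_codon = substr(seq, frame_offset + 1L, frame_offset + 3L),
           acg_start = first_codon == "ACG",
           codon1_edited = gene_id %in% edited1) %>%
    select(gene_id, first_codon, acg_start, codon1_edited)
}

#' Read a property scheme from JSON
#'
#' The JSON maps class names (`hydrophobic`, `hydrophilic`, `neutral`) to
#' arrays of one-letter amino acids, making the default scheme editable on
#' disk.
#'
#' @param path Path to a JSON file.
#' @return A validated scheme (see [property_scheme()]).
#' @export
read_property_scheme <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(c("hydrophobic", "hydrophilic", "neutral"), names(spec))
  if (length(missing)) {
    abort(sprintf("scheme JSON lacks class(es): %s", paste(missing, collapse = ", ")))
  }
  property_scheme(hydrophobic = spec$hydrophobic,
                  hydrophilic = spec$hydrophilic,
                  neutral = spec$neutral)
}
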