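#' Sequence context of editing sites
#'
#' Tallies the genomic (pre-editing) base at distance `flank` on the 5'
#' and 3' side of every editing site, plus the joint 5'/3' context, on the
#' coding strand. Bases are reported in the RNA alphabet (`T` rendered as
#' `U`), so the classic plastid bias reads as a 5' `U` / 3' `A` ("U_A")
#' preference.
#'
#' Sites within `flank` of a CDS end are excluded from all three tallies
#' (and counted in `n_excluded_boundary`), which keeps the joint table's
#' marginals exactly equal to the one-sided tables; sites with an `N` in
#' either flanking position are likewise excluded (`n_excluded_ambiguous`).
#'
#' @param sites Site tibble (needs `gene_id`, `cds_pos`).
#' @param genes Gene tibble supplying the sequences; every site's gene must
#'   be present and its coordinate in range.
#' @param flank Distance of the tallied base from the site (default 1,
#'   i.e. the immediately adjacent bases).
#' @return An object of class `cp_context_profile`: list with tibbles
#'   `preceding` and `following` (`base`, `n`, `freq`), `joint` (`base5`,
#'   `base3`, `n`, `freq`), and counts `n_sites`, `n_excluded_boundary`,
#'   `n_excluded_ambiguous`.
#' @export
context_profile <- function(sites, genes, flank = 1) {
  stopifnot(flank >= 1)
  genes <- validate_genes(genes)
  if (!all(sites$gene_id %in% genes$gene_id)) {
    abort(sprintf("sites reference unknown gene(s): %s",
                  paste(setdiff(unique(sites$gene_id), genes$gene_id), collapse = ", ")))
  }
  seqs <- setNames(genes$seq, genes$gene_id)
  glen <- nchar(seqs)[sites$gene_id]
  if (any(sites$cds_pos < 1 | sites$cds_pos > glen)) {
    abort("site coordinate outside its gene")
  }
  inside <- sites$cds_pos - flank >= 1 & sites$cds_pos + flank <= glen
  n_boundary <- sum(!inside)
  s <- sites[inside, , drop = FALSE]
  five <- substring(seqs[s$gene_id], s$cds_pos - flank, s$cds_pos - flank)
  three <- substring(seqs[s$gene_id], s$cds_pos + flank, s$cds_pos + flank)
  ok <- five != "N" & three != "N"
  n_amb <- sum(!ok)
  five <- dna_to_rna(five[ok])
  three <- dna_to_rna(three[ok])
  n <- length(five)

  rna <- c("U", "C", "A", "G")
  n_used <- n
  tally1 <- function(x) {
    counts <- unname(vapply(rna, function(b) sum(x == b), integer(1)))
    out <- tibble(base = rna, n = counts)
    out$freq <- if (n_used > 0) counts / n_used else NA_real_
    out
  }
  joint <- tidyr::expand_grid(base5 = rna, base3 = rna)
  joint$n <- map2_int_local(joint$base5, joint$base3, five, three)
  joint$freq <- if (n > 0) joint$n / n else NA_real_

  structure(list(
    preceding = tally1(five),
    following = tally1(three),
    joint = joint,
    n_sites = n,
    n_excluded_boundary = n_boundary,
    n_excluded_ambiguous = n_amb,
    flank = flank
  ), class = "cp_context_profile")
}

# joint context counts for each (5', 3') pair
map2_int_local <- function(b5, b3, five, three) {
  vapply(seq_along(b5), function(i) sum(five == b5[i] & three == b3[i]), integer(1))
}

#' @export
print.cp_context_profile <- function(x, ...) {
  cat(sprintf("Editing-site context profile (flank %d): %d sites (%d boundary-excluded, %d ambiguous)\n",
              x$flank, x$n_sites, x$n_excluded_boundary, x$n_excluded_ambiguous))
  cat("\n5' base:\n")
  print(as.data.frame(x$preceding), row.names = FALSE)
  cat("\n3' base:\n")
  print(as.data.frame(x$following), row.names = FALSE)
  top <- x$joint %>% arrange(desc(n)) %>% head(3)
  cat("\nTop joint contexts:",
      paste(sprintf("%s_%s %.2f%%", top$base5, top$base3, 100 * top$freq), collapse = ", "),
      "\n")
  invisible(x)
}

#' Extract sequence windows around editing sites
#'
#' Returns the genomic window centred on each site, the region thought to
#' be recognised by the PPR editing factors (roughly 30 nt around the
#' edited C). Windows are padded with `-` where they overrun a CDS end, so
#' all windows have length `2 * halfwidth + 1` with the edited base at the
#' centre.
#'
#' @param sites Site tibble (`gene_id`, `cds_pos`; `site_name` carried
#'   through when present).
#' @param genes Gene tibble.
#' @param halfwidth Bases on each side of the site (default 15).
#' @return A tibble `gene_id`, `site_name`, `cds_pos`, `window`.
#' @export
extract_windows <- function(sites, genes, halfwidth = 15) {
  stopifnot(halfwidth >= 1)
  genes <- validate_genes(genes)
  seqs <- setNames(genes$seq, genes$gene_id)
  if (!all(sites$gene_id %in% names(seqs))) {
    abort("sites reference genes absent from `genes`")
  }
  win <- vapply(seq_len(nrow(sites)), function(i) {
    s <- seqs[[sites$gene_id[i]]]
    p <- sites$cds_pos[i]
    lo <- p - halfwidth
    hi <- p + halfwidth
    core <- substring(s, max(1, lo), min(nchar(s), hi))
    paste0(strrep("-", max(0, 1 - lo)), core, strrep("-", max(0, hi - nchar(s))))
  }, character(1))
  tibble(
    gene_id = sites$gene_id,
    site_name = if ("site_name" %in% names(sites)) sites$site_name else NA_character_,
    cds_pos = sites$cds_pos,
    window = win
  )
}

#' Per-column information content of aligned windows
#'
#' Shannon information (bits) of each column over the four RNA bases:
#' `2 - H(column)`, with gap characters excluded column-wise. A fully
#' conserved column scores 2 bits; a column with equal quarters of all
#' four bases scores 0. Flat near-zero values outside the centre column
#' are the signature of editing sites with no conserved flanking motif.
#'
#' @param windows Character vector of equal-length windows, or the tibble
#'   from [extract_windows()].
#' @return A tibble `position` (1-based column), `offset` (relative to the
#'   centre column when the width is odd, otherwise `NA`), `info_bits`
#'   (`NA` for all-gap columns).
#' @export
column_information <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  if (!is.character(windows) || length(windows) < 2) {
    abort("need at least two windows")
  }
  w <- unique(nchar(windows))
  if (length(w) != 1) abort("windows must all have the same length")
  mat <- do.call(rbind, strsplit(toupper(windows), "", fixed = TRUE))
  mat <- chartr("T", "U", mat)
  info <- apply(mat, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "U")]
    if (!length(col)) return(NA_real_)
    p <- table(factor(col, levels = c("A", "C", "G", "U"))) / length(col)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  tibble(
    position = seq_len(w),
    offset = if (w %% 2 == 1) seq_len(w) - (w + 1) / 2 else NA_integer_,
    info_bits = as.numeric(info)
  )
}
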