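#' Is an alignment column parsimony-informative?
#'
#' A column is parsimony-informative (PIC) when, after excluding gaps and
#' ambiguous bases, at least two distinct states each occur in at least
#' two taxa — the standard definition, equivalently: the column can favour
#' one tree topology over another under parsimony.
#'
#' @param column Character vector of single characters, one per taxon,
#'   over `{A,C,G,T,-,N}` (case-insensitive; `?` also treated as missing).
#' @param missing Characters treated as missing rather than as states.
#' @return `TRUE`/`FALSE`.
#' @examples
#' is_parsimony_informative(c("A", "A", "T", "T")) # TRUE
#' is_parsimony_informative(c("A", "T", "C", "G")) # FALSE
#' @export
is_parsimony_informative <- function(column, missing = c("-", "N", "?")) {
  if (!length(column)) abort("empty column")
  states <- toupper(column)
  states <- states[!states %in% toupper(missing)]
  if (!length(states)) return(FALSE)
  tab <- table(states)
  sum(tab >= 2) >= 2
}

# alignment tibble (taxon, seq) -> character matrix (taxa x columns)
aln_matrix <- function(alignment, arg = "alignment") {
  if (is.matrix(alignment)) return(alignment)
  if (!is.data.frame(alignment) || !all(c("taxon", "seq") %in% names(alignment))) {
    abort(sprintf("`%s` must be a tibble with columns taxon and seq", arg))
  }
  if (anyDuplicated(alignment$taxon)) {
    abort(sprintf("duplicate taxon in `%s`: %s", arg,
                  paste(unique(alignment$taxon[duplicated(alignment$taxon)]), collapse = ", ")))
  }
  if (length(unique(nchar(alignment$seq))) > 1) {
    abort(sprintf("ragged alignment in `%s`: sequences differ in length", arg))
  }
  mat <- do.call(rbind, strsplit(toupper(alignment$seq), "", fixed = TRUE))
  rownames(mat) <- alignment$taxon
  mat
}

#' Count parsimony-informative characters in an alignment
#'
#' @param alignment A tibble with columns `taxon`, `seq` (equal-length
#'   aligned sequences) or a character matrix.
#' @inheritParams is_parsimony_informative
#' @return Integer count of informative columns.
#' @export
count_pic <- function(alignment, missing = c("-", "N", "?")) {
  mat <- aln_matrix(alignment)
  sum(apply(mat, 2, is_parsimony_informative, missing = missing))
}

#' Rank genes by PIC/length ratio and select phylogenetic loci
#'
#' Computes, for each per-gene alignment, the number of
#' parsimony-informative characters and the PIC/length ratio, and selects
#' genes whose ratio exceeds `threshold` (0.3 by default, the working rule
#' for picking loci that can resolve deep relationships). The cutoff is
#' strict (`>`) unless `inclusive = TRUE`.
#'
#' @param alignments Named list of per-gene alignments (tibbles
#'   `taxon`/`seq` or character matrices); names are the gene ids.
#' @param threshold PIC/length ratio cutoff.
#' @param inclusive Use `>=` instead of `>` at the cutoff.
#' @inheritParams is_parsimony_informative
#' @return A tibble `gene_id`, `aligned_length`, `pic_count`, `pic_ratio`,
#'   `selected`, sorted by decreasing ratio (ties broken by gene id).
#' @export
rank_loci_by_pic <- function(alignments, threshold = 0.3, inclusive = FALSE,
                             missing = c("-", "N", "?")) {
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    abort("`alignments` must be a named list (names = gene ids)")
  }
  rows <- imap(alignments, function(aln, g) {
    mat <- aln_matrix(aln, arg = g)
    tibble(gene_id = g,
           aligned_length = ncol(mat),
           pic_count = count_pic(mat, missing = missing))
  })
  out <- list_rbind(rows) %>%
    mutate(pic_ratio = pic_count / aligned_length,
           selected = if (inclusive) pic_ratio >= threshold else pic_ratio > threshold) %>%
    arrange(desc(pic_ratio), gene_id)
  out
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Joins per-gene alignments over the union of taxa, in the given gene
#' order, recording partition boundaries. A taxon missing from a gene gets
#' all-gap filler for that partition (flagged in the result).
#'
#' @param alignments Named list of per-gene alignments.
#' @param order Gene order in the supermatrix (default: list order).
#' @return An object of class `cp_supermatrix`: list with `alignment`
#'   (tibble `taxon`, `seq`), `partitions` (tibble `gene_id`, `start`,
#'   `end`, 1-based inclusive) and `missing` (tibble `taxon`, `gene_id` of
#'   gap-filled blocks).
#' @export
concat_supermatrix <- function(alignments, order = names(alignments)) {
  if (is.null(names(alignments))) abort("`alignments` must be a named list")
  if (!all(order %in% names(alignments))) {
    abort(sprintf("unknown gene(s) in `order`: %s",
                  paste(setdiff(order, names(alignments)), collapse = ", ")))
  }
  mats <- map(alignments[order], aln_matrix)
  taxa <- unique(unlist(map(mats, rownames)))
  lens <- map_int(mats, ncol)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  missing_blocks <- list()
  rows <- map_chr(taxa, function(tx) {
    paste(map_chr(seq_along(mats), function(k) {
      m <- mats[[k]]
      if (tx %in% rownames(m)) {
        paste(m[tx, ], collapse = "")
      } else {
        missing_blocks[[length(missing_blocks) + 1]] <<-
          tibble(taxon = tx, gene_id = order[k])
        strrep("-", lens[k])
      }
    }), collapse = "")
  })
  structure(list(
    alignment = tibble(taxon = taxa, seq = rows),
    partitions = tibble(gene_id = order, start = as.integer(starts), end = as.integer(ends)),
    missing = if (length(missing_blocks)) list_rbind(missing_blocks) else
      tibble(taxon = character(), gene_id = character())
  ), class = "cp_supermatrix")
}

#' @export
print.cp_supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d columns, %d partitions (%d gap-filled blocks)\n",
              nrow(x$alignment), nchar(x$alignment$seq[1]),
              nrow(x$partitions), nrow(x$missing)))
  invisible(x)
}

#' Export a supermatrix for external tree inference
#'
#' Writers for relaxed PHYLIP, NEXUS and FASTA, plus a RAxML-style
#' partition file (`DNA, gene = start-end`), so model selection and
#' ML/Bayesian inference can be run in external tools.
#'
#' @param x A `cp_supermatrix`.
#' @param path Output path.
#' @param format One of `"phylip"`, `"nexus"`, `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(x, path, format = c("phylip", "nexus", "fasta")) {
  stopifnot(inherits(x, "cp_supermatrix"))
  format <- match.arg(format)
  aln <- x$alignment
  ncols <- nchar(aln$seq[1])
  lines <- switch(format,
    phylip = c(sprintf("%d %d", nrow(aln), ncols),
               sprintf("%s  %s", format(aln$taxon, width = max(nchar(aln$taxon))), aln$seq)),
    nexus = c("#NEXUS", "BEGIN DATA;",
              sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(aln), ncols),
              "  FORMAT DATATYPE=DNA MISSING=N GAP=-;",
              "  MATRIX",
              sprintf("    %s  %s", format(aln$taxon, width = max(nchar(aln$taxon))), aln$seq),
              "  ;", "END;"),
    fasta = as.vector(rbind(paste0(">", aln$taxon), aln$seq))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_supermatrix
#' @export
write_partitions <- function(x, path) {
  stopifnot(inherits(x, "cp_supermatrix"))
  writeLines(sprintf("DNA, %s = %d-%d", x$partitions$gene_id,
                     x$partitions$start, x$partitions$end), path)
  invisible(path)
}

#' Neighbor-joining smoke-test tree
#'
#' Quick unrooted NJ tree from uncorrected p-distances, for sanity-checking
#' a supermatrix before handing it to external ML/Bayesian tools. Not a
#' substitute for model-based inference.
#'
#' @param x A `cp_supermatrix` or an alignment tibble (`taxon`, `seq`)
#'   with at least three taxa.
#' @return A `phylo` tree (see [ape::nj()]); write with
#'   [ape::write.tree()] for newick output.
#' @export
nj_tree <- function(x) {
  aln <- if (inherits(x, "cp_supermatrix")) x$alignment else x
  mat <- aln_matrix(aln)
  if (nrow(mat) < 3) abort("need at least 3 taxa")
  bin <- ape::as.DNAbin(tolower(mat))
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
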