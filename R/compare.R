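#' Species-by-site presence/absence matrix
#'
#' Container for cross-species comparison of orthologous editing sites.
#' Site identity follows the canonical codon-indexed label convention
#' (gene, codon index, amino-acid change); mapping sites between species'
#' coordinate systems is the caller's responsibility.
#'
#' @param presence A data frame with a `species` column followed by one
#'   0/1 column per site, or a logical/numeric matrix with species as row
#'   names and site names as column names.
#' @param clades Named character vector assigning a clade label (e.g.
#'   `"palms"`, `"monocots"`, `"dicots"`, `"gymnosperms"`) to every
#'   species; a single unnamed value is recycled.
#' @return An object of class `cp_species_matrix` with elements `species`,
#'   `clades`, `sites` and the logical `presence` matrix.
#' @export
species_site_matrix <- function(presence, clades = "all") {
  if (is.data.frame(presence)) {
    if (!"species" %in% names(presence)) abort("`presence` needs a `species` column")
    mat <- as.matrix(presence[setdiff(names(presence), c("species", "clade"))])
    rownames(mat) <- presence$species
    if ("clade" %in% names(presence) && identical(clades, "all")) {
      clades <- setNames(presence$clade, presence$species)
    }
  } else {
    mat <- as.matrix(presence)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("presence matrix needs species row names and site column names")
  }
  storage.mode(mat) <- "logical"
  if (anyNA(mat)) abort("presence values must be 0/1")
  if (anyDuplicated(rownames(mat))) abort("duplicate species")
  if (anyDuplicated(colnames(mat))) abort("duplicate site names")
  if (length(clades) == 1 && is.null(names(clades))) {
    clades <- setNames(rep(clades, nrow(mat)), rownames(mat))
  }
  if (!all(rownames(mat) %in% names(clades))) {
    abort(sprintf("missing clade label for: %s",
                  paste(setdiff(rownames(mat), names(clades)), collapse = ", ")))
  }
  structure(list(species = rownames(mat),
                 clades = clades[rownames(mat)],
                 sites = colnames(mat),
                 presence = mat),
            class = "cp_species_matrix")
}

#' @export
print.cp_species_matrix <- function(x, ...) {
  cat(sprintf("Species-site matrix: %d species x %d sites (clades: %s)\n",
              length(x$species), length(x$sites),
              paste(unique(x$clades), collapse = ", ")))
  invisible(x)
}

#' Write / read a species-site matrix as TSV (+ clade sidecar JSON)
#'
#' The TSV has species rows and 0/1 site columns; clade labels go to a
#' JSON sidecar mapping species to clade.
#'
#' @param x A `cp_species_matrix`.
#' @param path TSV path; the sidecar defaults to `<path>.clades.json`.
#' @param clade_path Optional explicit sidecar path.
#' @return `path` invisibly (writer); a `cp_species_matrix` (reader).
#' @export
write_species_matrix <- function(x, path, clade_path = paste0(path, ".clades.json")) {
  stopifnot(inherits(x, "cp_species_matrix"))
  df <- as_tibble(cbind(species = x$species,
                        as.data.frame(x$presence + 0L, check.names = FALSE)))
  readr::write_tsv(df, path)
  jsonlite::write_json(as.list(setNames(unname(x$clades), x$species)),
                       clade_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_species_matrix
#' @export
read_species_matrix <- function(path, clade_path = paste0(path, ".clades.json")) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  clades <- if (file.exists(clade_path)) {
    unlist(jsonlite::read_json(clade_path))
  } else {
    "all"
  }
  species_site_matrix(df, clades)
}

#' Shared and unique editing sites of a focal species
#'
#' For each clade, counts the focal species' sites present in at least one
#' member of that clade (the focal species itself never counts as
#' sharing); `unique` counts focal sites present in no other species.
#' Every focal site is therefore either unique or shared with at least one
#' clade.
#'
#' Published clade tallies sometimes nest one clade inside another (e.g.
#' palm species counted among the monocots) and sometimes keep them
#' disjoint; `clade_groups` makes the rule explicit, e.g.
#' `list(monocots = c("monocots", "palms"))` to count palms as monocots.
#'
#' @param x A `cp_species_matrix`.
#' @param focal Focal species name.
#' @param clade_groups Optional named list; each entry defines a reported
#'   group as the union of the listed clade labels. Default: one group per
#'   clade label present.
#' @return A tibble `group`, `n_shared`, with one extra row
#'   `group = "unique"`.
#' @export
shared_site_counts <- function(x, focal, clade_groups = NULL) {
  stopifnot(inherits(x, "cp_species_matrix"))
  if (!focal %in% x$species) {
    abort(sprintf("unknown species \"%s\"", focal))
  }
  focal_sites <- x$presence[focal, ]
  others <- setdiff(x$species, focal)
  if (is.null(clade_groups)) {
    labs <- unique(unname(x$clades))
    clade_groups <- setNames(as.list(labs), labs)
  }
  shared <- map_int(clade_groups, function(members) {
    sp <- others[x$clades[others] %in% members]
    if (!length(sp)) return(0L)
    present_any <- colSums(x$presence[sp, , drop = FALSE]) > 0
    sum(focal_sites & present_any)
  })
  unique_n <- if (length(others)) {
    sum(focal_sites & colSums(x$presence[others, , drop = FALSE]) == 0)
  } else {
    sum(focal_sites)
  }
  tibble(group = c(names(clade_groups), "unique"),
         n_shared = c(unname(shared), unique_n))
}

#' Sites shared jointly across several clades
#'
#' Counts the focal species' sites present in at least one member of
#' *each* listed clade (e.g. sites shared between monocots and dicots).
#'
#' @inheritParams shared_site_counts
#' @param clades Character vector of clade labels that must all share the
#'   site.
#' @return Integer count.
#' @export
shared_between_clades <- function(x, focal, clades) {
  stopifnot(inherits(x, "cp_species_matrix"))
  if (!focal %in% x$species) abort(sprintf("unknown species \"%s\"", focal))
  focal_sites <- x$presence[focal, ]
  others <- setdiff(x$species, focal)
  keep <- rep(TRUE, length(focal_sites))
  for (cl in clades) {
    sp <- others[x$clades[others] == cl]
    keep <- keep & (length(sp) > 0) &
      (colSums(x$presence[sp, , drop = FALSE]) > 0)
  }
  sum(focal_sites & keep)
}

#' Compare predicted editing sites against observed sites
#'
#' Set comparison of a prediction tool's site list with the observed
#' sites, keyed by gene and position. Inputs may be data frames sharing
#' key columns (`gene_id` plus `cds_pos`, or `gene_id` plus
#' `codon_index`), or character vectors of site labels (parsed with
#' [parse_site_name()], keyed by gene and codon index).
#'
#' @param predicted,observed Site sets (data frames or label vectors).
#' @return A one-row tibble: `n_predicted`, `n_observed`, `n_correct`,
#'   `precision_pct`, `recall_pct` (percentages rounded half-up to two
#'   decimals; `NA` — undefined, not zero — when the corresponding set is
#'   empty).
#' @examples
#' compare_predicted_sites(
#'   tibble::tibble(gene_id = "g", cds_pos = 1:67),
#'   tibble::tibble(gene_id = "g", cds_pos = c(1:32, 101:114))
#' )
#' @export
compare_predicted_sites <- function(predicted, observed) {
  as_df <- function(x, arg) {
    if (is.character(x)) x <- parse_site_name(x)
    if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame or character vector", arg))
    x
  }
  pd <- as_df(predicted, "predicted")
  od <- as_df(observed, "observed")
  key_col <- if (all(c("cds_pos") %in% names(pd)) && all(c("cds_pos") %in% names(od))) {
    "cds_pos"
  } else if ("codon_index" %in% names(pd) && "codon_index" %in% names(od)) {
    "codon_index"
  } else {
    abort("predicted and observed must share gene_id plus cds_pos or codon_index")
  }
  if (!all(c("gene_id", key_col) %in% names(pd)) ||
      !all(c("gene_id", key_col) %in% names(od))) {
    abort("predicted and observed must share gene_id plus cds_pos or codon_index")
  }
  p <- unique(paste(pd$gene_id, pd[[key_col]], sep = "\r"))
  o <- unique(paste(od$gene_id, od[[key_col]], sep = "\r"))
  n_correct <- length(intersect(p, o))
  tibble(
    n_predicted = length(p),
    n_observed = length(o),
    n_correct = n_correct,
    precision_pct = if (length(p) > 0) round_half_up(100 * n_correct / length(p), 2) else NA_real_,
    recall_pct = if (length(o) > 0) round_half_up(100 * n_correct / length(o), 2) else NA_real_
  )
}
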