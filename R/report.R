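#' Run the full editing analysis pipeline
#'
#' Orchestrates detection, codon-position summary, context profiling,
#' consequence tallies and (optionally) predicted-vs-observed comparison,
#' and bundles the results with a provenance block. Deterministic for
#' fixed inputs: the provenance carries a hash of the semantic
#' configuration, and every section is recomputed from the site table so
#' totals are mutually consistent.
#'
#' @param genes Gene tibble (see [read_gene_fasta()]).
#' @param transcripts Transcript tibble.
#' @param predicted Optional predicted-site set for
#'   [compare_predicted_sites()].
#' @param flank Context flank distance (see [context_profile()]).
#' @param params Alignment scoring ([alignment_params()]).
#' @param scheme Property scheme ([property_scheme()]).
#' @return An object of class `cp_run_report`: list with `sites`,
#'   `per_gene` (tibble `gene_id`, `n_sites`), `position_summary`,
#'   `context`, `consequences`, `prediction` (or `NULL`), and
#'   `provenance` (input sizes, parameters, config hash, package version,
#'   creation time).
#' @export
run_editing_pipeline <- function(genes, transcripts, predicted = NULL,
                                 flank = 1,
                                 params = alignment_params(),
                                 scheme = property_scheme()) {
  genes <- validate_genes(genes, "genes")
  transcripts <- validate_genes(transcripts, "transcripts")
  if (nrow(transcripts) == 0) {
    warn("empty transcript set: reporting zero sites")
    sites <- empty_sites()
  } else {
    sites <- detect_editing_sites(genes, transcripts, params = params,
                                  scheme = scheme)
  }
  per_gene <- sites %>% count(gene_id, name = "n_sites") %>% arrange(desc(n_sites), gene_id)
  config <- list(
    flank = flank,
    params = unclass(params),
    scheme = as.list(scheme),
    genes = genes$gene_id,
    transcripts = transcripts$gene_id
  )
  structure(list(
    sites = sites,
    per_gene = per_gene,
    position_summary = summarise_codon_positions(sites),
    context = context_profile(sites, genes, flank = flank),
    consequences = consequence_summary(sites),
    prediction = if (!is.null(predicted)) compare_predicted_sites(predicted, sites) else NULL,
    provenance = list(
      n_genes = nrow(genes),
      n_transcripts = nrow(transcripts),
      flank = flank,
      params = unclass(params),
      config_hash = hash(config),
      package_version = as.character(utils::packageVersion("cpedit")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "cp_run_report")
}

#' @export
print.cp_run_report <- function(x, ...) {
  n_genes_edited <- nrow(x$per_gene)
  cat(sprintf("RNA editing run report: %d site(s) in %d gene(s)\n",
              nrow(x$sites), n_genes_edited))
  if (nrow(x$per_gene)) {
    top <- head(x$per_gene, 3)
    cat("Most edited:", paste(sprintf("%s (%d)", top$gene_id, top$n_sites),
                              collapse = ", "), "\n")
  }
  ps <- x$position_summary
  if (!all(is.na(ps$pct))) {
    cat(sprintf("Codon positions 1/2/3: %d (%.2f%%), %d (%.2f%%), %d (%.2f%%)\n",
                ps$n[1], ps$pct[1], ps$n[2], ps$pct[2], ps$n[3], ps$pct[3]))
  }
  et <- table(x$sites$edit_type)
  if (length(et)) {
    cat("Edit types:", paste(sprintf("%s %d", names(et), et), collapse = ", "), "\n")
  }
  if (!is.null(x$prediction)) {
    cat(sprintf("Prediction: %d/%d correct (precision %.2f%%, recall %.2f%%)\n",
                x$prediction$n_correct, x$prediction$n_predicted,
                x$prediction$precision_pct, x$prediction$recall_pct))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `sites.tsv` (the full site table) and `report.json` (all summary
#' sections; exact fractions are stored alongside the rounded
#' percentages, so rounding never infects stored data).
#'
#' @param report A `cp_run_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "cp_run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(report$sites, file.path(dir, "sites.tsv"))
  ps <- report$position_summary
  total <- attr(ps, "total")
  json <- list(
    totals = list(n_sites = nrow(report$sites),
                  n_genes_edited = nrow(report$per_gene)),
    per_gene = report$per_gene,
    position_summary = list(
      counts = ps$n,
      pct = ps$pct,
      exact_fraction = if (total > 0) ps$n / total else rep(NA_real_, 3)
    ),
    context = list(
      preceding = report$context$preceding,
      following = report$context$following,
      joint = report$context$joint,
      n_sites = report$context$n_sites,
      n_excluded_boundary = report$context$n_excluded_boundary
    ),
    consequences = list(kinds = report$consequences$kinds,
                        transitions = report$consequences$transitions),
    prediction = report$prediction,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE)
  invisible(dir)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a run report
#'
#' @param x A `cp_run_report`.
#' @param ... Unused.
#' @return A one-row tibble with the headline counts.
#' @export
glance.cp_run_report <- function(x, ...) {
  ps <- x$position_summary
  tibble(
    n_sites = nrow(x$sites),
    n_genes_edited = nrow(x$per_gene),
    n_c_to_u = sum(x$sites$edit_type == "C-to-U"),
    n_missense = sum(x$sites$kind == "missense", na.rm = TRUE),
    n_silent = sum(x$sites$kind == "silent", na.rm = TRUE),
    n_stop_gain = sum(x$sites$kind == "stop_gain", na.rm = TRUE),
    pct_codon_pos2 = ps$pct[2]
  )
}

#' Tidy a context profile into a long tibble
#'
#' @param x A `cp_context_profile`.
#' @param ... Unused.
#' @return A tibble `side` (`preceding`/`following`/`joint`), `base`
#'   (joint contexts as `"U_A"`), `n`, `freq`.
#' @export
tidy.cp_context_profile <- function(x, ...) {
  bind_rows(
    x$preceding %>% mutate(side = "preceding"),
    x$following %>% mutate(side = "following"),
    x$joint %>% mutate(base = paste(base5, base3, sep = "_"), side = "joint") %>%
      select(base, n, freq, side)
  ) %>%
    select(side, base, n, freq)
}

#' Tidy a TM map into its segment table
#'
#' @param x A `cp_tm_map`.
#' @param ... Unused.
#' @return The segment tibble with `protein_id` attached.
#' @export
tidy.cp_tm_map <- function(x, ...) {
  x$segments %>% mutate(protein_id = x$protein_id, .before = 1)
}
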