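#' Configuration for the synthetic editing-data generator
#'
#' Defines the statistical structure the generator plants: the number and
#' length of CDSs, how many edits to plant, the codon-position skew and
#' the 5'U / 3'A context bias of the planted sites, and the fraction of
#' reverse (U-to-C) edits. The defaults mirror the site statistics
#' typically observed in a seed-plant chloroplast panel: codon-position
#' probabilities (0.1521, 0.8043, 0.0436), 5'U probability 0.6521, 3'A
#' probability 0.7391, 46 edits across 20 genes, and no reverse edits.
#'
#' @param n_genes Number of CDSs to simulate.
#' @param gene_length_range Inclusive range of gene lengths, in codons
#'   (start and stop codon included).
#' @param n_edits Number of edits to plant (unique positions).
#' @param codon_pos_probs Length-3 probability vector for the codon
#'   position of each planted edit; must sum to 1.
#' @param p_context_5U Probability that the base 5' of a planted site is
#'   `T` (genomic strand).
#' @param p_context_3A Probability that the base 3' of a planted site is
#'   `A`.
#' @param p_reverse_edit Fraction of edits planted as reverse (genomic
#'   `T` edited to `C`) rather than forward C-to-U.
#' @param seed Mandatory RNG seed; the whole fixture is reproducible from
#'   it.
#' @param max_attempts Rejection-sampling cap per edit; exhausting it is a
#'   loud infeasibility error, never a silent constraint relaxation.
#' @return A list of class `cp_sim_config`.
#' @export
sim_config <- function(n_genes = 20,
                       gene_length_range = c(100, 300),
                       n_edits = 46,
                       codon_pos_probs = c(0.1521, 0.8043, 0.0436),
                       p_context_5U = 0.6521,
                       p_context_3A = 0.7391,
                       p_reverse_edit = 0,
                       seed,
                       max_attempts = 10000) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` is mandatory")
  }
  if (length(gene_length_range) != 2 || gene_length_range[1] < 3 ||
      gene_length_range[2] < gene_length_range[1]) {
    abort("`gene_length_range` must be an increasing pair of codon counts >= 3")
  }
  if (length(codon_pos_probs) != 3 || any(codon_pos_probs < 0) ||
      abs(sum(codon_pos_probs) - 1) > 1e-6) {
    abort("`codon_pos_probs` must be three non-negative values summing to 1")
  }
  probs <- c(p_context_5U, p_context_3A, p_reverse_edit)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  structure(list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_edits = as.integer(n_edits),
    codon_pos_probs = as.numeric(codon_pos_probs),
    p_context_5U = p_context_5U,
    p_context_3A = p_context_3A,
    p_reverse_edit = p_reverse_edit,
    seed = as.integer(seed),
    max_attempts = as.integer(max_attempts)
  ), class = "cp_sim_config")
}

# the 61 sense codons (everything but TAA, TAG, TGA)
sense_codons <- function() {
  setdiff(names(codon_table()), c("TAA", "TAG", "TGA"))
}

#' Simulate chloroplast-gene-like coding sequences
#'
#' Random CDSs with an `ATG` start, a body of codons drawn uniformly from
#' the 61 sense codons (hence no internal stops) and a single terminal
#' stop codon. Output is fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A gene tibble (`gene_id`, `seq`, `source_accession`,
#'   `frame_offset`).
#' @export
simulate_cp_genes <- function(config) {
  stopifnot(inherits(config, "cp_sim_config"))
  set.seed(config$seed)
  len_choices <- seq(config$gene_length_range[1], config$gene_length_range[2])
  lens <- len_choices[sample.int(length(len_choices), config$n_genes, replace = TRUE)]
  sense <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  seqs <- vapply(lens, function(L) {
    paste0("ATG",
           paste(sample(sense, L - 2, replace = TRUE), collapse = ""),
           sample(stops, 1))
  }, character(1))
  validate_genes(tibble(
    gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
    seq = seqs,
    source_accession = "synthetic",
    frame_offset = 0L
  ))
}

#' Plant edits into simulated genes and emit transcripts plus truth ledger
#'
#' Chooses editable positions satisfying, per edit, a sampled codon
#' position and 5'/3' context class (rejection sampling over the pool of
#' remaining eligible positions), writes the edited transcripts, and
#' returns the complete ground-truth ledger including each edit's
#' intended codon consequence. Forward edits change a genomic `C` to `T`
#' in the transcript; reverse edits change a `T` to `C`. Positions are
#' unique per gene, and only positions with both flanking bases inside
#' the CDS are eligible (so every planted site has a defined context).
#'
#' @param genes Gene tibble, typically from [simulate_cp_genes()].
#' @param config The same [sim_config()]; the RNG stream is derived from
#'   `config$seed` (offset so that gene simulation and edit planting are
#'   independent).
#' @return A list of class `cp_synthetic_fixture`: `genes`, `transcripts`
#'   (tibble `gene_id`, `seq`), `truth` (site tibble in
#'   [detect_editing_sites()] column layout) and `config`.
#' @export
plant_edits <- function(genes, config) {
  stopifnot(inherits(config, "cp_sim_config"))
  genes <- validate_genes(genes)
  set.seed(config$seed + 1L)

  seq_chars <- lapply(setNames(genes$seq, genes$gene_id), chars)
  # pool of eligible positions with their sampling features
  pool <- list_rbind(imap(seq_chars, function(ch, g) {
    L <- length(ch)
    pos <- 2:(L - 1)
    tibble(gene_id = g, cds_pos = pos,
           ref_base = ch[pos],
           five_base = ch[pos - 1],
           three_base = ch[pos + 1])
  })) %>%
    filter(ref_base %in% c("C", "T")) %>%
    mutate(codon_pos = ((cds_pos - 1L) %% 3L) + 1L,
           key = paste(ref_base, codon_pos,
                       five_base == "T", three_base == "A", sep = "|"))

  buckets <- split(seq_len(nrow(pool)), pool$key)
  chosen <- integer(0)
  attempts <- 0L
  for (i in seq_len(config$n_edits)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > config$max_attempts) {
        abort(sprintf(
          "could not place edit %d of %d within %d attempts: not enough eligible positions for the requested constraints",
          i, config$n_edits, config$max_attempts))
      }
      cp <- sample.int(3, 1, prob = config$codon_pos_probs)
      want5U <- runif(1) < config$p_context_5U
      want3A <- runif(1) < config$p_context_3A
      rev_edit <- runif(1) < config$p_reverse_edit
      key <- paste(if (rev_edit) "T" else "C", cp, want5U, want3A, sep = "|")
      b <- buckets[[key]]
      if (length(b)) {
        pick <- b[sample.int(length(b), 1)]
        buckets[[key]] <- b[b != pick]
        chosen <- c(chosen, pick)
        break
      }
    }
  }

  truth_raw <- pool[chosen, , drop = FALSE] %>%
    mutate(alt_base = if_else(ref_base == "C", "T", "C")) %>%
    arrange(gene_id, cds_pos)

  # transcripts: apply the substitutions
  tx_chars <- seq_chars
  for (i in seq_len(nrow(truth_raw))) {
    g <- truth_raw$gene_id[i]
    tx_chars[[g]][truth_raw$cds_pos[i]] <- truth_raw$alt_base[i]
  }
  transcripts <- tibble(
    gene_id = genes$gene_id,
    seq = vapply(genes$gene_id, function(g) paste(tx_chars[[g]], collapse = ""),
                 character(1), USE.NAMES = FALSE),
    source_accession = "synthetic-transcript",
    frame_offset = 0L
  )

  # full ledger with intended consequences
  truth <- truth_raw %>%
    mutate(codon_index = ceiling(cds_pos / 3)) %>%
    mutate(ref_codon = substring(genes$seq[match(gene_id, genes$gene_id)],
                                 3 * (codon_index - 1) + 1, 3 * codon_index))
  alt_codon <- truth$ref_codon
  off <- truth$cds_pos - 3 * (truth$codon_index - 1)
  for (i in seq_len(nrow(truth))) {
    substr(alt_codon[i], off[i], off[i]) <- truth$alt_base[i]
  }
  cons <- classify_codons(truth$ref_codon, alt_codon, truth$codon_index)
  truth <- truth %>%
    mutate(alt_codon = alt_codon,
           ref_aa = cons$ref_aa, alt_aa = cons$alt_aa, kind = cons$kind,
           ref_class = cons$ref_class, alt_class = cons$alt_class,
           edit_type = if_else(ref_base == "C", "C-to-U", "U-to-C"),
           site_name = name_site(gene_id, codon_index, ref_aa, alt_aa),
           frame_disrupted = FALSE) %>%
    select(gene_id, cds_pos, codon_index, codon_pos, ref_base, alt_base,
           edit_type, site_name, ref_codon, alt_codon, ref_aa, alt_aa,
           kind, ref_class, alt_class, frame_disrupted) %>%
    mutate(cds_pos = as.integer(cds_pos), codon_index = as.integer(codon_index),
           codon_pos = as.integer(codon_pos))

  structure(list(genes = genes, transcripts = transcripts,
                 truth = truth, config = config),
            class = "cp_synthetic_fixture")
}

#' Simulate one synthetic fixture end to end
#'
#' Convenience wrapper: [simulate_cp_genes()] then [plant_edits()].
#'
#' @param config A [sim_config()].
#' @return See [plant_edits()].
#' @export
simulate_fixture <- function(config) {
  plant_edits(simulate_cp_genes(config), config)
}

#' @export
print.cp_synthetic_fixture <- function(x, ...) {
  cat(sprintf("Synthetic fixture: %d genes, %d planted edits (seed %d)\n",
              nrow(x$genes), nrow(x$truth), x$config$seed))
  invisible(x)
}

#' Simulate presence/absence of editing sites along a phylogeny
#'
#' Each site evolves independently as a two-state (absent/present) Markov
#' chain along the tree, with gain rate `gain_rate` (0 to 1) and loss
#' rate `loss_rate` (1 to 0). Over a branch of length `t` the probability
#' of changing state is `r / (gain + loss) * (1 - exp(-(gain + loss) t))`
#' with `r` the rate away from the current state. Closely related tips
#' therefore share more sites on average than distant ones — the pattern
#' observed for real plastid editing sites across seed plants.
#'
#' @param tree A newick string or `phylo` object (rooted, with branch
#'   lengths).
#' @param gain_rate,loss_rate Non-negative transition rates.
#' @param n_sites Number of independent sites.
#' @param seed RNG seed.
#' @param root_state `"stationary"` (default; present with probability
#'   `gain/(gain+loss)`), `"present"` or `"absent"`.
#' @param clades Clade labels for the tips (named vector or single
#'   value).
#' @return A [species_site_matrix()] over the tree's tips.
#' @export
simulate_species_sites <- function(tree, gain_rate, loss_rate, n_sites, seed,
                                   root_state = c("stationary", "present", "absent"),
                                   clades = "all") {
  root_state <- match.arg(root_state)
  if (gain_rate < 0 || loss_rate < 0) abort("rates must be >= 0")
  if (is.character(tree)) {
    tree <- tryCatch(ape::read.tree(text = tree), error = function(e) NULL,
                     warning = function(w) NULL)
    if (is.null(tree)) abort("malformed newick string")
  }
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object or newick string")
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  set.seed(seed)

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- gain_rate + loss_rate
  p_change <- function(state, t) {
    # probability of being in the other state after time t
    if (total == 0) return(rep(0, length(state)))
    r <- ifelse(state == 1, loss_rate, gain_rate)
    (r / total) * (1 - exp(-total * t))
  }
  states <- matrix(NA_integer_, nrow = ntip + nnode, ncol = n_sites)
  root <- ntip + 1L
  states[root, ] <- switch(root_state,
    stationary = rbinom(n_sites, 1, if (total > 0) gain_rate / total else 0),
    present = 1L,
    absent = 0L
  )
  tree <- stats::reorder(tree, "cladewise")
  for (k in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[k, 1]
    child <- tree$edge[k, 2]
    ps <- states[parent, ]
    flip <- runif(n_sites) < p_change(ps, tree$edge.length[k])
    states[child, ] <- ifelse(flip, 1L - ps, ps)
  }
  mat <- states[seq_len(ntip), , drop = FALSE]
  rownames(mat) <- tree$tip.label
  colnames(mat) <- sprintf("site%04d", seq_len(n_sites))
  species_site_matrix(mat == 1L, clades = clades)
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits `genes.fasta`, `transcripts.fasta`, `truth.tsv` and `config.json`
#' so a fixture can be consumed by external tools or reloaded later.
#'
#' @param fixture A `cp_synthetic_fixture` from [plant_edits()] /
#'   [simulate_fixture()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "cp_synthetic_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gene_fasta(fixture$genes, file.path(dir, "genes.fasta"))
  write_gene_fasta(fixture$transcripts, file.path(dir, "transcripts.fasta"))
  write_sites_tsv(fixture$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(unclass(fixture$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
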