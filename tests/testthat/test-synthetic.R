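test_that("gene simulation is deterministic and produces clean ORFs", {
  cfg <- sim_config(seed = 42)
  g1 <- simulate_cp_genes(cfg)
  g2 <- simulate_cp_genes(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 20)
  for (s in g1$seq) {
    prot <- translate(s)
    expect_match(prot, "^M[^*]+\\*$")  # ATG start, single terminal stop
  }
  lens <- nchar(g1$seq) / 3
  expect_true(all(lens >= 100 & lens <= 300))
})

test_that("codon usage of simulated genes is uniform over sense codons", {
  cfg <- sim_config(seed = 101, n_genes = 60, gene_length_range = c(200, 300))
  genes <- simulate_cp_genes(cfg)
  body <- unlist(lapply(genes$seq, function(s) {
    starts <- seq(4, nchar(s) - 3, by = 3)  # body codons only
    substring(s, starts, starts + 2)
  }))
  counts <- table(body)
  sense <- setdiff(names(codon_table()), c("TAA", "TAG", "TGA"))
  expect_setequal(names(counts), sense)
  # multinomial sampling oracle: chi-square goodness of fit against uniform
  gof <- stats::chisq.test(as.vector(counts), p = rep(1 / 61, 61))
  expect_gt(gof$p.value, 1e-3)
})

test_that("planting zero edits returns identical transcripts and empty ledger", {
  cfg <- sim_config(seed = 5, n_edits = 0)
  fx <- simulate_fixture(cfg)
  expect_equal(fx$transcripts$seq, fx$genes$seq)
  expect_equal(nrow(fx$truth), 0)
})

test_that("planted edits target genomic C (or T) at unique, context-true positions", {
  fx <- simulate_fixture(sim_config(seed = 9))
  seqs <- setNames(fx$genes$seq, fx$genes$gene_id)
  ref_at <- substring(seqs[fx$truth$gene_id], fx$truth$cds_pos, fx$truth$cds_pos)
  expect_equal(unname(ref_at), fx$truth$ref_base)
  expect_true(all(fx$truth$ref_base == "C"))  # default has no reverse edits
  expect_false(any(duplicated(fx$truth[c("gene_id", "cds_pos")])))

  # forced 5'U context
  fx5 <- simulate_fixture(sim_config(seed = 9, p_context_5U = 1))
  five <- substring(setNames(fx5$genes$seq, fx5$genes$gene_id)[fx5$truth$gene_id],
                    fx5$truth$cds_pos - 1, fx5$truth$cds_pos - 1)
  expect_true(all(five == "T"))

  # reverse edits are planted on T and typed U-to-C end to end
  fxr <- simulate_fixture(sim_config(seed = 9, p_reverse_edit = 1))
  expect_true(all(fxr$truth$ref_base == "T"))
  sites <- detect_editing_sites(fxr$genes, fxr$transcripts)
  expect_true(all(sites$edit_type == "U-to-C"))
})

test_that("infeasible edit demands fail loudly instead of truncating", {
  cfg <- sim_config(seed = 3, n_genes = 1, gene_length_range = c(4, 4),
                    n_edits = 30, max_attempts = 200)
  expect_error(simulate_fixture(cfg), "not enough eligible positions")
})

test_that("end-to-end detection reproduces the ledger composition exactly", {
  fx <- simulate_fixture(sim_config(seed = 77))
  sites <- detect_editing_sites(fx$genes, fx$transcripts)
  expect_equal(nrow(sites), nrow(fx$truth))
  key <- function(x) paste(x$gene_id, x$cds_pos, x$ref_base, x$alt_base)
  expect_setequal(key(sites), key(fx$truth))
  expect_equal(summarise_codon_positions(sites)$n,
               summarise_codon_positions(fx$truth)$n)
  expect_equal(consequence_summary(sites)$kinds, consequence_summary(fx$truth)$kinds)
})

test_that("codon-position fractions of many planted edits converge to the target", {
  cfg <- sim_config(seed = 55, n_genes = 150, gene_length_range = c(150, 300),
                    n_edits = 800)
  fx <- simulate_fixture(cfg)
  frac <- summarise_codon_positions(fx$truth)$n / 800
  for (k in 1:3) {
    p <- cfg$codon_pos_probs[k]
    expect_lt(abs(frac[k] - p), 3 * sqrt(p * (1 - p) / 800) + 1e-9)
  }
})

test_that("site evolution respects trivial rate limits", {
  tree <- "((A:0.2,B:0.2):0.3,C:0.5);"
  all_on <- simulate_species_sites(tree, gain_rate = 0.5, loss_rate = 0,
                                   n_sites = 50, seed = 1, root_state = "present")
  expect_true(all(all_on$presence))
  frozen <- simulate_species_sites(tree, gain_rate = 0, loss_rate = 0,
                                   n_sites = 50, seed = 1, root_state = "present")
  expect_true(all(frozen$presence))
  frozen0 <- simulate_species_sites(tree, gain_rate = 0, loss_rate = 0,
                                    n_sites = 50, seed = 1, root_state = "absent")
  expect_false(any(frozen0$presence))
  expect_error(simulate_species_sites("((A:0.1", 1, 1, 10, seed = 1),
               "malformed newick")
  # determinism
  a <- simulate_species_sites(tree, 0.3, 0.6, 100, seed = 8)
  b <- simulate_species_sites(tree, 0.3, 0.6, 100, seed = 8)
  expect_identical(a$presence, b$presence)
})

test_that("two-leaf change frequency matches the closed-form Markov probability", {
  g <- 0.2; l <- 0.5
  m <- simulate_species_sites("(A:0.3,B:0.7);", g, l, n_sites = 4000, seed = 21,
                              root_state = "present")
  for (leaf_t in list(c("A", 0.3), c("B", 0.7))) {
    t <- as.numeric(leaf_t[2])
    p_change <- (l / (g + l)) * (1 - exp(-(g + l) * t))
    obs <- mean(!m$presence[leaf_t[1], ])
    expect_lt(abs(obs - p_change), 3 * sqrt(p_change * (1 - p_change) / 4000))
  }
})

test_that("fixture bundles round-trip through disk", {
  fx <- simulate_fixture(sim_config(seed = 44))
  dir <- tempfile()
  write_fixture(fx, dir)
  expect_setequal(list.files(dir),
                  c("genes.fasta", "transcripts.fasta", "truth.tsv", "config.json"))
  genes <- read_gene_fasta(file.path(dir, "genes.fasta"))
  expect_equal(genes$seq, fx$genes$seq)
  truth <- read_sites_tsv(file.path(dir, "truth.tsv"))
  expect_equal(as.data.frame(truth), as.data.frame(fx$truth))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  expect_equal(cfg$seed, 44)
})
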