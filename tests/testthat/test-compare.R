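test_that("shared counts are trivial for identical and disjoint site sets", {
  sites <- paste0("ndhB_", 1:5, "SL")
  mat <- matrix(TRUE, 2, 5, dimnames = list(c("focal", "other"), sites))
  ssm <- species_site_matrix(mat, clades = c(focal = "palms", other = "palms"))
  counts <- shared_site_counts(ssm, "focal")
  expect_equal(counts$n_shared[counts$group == "palms"], 5L)
  expect_equal(counts$n_shared[counts$group == "unique"], 0L)

  mat2 <- rbind(focal = rep(TRUE, 5), other = rep(FALSE, 5))
  colnames(mat2) <- sites
  ssm2 <- species_site_matrix(mat2, clades = c(focal = "palms", other = "monocots"))
  counts2 <- shared_site_counts(ssm2, "focal")
  expect_equal(counts2$n_shared[counts2$group == "unique"], 5L)
  expect_equal(counts2$n_shared[counts2$group == "monocots"], 0L)

  expect_error(shared_site_counts(ssm, "missing_species"), "unknown species")
})

test_that("shared counts match an exhaustive per-site scan on random matrices", {
  set.seed(19)
  for (rep in 1:5) {
    mat <- matrix(stats::runif(10 * 30) < 0.4, 10, 30,
                  dimnames = list(paste0("sp", 1:10), paste0("ndhB_", 1:30, "SL")))
    clades <- setNames(sample(c("palms", "monocots", "dicots"), 10, replace = TRUE),
                       paste0("sp", 1:10))
    ssm <- species_site_matrix(mat, clades = clades)
    focal <- "sp1"
    counts <- shared_site_counts(ssm, focal)
    # brute force: scan every site against every other species
    for (cl in unique(unname(clades))) {
      manual <- 0L
      for (s in colnames(mat)) {
        if (!mat[focal, s]) next
        others <- setdiff(rownames(mat)[clades[rownames(mat)] == cl], focal)
        if (length(others) && any(mat[others, s])) manual <- manual + 1L
      }
      expect_equal(counts$n_shared[counts$group == cl], manual, info = cl)
    }
    manual_unique <- sum(vapply(colnames(mat), function(s) {
      mat[focal, s] && !any(mat[setdiff(rownames(mat), focal), s])
    }, logical(1)))
    expect_equal(counts$n_shared[counts$group == "unique"], manual_unique)

    # partition check: every focal site is unique or shared with >= 1 clade
    shared_any <- sum(vapply(colnames(mat), function(s) {
      mat[focal, s] && any(mat[setdiff(rownames(mat), focal), s])
    }, logical(1)))
    expect_equal(shared_any + manual_unique, sum(mat[focal, ]))

    # invariance to permuting species and site order
    perm <- mat[sample(10), sample(30)]
    counts_perm <- shared_site_counts(species_site_matrix(perm, clades), focal)
    expect_equal(dplyr::arrange(counts_perm, group), dplyr::arrange(counts, group))
  }
})

test_that("joint sharing across clades and clade grouping behave", {
  mat <- rbind(
    focal = c(TRUE, TRUE, TRUE, FALSE),
    mono1 = c(TRUE, FALSE, TRUE, TRUE),
    dico1 = c(TRUE, TRUE, FALSE, FALSE)
  )
  colnames(mat) <- paste0("g_", 1:4, "SL")
  clades <- c(focal = "palms", mono1 = "monocots", dico1 = "dicots")
  ssm <- species_site_matrix(mat, clades = clades)
  # sites present in >= 1 monocot AND >= 1 dicot: site 1 only
  expect_equal(shared_between_clades(ssm, "focal", c("monocots", "dicots")), 1L)
  # nested grouping: count palms within the monocots group
  grouped <- shared_site_counts(ssm, "focal",
                                clade_groups = list(monocots = c("monocots", "palms")))
  flat <- shared_site_counts(ssm, "focal", clade_groups = list(monocots = "monocots"))
  expect_true(grouped$n_shared[grouped$group == "monocots"] >=
                flat$n_shared[flat$group == "monocots"])
})

test_that("prediction comparison reproduces printed worked examples exactly", {
  cmp <- compare_predicted_sites(
    tibble::tibble(gene_id = "g", cds_pos = 1:67),
    tibble::tibble(gene_id = "g", cds_pos = c(1:32, 201:214))
  )
  expect_equal(cmp$n_predicted, 67L)
  expect_equal(cmp$n_observed, 46L)
  expect_equal(cmp$n_correct, 32L)
  expect_equal(cmp$precision_pct, 47.76)

  same <- tibble::tibble(gene_id = "g", cds_pos = 1:10)
  cmp2 <- compare_predicted_sites(same, same)
  expect_equal(cmp2$precision_pct, 100)
  expect_equal(cmp2$recall_pct, 100)

  # empty predicted set: precision undefined, not zero
  cmp3 <- compare_predicted_sites(tibble::tibble(gene_id = character(),
                                                 cds_pos = integer()), same)
  expect_true(is.na(cmp3$precision_pct))
  expect_equal(cmp3$recall_pct, 0)

  expect_error(compare_predicted_sites(c("ndhB_50SL", "garbage!!"), same),
               "cannot parse")
})

test_that("prediction comparison matches brute-force membership on random sets", {
  set.seed(4)
  for (rep in 1:10) {
    p <- tibble::tibble(gene_id = sample(c("a", "b"), 40, TRUE),
                        cds_pos = sample(1:60, 40, TRUE))
    o <- tibble::tibble(gene_id = sample(c("a", "b"), 40, TRUE),
                        cds_pos = sample(1:60, 40, TRUE))
    cmp <- compare_predicted_sites(p, o)
    pk <- unique(paste(p$gene_id, p$cds_pos))
    ok <- unique(paste(o$gene_id, o$cds_pos))
    manual <- sum(pk %in% ok)
    expect_equal(cmp$n_correct, manual)
    expect_equal(cmp$precision_pct, round_half_up_oracle(100 * manual / length(pk)))
    # swapping arguments swaps precision and recall
    swapped <- compare_predicted_sites(o, p)
    expect_equal(swapped$precision_pct, cmp$recall_pct)
    expect_equal(swapped$recall_pct, cmp$precision_pct)
  }
})

test_that("site labels can key the comparison through parsing", {
  cmp <- compare_predicted_sites(c("ndhB_50SL", "ndhA_S159L"),
                                 c("ndhB_50SL", "rpoC1_169SL"))
  expect_equal(cmp$n_correct, 1L)
  expect_equal(cmp$precision_pct, 50)
})

test_that("species matrices round-trip through TSV plus clade sidecar", {
  set.seed(2)
  mat <- matrix(stats::runif(12) < 0.5, 3, 4,
                dimnames = list(c("sp1", "sp2", "sp3"), paste0("g_", 1:4, "SL")))
  ssm <- species_site_matrix(mat, clades = c(sp1 = "palms", sp2 = "monocots",
                                             sp3 = "dicots"))
  path <- tempfile(fileext = ".tsv")
  write_species_matrix(ssm, path)
  back <- read_species_matrix(path)
  expect_equal(back$presence, ssm$presence)
  expect_equal(back$clades, ssm$clades)
})
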