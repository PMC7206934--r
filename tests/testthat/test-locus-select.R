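test_that("textbook columns classify correctly and ignore gaps", {
  expect_true(is_parsimony_informative(c("A", "A", "T", "T")))
  expect_false(is_parsimony_informative(c("A", "T", "C", "G")))
  expect_false(is_parsimony_informative(c("A", "A", "A", "T")))
  # gap/N are missing data, not a fifth state
  expect_false(is_parsimony_informative(c("A", "A", "-", "-", "N")))
  expect_true(is_parsimony_informative(c("A", "A", "-", "T", "T")))
  expect_error(is_parsimony_informative(character(0)), "empty")
  # taxon order invariance
  set.seed(1)
  col <- sample(c("A", "C", "-"), 8, TRUE)
  expect_equal(is_parsimony_informative(col), is_parsimony_informative(rev(col)))
})

test_that("PIC calls agree with the exhaustive tree-score oracle (small batch)", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (ntax in 4:6) {
    mat <- matrix(sample(c("A", "C", "G", "T", "-", "N"), ntax * 60, TRUE,
                         prob = c(0.3, 0.3, 0.15, 0.15, 0.05, 0.05)),
                  nrow = ntax, dimnames = list(paste0("t", seq_len(ntax)), NULL))
    mine <- apply(mat, 2, is_parsimony_informative)
    oracle <- fitch_varies(mat)
    expect_equal(unname(mine), oracle, info = paste("ntax", ntax))
  }
})

test_that("gene ranking applies the PIC/length cutoff strictly", {
  constant <- tibble::tibble(taxon = paste0("t", 1:4), seq = rep("AAAAAAAAAA", 4))
  # 4 informative columns out of 10
  inf <- c("AATT", "CCGG", "TTAA", "GGCC")
  toy <- tibble::tibble(
    taxon = paste0("t", 1:4),
    seq = vapply(1:4, function(i) {
      paste0(substr(inf[1], i, i), substr(inf[2], i, i), substr(inf[3], i, i),
             substr(inf[4], i, i), "AAAAAA")
    }, character(1))
  )
  ranked <- rank_loci_by_pic(list(flat = constant, toy = toy), threshold = 0.3)
  expect_equal(ranked$gene_id, c("toy", "flat"))
  expect_equal(ranked$pic_ratio, c(0.4, 0))
  expect_equal(ranked$selected, c(TRUE, FALSE))

  at_cut <- rank_loci_by_pic(list(toy = toy), threshold = 0.4)
  expect_false(at_cut$selected)
  expect_true(rank_loci_by_pic(list(toy = toy), threshold = 0.4,
                               inclusive = TRUE)$selected)

  ragged <- tibble::tibble(taxon = c("a", "b"), seq = c("AAA", "AAAA"))
  expect_error(rank_loci_by_pic(list(bad = ragged)), "ragged")
})

test_that("concatenation tiles partitions, gap-fills and conserves PIC", {
  g1 <- tibble::tibble(taxon = c("t1", "t2"), seq = c("AAATTT", "AAATTA"))
  g2 <- tibble::tibble(taxon = c("t1", "t2"), seq = c("CCCGGGAAA", "CCCGGGAAT"))
  sm <- concat_supermatrix(list(g1 = g1, g2 = g2))
  expect_equal(nchar(sm$alignment$seq), c(15L, 15L))
  expect_equal(sm$partitions$start, c(1L, 7L))
  expect_equal(sm$partitions$end, c(6L, 15L))

  # taxon missing from the second gene gets trailing gaps
  g2b <- g2[1, ]
  sm2 <- concat_supermatrix(list(g1 = g1, g2 = g2b))
  row_t2 <- sm2$alignment$seq[sm2$alignment$taxon == "t2"]
  expect_equal(substr(row_t2, 7, 15), strrep("-", 9))
  expect_equal(sm2$missing, tibble::tibble(taxon = "t2", gene_id = "g2"))

  expect_error(concat_supermatrix(list(dup = tibble::tibble(
    taxon = c("a", "a"), seq = c("AA", "AA")))), "duplicate taxon")

  # PIC additivity under concatenation and gene-order shuffles
  set.seed(6)
  genes <- lapply(1:4, function(i) {
    tibble::tibble(taxon = paste0("t", 1:6),
                   seq = vapply(1:6, function(j) random_dna(30), character(1)))
  })
  names(genes) <- paste0("g", 1:4)
  total <- sum(vapply(genes, count_pic, integer(1)))
  expect_equal(count_pic(concat_supermatrix(genes)$alignment), total)
  shuffled <- concat_supermatrix(genes, order = rev(names(genes)))
  expect_equal(count_pic(shuffled$alignment), total)
})

test_that("supermatrix exports are readable and partition file is RAxML-style", {
  g <- tibble::tibble(taxon = c("tax_one", "tax_two", "tax_three"),
                      seq = c("ACGTACGTA", "ACGTACGTT", "ACGAACGTA"))
  sm <- concat_supermatrix(list(locus = g))
  fa <- tempfile(fileext = ".fasta")
  write_supermatrix(sm, fa, format = "fasta")
  back <- Biostrings::readBStringSet(fa)
  expect_equal(names(back), g$taxon)
  expect_equal(as.character(back), setNames(g$seq, g$taxon))

  phy <- tempfile(fileext = ".phy")
  write_supermatrix(sm, phy, format = "phylip")
  first <- readLines(phy, n = 1)
  expect_equal(first, "3 9")

  nex <- tempfile(fileext = ".nex")
  write_supermatrix(sm, nex, format = "nexus")
  nx <- readLines(nex)
  expect_equal(nx[1], "#NEXUS")
  expect_true(any(grepl("NTAX=3 NCHAR=9", nx)))

  part <- tempfile(fileext = ".txt")
  write_partitions(sm, part)
  expect_equal(readLines(part), "DNA, locus = 1-9")
})

test_that("NJ smoke tree recovers simple topologies", {
  # additive case: two tight pairs separated by a long internal branch
  base <- strsplit("ACGTACGTACGTACGTACGTACGTACGTACGT", "")[[1]]
  far <- chartr("ACGT", "TGCA", paste(base, collapse = ""))
  mutate_at <- function(s, pos, to) { ss <- strsplit(s, "")[[1]]; ss[pos] <- to
                                      paste(ss, collapse = "") }
  aln <- tibble::tibble(
    taxon = c("A", "B", "C", "D"),
    seq = c(paste(base, collapse = ""),
            mutate_at(paste(base, collapse = ""), 1, "T"),
            far,
            mutate_at(far, 2, "A"))
  )
  tr <- nj_tree(aln)
  cph <- stats::cophenetic(tr)
  expect_lt(cph["A", "B"], cph["A", "C"])
  expect_lt(cph["C", "D"], cph["B", "C"])

  # identical sequences give a star tree with zero branch lengths
  star <- tibble::tibble(taxon = c("A", "B", "C", "D"),
                         seq = rep("ACGTACGT", 4))
  tr0 <- nj_tree(star)
  expect_true(all(abs(tr0$edge.length) < 1e-9))

  expect_error(nj_tree(star[1:2, ]), "at least 3")
})

test_that("NJ recovers a known 6-taxon simulated topology", {
  skip_if_not_installed("phangorn")
  set.seed(14)
  true_tree <- ape::read.tree(
    text = "((t1:0.02,t2:0.02):0.06,(t3:0.02,t4:0.02):0.06,(t5:0.02,t6:0.02):0.06);")
  dat <- phangorn::simSeq(true_tree, l = 2000)
  mat <- toupper(as.character(dat))
  aln <- tibble::tibble(taxon = rownames(mat),
                        seq = apply(mat, 1, paste, collapse = ""))
  est <- nj_tree(aln)
  expect_equal(phangorn::RF.dist(ape::unroot(true_tree), ape::unroot(est)), 0)
})
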