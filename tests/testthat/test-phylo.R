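test_that("identical sequences align without gaps at their self-score", {
  s <- random_protein(40, seed = 3)
  al <- pairwise_align(s, s)
  expect_equal(al$aligned_a, s)
  expect_equal(al$aligned_b, s)
  expect_equal(al$score, pksline:::.self_score(s))
  expect_equal(al$identity, 1)
})

test_that("global alignment score matches the textbook DP oracle", {
  S <- blosum62()
  expect_equal(pairwise_align("HEAGAWGHEE", "PAWHEAE")$score,
               oracle_nw_score("HEAGAWGHEE", "PAWHEAE", S))
  set.seed(17)
  for (i in 1:10) {
    a <- random_protein(sample(5:60, 1))
    b <- random_protein(sample(5:60, 1))
    expect_equal(pairwise_align(a, b)$score, oracle_nw_score(a, b, S))
    # symmetry
    expect_equal(pairwise_align(a, b)$score, pairwise_align(b, a)$score)
  }
})

test_that("alignment scores agree with an independent implementation", {
  set.seed(23)
  for (i in 1:5) {
    a <- random_protein(sample(20:80, 1))
    b <- random_protein(sample(20:80, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(pairwise_align(a, b)$score, ref)
  }
})

test_that("progressive MSA reduces to pairwise for two records and is
           gap-free for identical inputs", {
  a <- random_protein(30, seed = 5); b <- random_protein(34, seed = 6)
  aln <- progressive_msa(list(protein_record("a", a), protein_record("b", b)))
  pw <- pairwise_align(a, b)
  expect_equal(paste(aln["a", ], collapse = ""), pw$aligned_a)
  expect_equal(paste(aln["b", ], collapse = ""), pw$aligned_b)

  recs <- lapply(c("x", "y", "z"), function(id) protein_record(id, a))
  aln3 <- progressive_msa(recs)
  expect_equal(ncol(aln3), nchar(a))
  expect_false(any(aln3 == "-"))
})

test_that("MSA of a simulated family recovers ancestor columns", {
  set.seed(101)
  anc <- random_protein(120)
  leaves <- lapply(1:8, function(i) {
    ch <- strsplit(anc, "")[[1]]
    hit <- which(stats::runif(120) < 0.05)
    ch[hit] <- sample(AA20, length(hit), replace = TRUE)
    protein_record(paste0("L", i), paste(ch, collapse = ""))
  })
  aln <- progressive_msa(leaves)
  expect_gte(ncol(aln), 120)
  expect_gte(mean(colSums(aln == "-") == 0), 0.9)
})

test_that("NJ recovers a 4-taxon additive topology with exact lengths", {
  # tree: ((A:2,B:3):1,(C:4,D:5)) => additive distances
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 0 + 9 * 0, 0), 4, 4)
  D[3, 4] <- D[4, 3] <- 9
  dimnames(D) <- list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  tree <- nj_tree(distance_matrix(D))
  expect_true(ape::is.monophyletic(tree, c("A", "B")))
  expect_true(ape::is.monophyletic(tree, c("C", "D")))
  # tip branch lengths solve the additive system
  bl <- stats::setNames(tree$edge.length[tree$edge[, 2] <= 4],
                        tree$tip.label[tree$edge[tree$edge[, 2] <= 4, 2]])
  expect_equal(unname(bl[c("A", "B", "C", "D")]), c(2, 3, 4, 5))
})

test_that("three taxa resolve by the closed-form three-point equations", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(distance_matrix(D))
  bl <- stats::setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(nj_tree(distance_matrix(D[1:2, 1:2])), "at least 3")
})

test_that("NJ recovers the generating topology from random additive
           matrices and matches an independent NJ", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
    D <- ape::cophenetic.phylo(true)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    mine <- nj_tree(distance_matrix(D))
    expect_equal(unrooted_rf(mine, true), 0, info = paste("rep", i))
    expect_equal(unrooted_rf(mine, ape::nj(as.dist(D))), 0)
  }
})

test_that("NJ on an ultrametric matrix matches the UPGMA topology", {
  set.seed(13)
  true <- ape::rcoal(6)   # coalescent trees are ultrametric
  D <- ape::cophenetic.phylo(true)
  mine <- nj_tree(distance_matrix(D))
  upgma <- ape::as.phylo(stats::hclust(stats::as.dist(D),
                                       method = "average"))
  expect_equal(unrooted_rf(mine, upgma), 0)
})

test_that("negative branch lengths are clamped but retained as attributes", {
  # a non-additive matrix known to produce a negative NJ branch
  D <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 0.2,
                6, 6, 0.2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- nj_tree(distance_matrix(D))
  expect_true(all(tree$edge.length >= 0))
  raw <- attr(tree, "raw_lengths")
  expect_true(is.data.frame(raw))
  if (nrow(raw)) expect_true(all(raw$raw_length < 0))
})

test_that("newick write/read round-trips topology and lengths", {
  set.seed(3)
  true <- ape::rtree(6)
  D <- ape::cophenetic.phylo(true)
  tree <- nj_tree(distance_matrix(D))
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, tf)
  back <- read_newick(tf)
  expect_equal(unrooted_rf(tree, back), 0)
  expect_equal(sort(back$edge.length), sort(tree$edge.length),
               tolerance = 1e-6)
})

test_that("bootstrap supports: no-variance limit, single replicate,
           determinism", {
  # every column carries the same split -> every replicate identical
  taxa <- c("a1", "a2", "b1", "b2")
  aln <- rbind(rep("A", 30), rep("A", 30), rep("C", 30), rep("C", 30))
  # add within-pair signal so distances are not degenerate
  aln[1, 1:3] <- "G"; aln[3, 4:6] <- "H"
  rownames(aln) <- taxa
  bt <- bootstrap_tree(aln, n_replicates = 50, seed = 1)
  sup <- bt$node.label[!is.na(bt$node.label)]
  expect_true(all(sup == 100))

  bt1 <- bootstrap_tree(aln, n_replicates = 1, seed = 2)
  sup1 <- bt1$node.label[!is.na(bt1$node.label)]
  expect_true(all(sup1 %in% c(0, 100)))

  a <- bootstrap_tree(aln, n_replicates = 25, seed = 9)$node.label
  b <- bootstrap_tree(aln, n_replicates = 25, seed = 9)$node.label
  expect_identical(a, b)
  expect_true(all(stats::na.omit(a) >= 0 & stats::na.omit(a) <= 100))
})

test_that("distance matrices reject asymmetry and negativity", {
  M <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(distance_matrix(M), "symmetric")
  M2 <- matrix(c(0, -1, -1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(distance_matrix(M2), "negative")
})
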