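test_that("corrected distances match their closed forms", {
  expect_identical(pairwise_distance("ARNDK", "ARNDK"), 0)
  # p = 0.1
  a <- strrep("A", 10); b <- paste0(strrep("A", 9), "R")
  expect_equal(pairwise_distance(a, b), -log(0.9), tolerance = 1e-12)
  expect_equal(round(pairwise_distance(a, b), 5), 0.10536)
  # gamma tends to the Poisson distance for large shape
  expect_equal(pairwise_distance(a, b, model = "gamma", alpha = 1e6),
               -log(0.9), tolerance = 1e-3)
  # gamma correction exceeds Poisson at finite shape
  expect_gt(pairwise_distance(a, b, model = "gamma", alpha = 1), -log(0.9))
  # gaps: only both-non-gap columns compared
  expect_equal(pairwise_distance("AR-DK", "ARN-K"), 0)
  expect_error(pairwise_distance("A---", "-RND"), "comparable")
})

test_that("near-saturated pairs return the bounded sentinel, flagged", {
  a <- strrep("A", 20); b <- strrep("R", 20)
  d <- pairwise_distance(a, b)
  expect_equal(as.numeric(d), 10)
  expect_true(attr(d, "saturated"))
})

test_that("distance matrices are symmetric with zero diagonal", {
  seqs <- setNames(rep("ARNDKLIVWY", 3), c("a", "b", "c"))
  dm <- distance_matrix(msa(seqs))
  expect_identical(unname(dm[1:3, 1:3]), matrix(0, 3, 3))
  m <- simulate_family(evolution_scenario(n_taxa = 10, n_sites = 200, seed = 7))
  dm2 <- distance_matrix(m)
  expect_identical(unname(dm2), unname(t(dm2)))
  expect_true(all(diag(dm2) == 0) && all(dm2 >= 0))
  # degenerate pair is reported by name
  seqs3 <- c(x = "AR--", y = "AR--", z = "--ND")
  expect_error(distance_matrix(msa(seqs3)), "x / z")
})

test_that("estimated distances track true path lengths on a known tree", {
  m <- simulate_family(evolution_scenario(n_taxa = 12, n_sites = 1000,
                                          seed = 3, site_rates = c(all = 1),
                                          site_fractions = c(all = 1)))
  dm <- distance_matrix(m)
  tru <- stats::cophenetic(attr(m, "tree"))[rownames(dm), colnames(dm)]
  expect_gt(cor(dm[upper.tri(dm)], tru[upper.tri(tru)]), 0.9)
})

test_that("neighbour joining matches the three-taxon closed form and recovers additive trees", {
  m <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  class(m) <- c("dist_matrix", "matrix", "array")
  tr <- nj_tree(m)
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl[["a"]], (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-12)
  expect_equal(bl[["b"]], (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(bl[["c"]], (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-12)

  # additive five-taxon matrix: exact topology and branch lengths
  set.seed(11)
  true_tree <- ape::rtree(5)
  dm <- stats::cophenetic(true_tree)
  class(dm) <- c("dist_matrix", "matrix", "array")
  rec <- nj_tree(dm)
  expect_identical(ape::dist.topo(ape::unroot(true_tree), rec)[1], 0)
  expect_equal(stats::cophenetic(rec)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(nj_tree(dm[, c(2, 1, 3, 4, 5)]), "symmetric")
})

test_that("matrix correlation is affine-invariant and sign-faithful", {
  m <- simulate_family(evolution_scenario(n_taxa = 8, n_sites = 200, seed = 5))
  a <- distance_matrix(m)
  expect_equal(matrix_correlation(a, a)$r, 1.0)
  b <- a * 2 + 0.3; diag(b) <- 0
  class(b) <- class(a)
  expect_equal(matrix_correlation(a, b)$r, 1.0)
  # hand-computed three-point anticorrelation
  m1 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m2 <- m1
  m1[upper.tri(m1)] <- c(1, 2, 3); m1 <- m1 + t(m1)
  m2[upper.tri(m2)] <- c(3, 2, 1); m2 <- m2 + t(m2)
  class(m1) <- class(m2) <- c("dist_matrix", "matrix", "array")
  expect_equal(matrix_correlation(m1, m2, min_species = 3)$r, -1.0)
  expect_error(matrix_correlation(m1, m2), "at least 4")
  # restriction to common species
  b2 <- a[1:6, 1:6]
  class(b2) <- class(a)
  expect_identical(matrix_correlation(a, b2)$n_common, 6L)
})

test_that("permutation p-values behave at the identity and against vegan", {
  m <- simulate_family(evolution_scenario(n_taxa = 10, n_sites = 300, seed = 9))
  a <- distance_matrix(m)
  res <- correlation_significance(a, a, n_perm = 199, seed = 4)
  expect_equal(res$p_value, 1 / 200)
  expect_error(correlation_significance(a, a, n_perm = 50), "at least 99")

  skip_if_not_installed("vegan")
  m2 <- simulate_family(evolution_scenario(n_taxa = 10, n_sites = 300,
                                           seed = 10))
  b <- distance_matrix(m2)[rownames(a), rownames(a)]
  class(b) <- class(a)
  ours <- correlation_significance(a, b, n_perm = 999, seed = 2)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - ref$signif), 0.1)
})

test_that("mirror batch produces one row per pair with baselines included", {
  ms <- lapply(c(31, 32, 34), function(sd) simulate_family(
    evolution_scenario(n_taxa = 10, n_sites = 200, seed = sd)))
  mats <- list(x = distance_matrix(ms[[1]]), y = distance_matrix(ms[[2]]),
               z = distance_matrix(ms[[3]]))
  pairs <- data.frame(a = c("x", "x"), b = c("y", "z"),
                      role = c("interacting", "baseline"))
  tab <- mirror_batch(mats, pairs, n_perm = 99, seed = 1)
  expect_identical(nrow(tab), 2L)
  expect_true(all(abs(tab$r) <= 1))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
})

test_that("distance matrices and trees round-trip through PHYLIP and Newick", {
  m <- simulate_family(evolution_scenario(n_taxa = 8, n_sites = 150, seed = 6))
  dm <- distance_matrix(m)
  f <- withr::local_tempfile(fileext = ".phy")
  write_dist_phylip(dm, f)
  dm2 <- read_dist_phylip(f)
  expect_equal(dm2[rownames(dm), colnames(dm)], dm, tolerance = 1e-6,
               ignore_attr = TRUE)
  tr <- nj_tree(dm)
  ft <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, ft)
  tr2 <- read_tree_newick(ft)
  expect_identical(ape::dist.topo(tr, tr2)[1], 0)
})
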