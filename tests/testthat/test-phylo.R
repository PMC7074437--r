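three_taxon_D <- function(d12 = 0.2, d13 = 0.3, d23 = 0.4) {
  matrix(c(0, d12, d13, d12, 0, d23, d13, d23, 0), 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

test_that("three-taxon NJ matches the closed-form pendant lengths", {
  tr <- nj_tree(three_taxon_D())
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 0.05)
  expect_equal(len[["B"]], 0.15)
  expect_equal(len[["C"]], 0.25)
  # additivity: the 3-taxon tree reproduces its input distances exactly
  expect_equal(patristic(tr)[c("A", "B", "C"), c("A", "B", "C")],
               three_taxon_D())
})

test_that("two-taxon tree is a single path of the input length", {
  D <- matrix(c(0, 0.1, 0.1, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr <- nj_tree(D)
  expect_equal(sum(tr$edge.length), 0.1)
  expect_equal(patristic(tr)["x", "y"], 0.1)
})

test_that("NJ recovers random additive trees and their branch lengths", {
  skip_if_not_installed("phangorn")
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.01, 1))
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), est), 0)
    expect_lt(max(abs(patristic(est)[rownames(D), colnames(D)] - D)), 1e-9)
  }
})

test_that("NJ is deterministic and order-invariant via lexicographic ties", {
  g <- random_geno(8, 40, miss = 0, seed = 5)
  D <- snp_distance_matrix(g)
  t1 <- nj_tree(D)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  D2 <- D$d[perm, perm]
  t2 <- nj_tree(D2)
  P1 <- patristic(t1, plants = plant_ids(g))
  P2 <- patristic(t2, plants = plant_ids(g))
  expect_equal(P1, P2)
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2)), "undefined")
})

test_that("patristic distances are path sums and satisfy the four-point condition", {
  # trifurcating root, unit branches: path A->D crosses 4 edges
  tr <- read_newick(text = "((A:1,B:1):1,C:1,(D:1,E:1):1);")
  P <- patristic(tr)
  expect_equal(P["A", "B"], 2)
  expect_equal(P["A", "C"], 3)
  expect_equal(P["A", "D"], 4)
  expect_equal(unname(diag(P)), rep(0, 5))
  for (s in 1:3) {
    g <- random_geno(7, 30, miss = 0.05, seed = 70 + s)
    P <- patristic(nj_tree(snp_distance_matrix(g)))
    expect_lt(four_point_violation(P), 1e-12)
  }
})

test_that("bootstrap support is 100 for unanimous splits and deterministic", {
  calls <- rbind(A = rep(0, 30), B = rep(0, 30),
                 C = rep(2, 30), D = rep(2, 30))
  g <- make_geno(calls)
  bt <- bootstrap_support(g, replicates = 25, seed = 3)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  bt2 <- bootstrap_support(g, replicates = 25, seed = 3)
  expect_identical(write_newick(bt), write_newick(bt2))
  expect_error(bootstrap_support(g, replicates = 0), "replicates")
})

test_that("single-replicate bootstrap quantizes support to 0 or 100", {
  g <- random_geno(6, 40, miss = 0, seed = 8)
  bt <- bootstrap_support(g, replicates = 1, seed = 2)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("duplicating unanimous loci cannot decrease a clean split's support", {
  calls <- cbind(rbind(A = rep(0, 10), B = rep(0, 10),
                       C = rep(2, 10), D = rep(2, 10)),
                 matrix(sample(0:2, 4 * 10, replace = TRUE), 4))
  g <- make_geno(calls)
  base <- bootstrap_support(g, replicates = 40, seed = 6)
  dup <- make_geno(cbind(calls, calls[, 1:10]), plants = plant_ids(g))
  more <- bootstrap_support(dup, replicates = 40, seed = 6)
  split_support <- function(tree) {
    # support on the AB|CD split: the internal edge below {A,B} or {C,D}
    sup <- suppressWarnings(as.numeric(tree$node.label))
    max(sup, na.rm = TRUE)
  }
  expect_gte(split_support(more), split_support(base))
})

test_that("newick round-trip preserves lengths and support annotations", {
  g <- random_geno(6, 25, miss = 0, seed = 12)
  tr <- nj_tree(snp_distance_matrix(g))
  txt <- write_newick(tr)
  tr2 <- read_newick(text = txt)
  expect_equal(patristic(tr2)[tr$tip.label, tr$tip.label],
               patristic(tr)[tr$tip.label, tr$tip.label], tolerance = 1e-9)

  tr3 <- read_newick(text = "(A:1,B:2);")
  expect_equal(sort(tr3$tip.label), c("A", "B"))
  expect_equal(sort(tr3$edge.length), c(1, 2))

  tr4 <- read_newick(text = "(A:1,(B:2,C:3)97:4);")
  expect_true("97" %in% tr4$node.label)

  expect_error(read_newick(text = "(A:1,(B:2"), "malformed")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_equal(write_newick(read_newick(path)), txt)
})
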