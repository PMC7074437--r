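test_that("plant purity is the homozygous fraction of called loci", {
  g <- make_geno(rbind(a = rep(c(0, 2), 5)))
  expect_equal(plant_purity(g)$purity, 1.0)

  g2 <- make_geno(rbind(a = c(rep(0, 5), rep(2, 4), 1)))
  expect_equal(plant_purity(g2)$purity, 0.9)

  g3 <- make_geno(rbind(a = c(0, 2, 0, 2, 1, rep(NA, 5))))
  p3 <- plant_purity(g3)
  expect_equal(p3$purity, 0.8)
  expect_equal(p3$n_missing, 5L)

  g4 <- make_geno(rbind(a = c(0, 1), b = c(NA, NA)))
  expect_error(plant_purity(g4), "b")
})

test_that("cultivar purity table aggregates to percent summaries", {
  pur <- tibble::tibble(plant_id = c("p1", "p2", "p3"),
                        purity = c(0.90, 0.94, 0.88))
  sheet <- tibble::tibble(plant_id = c("p1", "p2", "p3"),
                          cultivar = c("A", "A", "B"))
  tab <- cultivar_purity_table(pur, sheet)
  a <- tab[tab$cultivar == "A", ]
  expect_equal(a$purity_pct, 92.0)
  expect_equal(a$min_pct, 90.0)
  expect_equal(a$max_pct, 94.0)
  expect_equal(a$sd_pct, 100 * sd(c(0.90, 0.94)))
  b <- tab[tab$cultivar == "B", ]
  expect_equal(b$sd_pct, 0)
  expect_true(b$single_plant)

  # identical purities give zero spread
  pur2 <- tibble::tibble(plant_id = c("p1", "p2"), purity = c(0.9, 0.9))
  tab2 <- cultivar_purity_table(pur2, sheet[1:2, ])
  expect_equal(tab2$sd_pct, 0)

  expect_error(cultivar_purity_table(
    tibble::tibble(plant_id = "zz", purity = 1), sheet), "zz")
})

test_that("stable heterozygous loci form per-cultivar sets with shared counts", {
  # locus 1: het in all of A and B, hom in C -> diag A, diag B, cell (A,B)
  # locus 2: het only in A; locus 3: het nowhere
  calls <- rbind(
    a1 = c(1, 1, 0), a2 = c(1, 1, 2),
    b1 = c(1, 0, 0), b2 = c(1, 0, 0),
    c1 = c(0, 0, 2), c2 = c(2, 0, 0))
  sheet <- tibble::tibble(plant_id = rownames(calls),
                          cultivar = rep(c("A", "B", "C"), each = 2))
  hs <- stable_het_loci(make_geno(calls), sheet)
  expect_equal(hs$counts["A", "A"], 2L)
  expect_equal(hs$counts["B", "B"], 1L)
  expect_equal(hs$counts["C", "C"], 0L)
  expect_equal(hs$counts["A", "B"], 1L)
  expect_equal(hs$counts["A", "C"], 0L)

  # zero heterozygous calls anywhere: all-zero matrix
  hs0 <- stable_het_loci(make_geno(matrix(0L, 4, 6),
                                   plants = sheet$plant_id[1:4]),
                         sheet[1:4, ])
  expect_true(all(hs0$counts == 0))
})

test_that("het sharing equals the brute-force set oracle and its bounds", {
  for (s in 1:5) {
    set.seed(200 + s)
    calls <- matrix(sample(0:2, 15 * 30, replace = TRUE, prob = c(.4, .2, .4)),
                    15, 30)
    calls[matrix(runif(450) < 0.1, 15, 30)] <- NA
    g <- make_geno(calls)
    sheet <- tibble::tibble(plant_id = plant_ids(g),
                            cultivar = rep(c("A", "B", "C"), each = 5))
    hs <- stable_het_loci(g, sheet)
    oracle <- oracle_stable_het(g$calls, sheet$cultivar)
    for (cv in names(oracle))
      expect_equal(hs$sets[[cv]], g$loci$key[oracle[[cv]]])
    cnt <- hs$counts
    for (i in 1:3) for (j in 1:3) if (i != j)
      expect_lte(cnt[i, j], min(cnt[i, i], cnt[j, j]))
  }
})

test_that("mutually equidistant cultivars yield no off-type flags", {
  n <- 8
  P <- matrix(0.02, n, n); diag(P) <- 0
  rownames(P) <- colnames(P) <- paste0("p", 1:n)
  sheet <- tibble::tibble(plant_id = rownames(P), cultivar = "A")
  ot <- classify_offtypes(P, sheet)
  expect_false(any(ot$plants$flagged))
})

test_that("a plant far outside the within-cultivar baseline is flagged", {
  # 19 plants at pairwise 0.02, one at 0.13 from everyone
  n <- 20
  P <- matrix(0.02, n, n)
  P[n, ] <- P[, n] <- 0.13
  diag(P) <- 0
  rownames(P) <- colnames(P) <- paste0("p", 1:n)
  sheet <- tibble::tibble(plant_id = rownames(P), cultivar = "A")
  ot <- classify_offtypes(P, sheet)
  expect_equal(offtype_plants(ot), "p20")
  # summary stats computed without the flagged plant
  expect_equal(ot$cultivars$d_avg, 0.02)
  expect_equal(ot$cultivars$d_max, 0.02)

  # invariance to plant order and to uniform distance rescaling
  perm <- sample(n)
  ot2 <- classify_offtypes(P[perm, perm], sheet)
  expect_equal(offtype_plants(ot2), "p20")
  ot3 <- classify_offtypes(10 * P, sheet)
  expect_equal(offtype_plants(ot3), "p20")

  # small cultivars are skipped with a warning, not flagged
  sheet2 <- tibble::tibble(plant_id = rownames(P)[1:2], cultivar = "B")
  expect_warning(ot4 <- classify_offtypes(P[1:2, 1:2], sheet2), "fewer than 3")
  expect_false(any(ot4$plants$flagged))
})

test_that("an injected contaminant is the one flagged plant (truth recovery)", {
  ex <- simulate_experiment(sim_config(seed = 1))
  filt <- suppressMessages(filter_markers(ex$genotypes))
  P <- patristic(nj_tree(snp_distance_matrix(filt)), plants = plant_ids(filt))
  ot <- classify_offtypes(P, ex$sheet)
  truth <- ex$truth$plants
  expect_setequal(offtype_plants(ot), truth$plant_id[truth$off_type])
})

test_that("distinctness reads cultivar separation off tree bipartitions", {
  # two clean clusters: both cultivars distinct and separated
  calls <- rbind(a1 = rep(0, 20), a2 = rep(0, 20), a3 = c(1, rep(0, 19)),
                 b1 = rep(2, 20), b2 = rep(2, 20), b3 = c(1, rep(2, 19)))
  g <- make_geno(calls)
  sheet <- tibble::tibble(plant_id = plant_ids(g),
                          cultivar = rep(c("A", "B"), each = 3))
  tree <- nj_tree(snp_distance_matrix(g))
  dc <- distinctness_check(tree, sheet)
  expect_true(all(dc$cultivars$distinct))
  expect_true(all(dc$pairs$separated))

  # cultivars simulated from the identical cross are non-separated
  ex <- simulate_experiment(sim_config(seed = 4))
  filt <- suppressMessages(filter_markers(ex$genotypes))
  tree2 <- nj_tree(snp_distance_matrix(filt))
  ot <- classify_offtypes(patristic(tree2, plants = plant_ids(filt)), ex$sheet)
  dc2 <- distinctness_check(tree2, ex$sheet, exclude = ot)
  ns <- dc2$pairs[!dc2$pairs$separated, ]
  expect_equal(nrow(ns), 1L)
  expect_setequal(c(ns$cultivar_a, ns$cultivar_b), c("cv1", "cv2"))
  expect_false(any(dc2$cultivars$distinct[dc2$cultivars$cultivar %in%
                                            c("cv1", "cv2")]))
  expect_true(all(dc2$cultivars$distinct[dc2$cultivars$cultivar %in%
                                           c("cv3", "cv4", "cv5")]))
})

test_that("downsampling with the full panel reproduces the full analysis", {
  ex <- simulate_experiment(sim_config(seed = 2))
  filt <- suppressMessages(filter_markers(ex$genotypes))
  L <- n_loci(filt)
  rb <- downsample_robustness(filt, ex$sheet, sizes = L, replicates = 1,
                              seed = 7)
  tree <- nj_tree(snp_distance_matrix(filt))
  ot <- classify_offtypes(patristic(tree, plants = plant_ids(filt)), ex$sheet)
  dc <- distinctness_check(tree, ex$sheet, exclude = ot)
  expect_equal(dplyr::arrange(rb$cultivars[, c("cultivar", "distinct")],
                              cultivar),
               dplyr::arrange(dc$cultivars[, c("cultivar", "distinct")],
                              cultivar))
  expect_setequal(rb$offtypes$plant_id[rb$offtypes$flagged],
                  offtype_plants(ot))

  # determinism under the master seed
  rb2 <- downsample_robustness(filt, ex$sheet, sizes = c(300, 100),
                               replicates = 2, seed = 9)
  rb3 <- downsample_robustness(filt, ex$sheet, sizes = c(300, 100),
                               replicates = 2, seed = 9)
  expect_identical(rb2$runs, rb3$runs)
  expect_identical(rb2$cultivars, rb3$cultivars)

  expect_error(downsample_robustness(filt, ex$sheet, sizes = L + 1), "exceeds")
})
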