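test_that("founder divergence behaves like independent allele flips", {
  base <- integer(10000)
  set.seed(50)
  expect_identical(diverge_genome(base, 0), base)
  expect_identical(diverge_genome(base, 1), rep(1L, 10000))
  d <- diverge_genome(base, 0.3)
  frac <- mean(d != base)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(frac - 0.3), 3 * se)
  expect_error(diverge_genome(base, 1.5), "\\[0, 1\\]")
})

test_that("simulated founders are homozygous with sorted collision-free loci", {
  cfg <- sim_config(n_loci = 500, seed = 21)
  fnd <- simulate_founders(cfg)
  expect_equal(nrow(fnd$loci), 500)
  expect_false(anyDuplicated(paste(fnd$loci$chrom, fnd$loci$pos)) > 0)
  for (f in fnd$founders) expect_true(all(f %in% 0:1))
  # shared-cross pair uses the identical founder pair
  expect_identical(fnd$founder_pairs$cv1, fnd$founder_pairs$cv2)
  # every cultivar has a two-founder cross
  expect_true(all(lengths(fnd$founder_pairs) == 2))
})

test_that("single-seed descent heterozygosity follows 0.5^g", {
  a <- integer(5000); b <- rep(1L, 5000)
  # F1: fully heterozygous at differing loci
  pop0 <- simulate_cultivar_population(a, b, g = 0, n_plants = 5, seed = 1)
  expect_true(all(pop0$calls == 1L))
  # deep selfing: absorbed to homozygosity
  pop30 <- simulate_cultivar_population(a, b, g = 30, n_plants = 5, seed = 2)
  expect_lt(mean(pop30$calls == 1L), 1e-3)
  # g = 6 decay within Monte-Carlo error
  pop6 <- simulate_cultivar_population(a, b, g = 6, n_plants = 20,
                                       seed = 3)
  het <- rowMeans(pop6$calls == 1L)
  se <- stats::sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - 0.5^6), 3 * se)
  # non-differing loci stay fixed at the founder genotype
  pop <- simulate_cultivar_population(c(a, 1L), c(b, 1L), g = 2,
                                      n_plants = 4, seed = 4)
  expect_true(all(pop$calls[, 5001] == 2L))

  expect_error(simulate_cultivar_population(a, b[-1], 1, 2), "length")
  expect_error(simulate_cultivar_population(c(a, 1L), c(b, 1L), 1, 2,
                                            stable_het_idx = 5001),
               "subset")
})

test_that("pinned loci stay heterozygous and are recovered by stable_het_loci", {
  # noise-free, contamination-free trial: recovery must be exact
  cfg <- sim_config(seed = 6, missing_rate = 0, error_rate = 0,
                    offtypes = tibble::tibble(host = character(),
                                              donor = character(),
                                              k = integer()))
  ex <- simulate_experiment(cfg)
  hs <- stable_het_loci(ex$genotypes, ex$sheet)
  for (cv in names(ex$truth$stable_het))
    expect_setequal(hs$sets[[cv]], ex$truth$stable_het[[cv]])

  # a contaminant plant carries homozygous calls at the host's pinned
  # loci, so a contaminated host legitimately loses its stable set
  cfg2 <- sim_config(seed = 6, missing_rate = 0, error_rate = 0)
  ex2 <- simulate_experiment(cfg2)
  hs2 <- stable_het_loci(ex2$genotypes, ex2$sheet)
  clean <- setdiff(names(hs2$sets), cfg2$offtypes$host)
  for (cv in clean)
    expect_setequal(hs2$sets[[cv]], ex2$truth$stable_het[[cv]])
  for (cv in cfg2$offtypes$host)
    expect_length(hs2$sets[[cv]], 0)
})

test_that("off-type injection relabels donor plants and is guarded", {
  a <- integer(200); b <- rep(1L, 200)
  set.seed(9)
  host <- simulate_cultivar_population(diverge_genome(a, 0.02), a,
                                       g = 6, n_plants = 10, seed = 11)
  donor <- simulate_cultivar_population(diverge_genome(a, 0.4),
                                        diverge_genome(a, 0.4),
                                        g = 6, n_plants = 10, seed = 12)
  expect_identical(inject_offtypes(host, donor, 0), host)
  out <- inject_offtypes(host, donor, 1, seed = 13)
  expect_equal(nrow(out$offtype), 1)
  victim <- out$offtype$plant_id
  # the contaminant now sits far from the host baseline
  g <- make_geno(out$calls)
  D <- snp_distance_matrix(g)$d
  r <- rowSums(D[victim, -match(victim, rownames(D)), drop = FALSE]) / 9
  host_med <- median(D[upper.tri(D)])
  expect_gt(unname(r)[1], 3 * host_med)

  expect_error(inject_offtypes(host, host, 1), "differ")
  expect_error(inject_offtypes(host, donor, 10), "at least one host")
})

test_that("noise applies missingness and the two genotyping error modes", {
  calls <- matrix(rep(c(0L, 1L, 2L), length.out = 1e5), 100)
  expect_identical(apply_noise(calls, 0, 0, seed = 1), calls)
  expect_true(all(is.na(apply_noise(calls, 1, 0, seed = 1))))
  noisy <- apply_noise(calls, 0.1, 0, seed = 2)
  frac <- mean(is.na(noisy))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
  # error mode: homs become het, hets become homs
  err <- apply_noise(calls, 0, 1, seed = 3)
  expect_true(all(err[calls != 1L] == 1L))
  expect_true(all(err[calls == 1L] %in% c(0L, 2L)))
})

test_that("SSR panel covers every chromosome and separates unrelated cultivars", {
  cfg <- sim_config(seed = 8, missing_rate = 0)
  ssr <- simulate_ssr_panel(cfg, seed = 15)
  expect_setequal(unique(ssr$chrom), paste0("chr", 1:20))
  expect_error(simulate_ssr_panel(cfg, n_markers = 10), "n_chromosomes")
  D <- ssr_distance_matrix(ssr)$d
  lab <- sub("-.*", "", rownames(D))
  within <- D[outer(lab, lab, `==`) & upper.tri(D)]
  expect_true(all(within == 0))
  # the shared-cross pair is identical on SSR; others separate
  cross <- D[lab == "cv1", lab == "cv2"]
  expect_true(all(cross == 0))
  other <- D[lab == "cv3", lab == "cv5"]
  expect_true(all(other > 0.5))
})

test_that("experiments are exact functions of config and master seed", {
  cfg <- sim_config(n_loci = 300, seed = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_experiment(cfg, out_dir = d1)
  simulate_experiment(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  ex <- simulate_experiment(sim_config(seed = 12))
  expect_equal(n_plants(ex$genotypes), 100)
  expect_equal(nrow(ex$sheet), 100)
  expect_equal(sum(ex$truth$plants$off_type), 2)
  # truth calls are the pre-noise dosages: equal wherever observed calls
  # are present and no error was injected at rate 0
  ex0 <- simulate_experiment(sim_config(seed = 12, missing_rate = 0,
                                        error_rate = 0))
  expect_identical(ex0$genotypes$calls, {
    m <- ex0$truth$calls; dimnames(m) <- dimnames(ex0$genotypes$calls); m
  })
})
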