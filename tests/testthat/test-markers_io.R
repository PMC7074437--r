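test_that("GT calls decode to dosages with missing and phasing handled", {
  p <- write_tmp_vcf(
    vcf_record("chr1", 100, "A", "G", c("0/0", "0|1", "1/1", "./.")),
    samples = c("p1", "p2", "p3", "p4"))
  g <- read_vcf(p)
  expect_equal(unname(g$calls[, 1]), c(0L, 1L, 2L, NA))
  expect_equal(plant_ids(g), c("p1", "p2", "p3", "p4"))

  # phased and unphased encodings of the same genotypes are identical
  p2 <- write_tmp_vcf(
    vcf_record("chr1", 100, "A", "G", c("0|0", "0/1", "1|1", ".|.")),
    samples = c("p1", "p2", "p3", "p4"))
  expect_equal(read_vcf(p2)$calls, g$calls)
})

test_that("loci are reordered into natural chromosome/position order", {
  p <- write_tmp_vcf(c(
    vcf_record("chr10", 50, "A", "G", c("0/0", "1/1")),
    vcf_record("chr1", 300, "C", "T", c("0/1", "0/0")),
    vcf_record("chr1", 100, "G", "A", c("1/1", "0/0")),
    vcf_record("chr2", 20, "T", "C", c("0/0", "0/1"))),
    samples = c("a", "b"))
  g <- read_vcf(p)
  expect_equal(g$loci$key, c("chr1:100", "chr1:300", "chr2:20", "chr10:50"))
  expect_equal(unname(g$calls["a", ]), c(2L, 1L, 0L, 0L))
})

test_that("multiallelic and indel records are skipped with a count, or rejected", {
  recs <- c(
    vcf_record("chr1", 100, "A", "G", c("0/0", "0/1")),
    vcf_record("chr1", 200, "A", "G,T", c("0/1", "1/2")),
    vcf_record("chr1", 300, "C", "T", c("1/1", "0/0")),
    vcf_record("chr1", 400, "CA", "C", c("0/0", "0/1")),
    vcf_record("chr1", 500, "G", "A", c("0/1", "0/1")))
  p <- write_tmp_vcf(recs, samples = c("x", "y"))
  expect_message(g <- read_vcf(p), "skipped 2")
  expect_equal(attr(g, "n_skipped"), 2L)
  expect_equal(n_loci(g), 3L)
  expect_error(read_vcf(p, multiallelic = "error"), "strict")
})

test_that("duplicate loci and absent GT are format errors", {
  p <- write_tmp_vcf(c(
    vcf_record("chr1", 100, "A", "G", c("0/0", "0/1")),
    vcf_record("chr1", 100, "A", "C", c("0/0", "0/1"))),
    samples = c("x", "y"))
  expect_error(read_vcf(p), "duplicate locus")
  p2 <- write_tmp_vcf(
    vcf_record("chr1", 100, "A", "G", c("20,3", "11,2"), format = "AD"),
    samples = c("x", "y"))
  expect_error(read_vcf(p2), "GT")
})

test_that("VCF round-trip is the identity on plants, loci and dosages", {
  g <- random_geno(3, 4, miss = 0, seed = 4)
  g$calls[2, 3] <- NA_integer_
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  # missing entries must be emitted as ./.
  expect_true(any(grepl("\\./\\.", readLines(path))))
  g2 <- read_vcf(path)
  expect_equal(g2$calls, g$calls)
  expect_equal(g2$loci, g$loci)
  expect_error(write_vcf(subset_genotypes(g, plants = integer(0)), path),
               "no plants")
})

test_that("sample sheets parse and reject duplicate plants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("plant_id\tcultivar", "p1\tA", "p2\tA"), path)
  sheet <- read_sample_sheet(path)
  expect_equal(nrow(sheet), 2)
  expect_equal(sheet$cultivar, c("A", "A"))
  writeLines(c("plant_id\tcultivar", "p1\tA", "p1\tB"), path)
  expect_error(read_sample_sheet(path), "duplicate")
})

test_that("SSR tables store unordered allele pairs and reject malformed sizes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("plant_id\tmarker\tallele1_bp\tallele2_bp",
               "p1\tSat_001\t210\t214",
               "p2\tSat_001\t214\t210",
               "p3\tSat_001\tNA\tNA"), path)
  tab <- read_ssr_table(path)
  expect_equal(tab$allele1_bp[1:2], c(210L, 210L))
  expect_equal(tab$allele2_bp[1:2], c(214L, 214L))
  expect_true(is.na(tab$allele1_bp[3]))
  writeLines(c("plant_id\tmarker\tallele1_bp\tallele2_bp",
               "p1\tSat_001\t210.5\t214"), path)
  expect_error(read_ssr_table(path), "malformed")
})
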