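# fixtures are built in code at test time; no binary data ships with the tests

toy_loci <- function(n, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = seq_len(n) * 100L,
                 ref = "A", alt = "G")
}

make_geno <- function(calls, plants = NULL, chrom = "chr1") {
  calls <- as.matrix(calls)
  if (is.null(plants)) plants <- rownames(calls)
  if (is.null(plants)) plants <- paste0("p", seq_len(nrow(calls)))
  genotype_matrix(calls, toy_loci(ncol(calls), chrom), plants = plants)
}

random_geno <- function(n_plants, n_loci, miss = 0.1, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n_plants * n_loci, replace = TRUE),
                  n_plants, n_loci)
  calls[matrix(runif(n_plants * n_loci) < miss, n_plants, n_loci)] <- NA
  make_geno(calls)
}

write_tmp_vcf <- function(records, samples, header_extra = character(0)) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    header_extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts, format = "GT") {
  paste(c(chrom, pos, ".", ref, alt, ".", ".", ".", format, gts),
        collapse = "\t")
}

# ---- independent brute-force oracles (naive per-locus / per-pair loops) ----

oracle_locus_stats <- function(calls) {
  n <- nrow(calls)
  t(vapply(seq_len(ncol(calls)), function(l) {
    alt <- 0; called <- 0
    for (i in seq_len(n)) {
      g <- calls[i, l]
      if (!is.na(g)) { called <- called + 1; alt <- alt + g }
    }
    p <- if (called > 0) alt / (2 * called) else NA_real_
    c(n_called = called, integrity = called / n, p_alt = p,
      maf = if (is.na(p)) NA_real_ else min(p, 1 - p))
  }, numeric(4)))
}

oracle_snp_distance <- function(calls) {
  n <- nrow(calls)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; shared <- 0
    for (l in seq_len(ncol(calls))) {
      a <- calls[i, l]; b <- calls[j, l]
      if (!is.na(a) && !is.na(b)) {
        shared <- shared + 1
        num <- num + abs(a - b)
      }
    }
    d[i, j] <- if (shared > 0) num / (2 * shared) else NA_real_
  }
  dimnames(d) <- list(rownames(calls), rownames(calls))
  d
}

oracle_purity <- function(calls) {
  vapply(seq_len(nrow(calls)), function(i) {
    hom <- 0; het <- 0
    for (l in seq_len(ncol(calls))) {
      g <- calls[i, l]
      if (is.na(g)) next
      if (g == 1) het <- het + 1 else hom <- hom + 1
    }
    hom / (hom + het)
  }, numeric(1))
}

oracle_stable_het <- function(calls, labels, min_callrate = 0.8) {
  cultivars <- unique(labels)
  sets <- lapply(cultivars, function(cv) {
    rows <- which(labels == cv)
    keep <- c()
    for (l in seq_len(ncol(calls))) {
      g <- calls[rows, l]
      n_called <- sum(!is.na(g))
      if (n_called == 0) next
      if (n_called / length(rows) < min_callrate) next
      if (all(g[!is.na(g)] == 1)) keep <- c(keep, l)
    }
    keep
  })
  names(sets) <- cultivars
  sets
}

# largest |entry| violation of the four-point condition over all quadruples
four_point_violation <- function(P) {
  n <- nrow(P)
  worst <- 0
  for (q in utils::combn(n, 4, simplify = FALSE)) {
    i <- q[1]; j <- q[2]; k <- q[3]; l <- q[4]
    s <- sort(c(P[i, j] + P[k, l], P[i, k] + P[j, l], P[i, l] + P[j, k]))
    worst <- max(worst, s[3] - s[2])
  }
  worst
}
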