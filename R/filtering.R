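#' Per-locus quality statistics
#'
#' Computes, for every locus, the alternate-allele frequency over called
#' alleles, the minor allele frequency (MAF), the integrity (call rate:
#' fraction of plants with a non-missing call) and the number of called
#' plants. A locus with no calls at all has undefined allele frequencies
#' (`NA`) and can never pass the marker filters.
#'
#' @param x A `geno_matrix` with at least one plant.
#' @return A tibble with one row per locus: `chrom`, `pos`, `ref`, `alt`,
#'   `key`, `n_called`, `integrity`, `p_alt`, `maf`.
#' @export
locus_stats <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  if (nrow(x$calls) < 1) stop("locus_stats needs at least one plant")
  called <- unname(colSums(!is.na(x$calls)))
  alt <- unname(colSums(x$calls, na.rm = TRUE))
  p <- ifelse(called > 0, alt / (2 * called), NA_real_)
  dplyr::mutate(x$loci,
                n_called = as.integer(called),
                integrity = called / nrow(x$calls),
                p_alt = p,
                maf = pmin(p, 1 - p))
}

#' Filter markers on minor allele frequency and integrity
#'
#' Retains loci with `maf >= maf_min` and `integrity >= integrity_min` (both
#' thresholds inclusive). Loci with undefined MAF (no calls) are always
#' removed. The plant set is unchanged. A per-locus report is attached as
#' attribute `"filter_report"` (see [filter_report()]): locus, maf,
#' integrity, pass flag and failure reason.
#'
#' @param x A `geno_matrix`.
#' @param maf_min Minimum minor allele frequency in `[0, 1]`; default 0.05.
#' @param integrity_min Minimum call rate in `[0, 1]`; default 0.8.
#' @return The filtered `geno_matrix` with the report attached.
#' @export
filter_markers <- function(x, maf_min = 0.05, integrity_min = 0.8) {
  stopifnot(inherits(x, "geno_matrix"))
  if (!is.numeric(maf_min) || maf_min < 0 || maf_min > 1 ||
      !is.numeric(integrity_min) || integrity_min < 0 || integrity_min > 1)
    stop("filter thresholds must lie in [0, 1]")
  st <- locus_stats(x)
  fail_maf <- is.na(st$maf) | st$maf < maf_min
  fail_int <- st$integrity < integrity_min
  pass <- !fail_maf & !fail_int
  reason <- dplyr::case_when(
    is.na(st$maf) ~ "undefined",
    fail_maf & fail_int ~ "maf+integrity",
    fail_maf ~ "maf",
    fail_int ~ "integrity",
    TRUE ~ NA_character_)
  report <- dplyr::mutate(
    st[, c("key", "chrom", "pos", "maf", "integrity")],
    pass = pass, fail_reason = reason)
  out <- subset_genotypes(x, loci = which(pass), sort_loci = FALSE)
  attr(out, "filter_report") <- report
  attr(out, "filter_params") <- list(maf_min = maf_min,
                                     integrity_min = integrity_min)
  out
}

#' Retrieve the per-locus report attached by [filter_markers()]
#' @param x A filtered `geno_matrix`.
#' @return A tibble, or `NULL` if `x` was not produced by `filter_markers()`.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' Adjacent-SNP gap statistics
#'
#' Distances (bp) between consecutive loci within each chromosome; gaps are
#' never taken across chromosome boundaries. Reports the mean gap, the
#' fraction of gaps below a threshold (the marker-density summary used for
#' SNP panels), and per-chromosome locus counts. With fewer than two loci on
#' every chromosome there are no gaps and the fraction is `NA`.
#'
#' @param loci A `geno_matrix` or a loci tibble with `chrom` and `pos`,
#'   sorted in canonical order (an unsorted input is a contract error).
#' @param threshold_bp Gap threshold in bp; default 150000 (150 kb).
#' @return An object of class `gap_stats`: list with `gaps` (tibble `chrom`,
#'   `gap`), `per_chrom` (tibble `chrom`, `n_loci`), `mean_gap`,
#'   `frac_below`, `threshold_bp`.
#' @export
gap_stats <- function(loci, threshold_bp = 150000) {
  if (inherits(loci, "geno_matrix")) loci <- loci$loci
  loci <- tibble::as_tibble(loci)
  if (!loci_sorted(loci$chrom, loci$pos))
    stop("loci must be sorted by (chrom, pos) before gap_stats")
  by_chr <- split(loci$pos, factor(loci$chrom, levels = unique(loci$chrom)))
  gaps <- purrr::imap(by_chr, function(pos, chrom) {
    if (length(pos) < 2) return(NULL)
    tibble::tibble(chrom = chrom, gap = diff(pos))
  })
  gaps <- dplyr::bind_rows(gaps)
  per_chrom <- tibble::tibble(chrom = names(by_chr),
                              n_loci = lengths(by_chr))
  n_gaps <- if (is.null(gaps) || nrow(gaps) == 0) 0L else nrow(gaps)
  structure(list(
    gaps = if (n_gaps) gaps else tibble::tibble(chrom = character(),
                                                gap = integer()),
    per_chrom = per_chrom,
    mean_gap = if (n_gaps) mean(gaps$gap) else NA_real_,
    frac_below = if (n_gaps) mean(gaps$gap < threshold_bp) else NA_real_,
    threshold_bp = threshold_bp
  ), class = "gap_stats")
}

#' @export
print.gap_stats <- function(x, ...) {
  cat(sprintf("<gap_stats> %d gaps on %d chromosomes\n",
              nrow(x$gaps), nrow(x$per_chrom)))
  if (is.na(x$mean_gap)) {
    cat("  no adjacent-locus gaps (fewer than 2 loci per chromosome)\n")
  } else {
    cat(sprintf("  mean gap: %.1f bp; %.1f%% of gaps below %d bp\n",
                x$mean_gap, 100 * x$frac_below, x$threshold_bp))
  }
  invisible(x)
}

#' @export
tidy.gap_stats <- function(x, ...) x$gaps

#' @export
glance.gap_stats <- function(x, ...) {
  tibble::tibble(n_gaps = nrow(x$gaps), n_chrom = nrow(x$per_chrom),
                 mean_gap = x$mean_gap, frac_below = x$frac_below,
                 threshold_bp = x$threshold_bp)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
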