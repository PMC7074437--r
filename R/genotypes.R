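#' Construct a genotype matrix
#'
#' The central container of the package: diploid biallelic genotype calls for a
#' panel of plants, stored as alternate-allele dosages (0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternate, `NA` = missing).
#' Every downstream statistic (minor allele frequency, heterozygosity,
#' genetic distance, kinship) is a function of dosage for biallelic diploids,
#' which is why dosages are stored rather than allele-pair strings.
#'
#' @param calls Integer matrix, plants in rows, loci in columns. Entries must
#'   be 0, 1, 2 or `NA`. Row names are taken as plant IDs if `plants` is
#'   missing.
#' @param loci A data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   describing each column of `calls`, in the same order. Loci must be unique
#'   by (chrom, pos).
#' @param plants Character vector of unique plant IDs (one per row of `calls`).
#' @param sort_loci Reorder loci (and the columns of `calls`) into the
#'   canonical order: chromosomes in natural sort order ("chr2" before
#'   "chr10"), then position ascending. Default `TRUE`.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   (the dosage matrix, dimnames plant x locus key) and `loci` (a tibble with
#'   columns `chrom`, `pos`, `ref`, `alt`, `key`).
#' @export
genotype_matrix <- function(calls, loci, plants = rownames(calls),
                            sort_loci = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(plants) && nrow(calls) == 0) plants <- character(0)
  if (is.null(plants)) stop("plant IDs are required (rownames or `plants`)")
  plants <- as.character(plants)
  if (length(plants) != nrow(calls))
    stop("length of `plants` does not match nrow(calls)")
  if (anyDuplicated(plants))
    stop("duplicate plant IDs: ",
         paste(unique(plants[duplicated(plants)]), collapse = ", "))
  loci <- tibble::as_tibble(loci)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(loci)))
    stop("`loci` must have columns chrom, pos, ref, alt")
  if (nrow(loci) != ncol(calls))
    stop("nrow(loci) does not match ncol(calls)")
  if (any(loci$pos < 1)) stop("locus positions must be >= 1")
  if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
  key <- paste(loci$chrom, loci$pos, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate loci: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad)) stop("dosage calls must be 0, 1, 2 or NA")
  loci$key <- key
  if (sort_loci) {
    o <- locus_order(loci$chrom, loci$pos)
    loci <- loci[o, ]
    calls <- calls[, o, drop = FALSE]
  }
  dimnames(calls) <- list(plants, loci$key)
  structure(list(calls = calls, loci = loci), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d plants x %d loci (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  chroms <- unique(x$loci$chrom)
  cat(sprintf("  chromosomes: %d (%s%s)\n", length(chroms),
              paste(utils::head(chroms, 4), collapse = ", "),
              if (length(chroms) > 4) ", ..." else ""))
  invisible(x)
}

#' Plant IDs of a genotype matrix
#' @param x A `geno_matrix`.
#' @return Character vector of plant IDs.
#' @export
plant_ids <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  rownames(x$calls)
}

#' Number of loci / plants
#' @param x A `geno_matrix`.
#' @return Integer count.
#' @export
n_loci <- function(x) ncol(x$calls)

#' @rdname n_loci
#' @export
n_plants <- function(x) nrow(x$calls)

#' Subset a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param plants Plant IDs or row indices to keep (default all).
#' @param loci Locus keys or column indices to keep (default all). Order is
#'   preserved as given, so this can also be used to take bootstrap or
#'   downsampling replicates of loci.
#' @param sort_loci Re-sort loci after subsetting (default `FALSE`: keep the
#'   requested order).
#' @return A `geno_matrix`.
#' @export
subset_genotypes <- function(x, plants = NULL, loci = NULL, sort_loci = FALSE) {
  stopifnot(inherits(x, "geno_matrix"))
  calls <- x$calls
  tab <- x$loci
  if (!is.null(plants)) calls <- calls[plants, , drop = FALSE]
  if (!is.null(loci)) {
    calls <- calls[, loci, drop = FALSE]
    idx <- if (is.character(loci)) match(loci, tab$key) else loci
    tab <- tab[idx, ]
  }
  genotype_matrix(calls, tab, rownames(calls), sort_loci = sort_loci)
}

#' @export
as.matrix.geno_matrix <- function(x, ...) x$calls

# Canonical locus order: natural chromosome sort (trailing integers compared
# numerically, so "chr2" < "chr10"), then position ascending.
locus_order <- function(chrom, pos) {
  prefix <- stringr::str_replace(chrom, "[0-9]+$", "")
  num <- suppressWarnings(as.numeric(stringr::str_extract(chrom, "[0-9]+$")))
  order(prefix, !is.na(num), num, chrom, pos, method = "radix")
}

# TRUE if loci are already in canonical order
loci_sorted <- function(chrom, pos) {
  o <- locus_order(chrom, pos)
  identical(o, seq_along(chrom))
}
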