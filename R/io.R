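#' Read diploid biallelic SNP genotypes from a VCF file
#'
#' Parses GT calls from a VCF 4.x file into a [genotype_matrix()]. Only
#' biallelic SNP records are kept: multiallelic records (comma in ALT) and
#' indels (REF or ALT longer than one base) are skipped with a message, or
#' rejected in strict mode. Phased (`|`) and unphased (`/`) genotype
#' separators are treated identically; `./.` and `.|.` (or any genotype
#' containing a missing allele) become `NA`. Loci are sorted into the
#' canonical (chromosome natural order, position) order on read.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param ploidy_check If `TRUE` (default), a genotype that is not diploid
#'   (e.g. a haploid `0`) raises an error.
#' @param multiallelic Either `"skip"` (default: drop multiallelic/indel
#'   records, reporting the count) or `"error"`.
#' @return A `geno_matrix`. The number of skipped records is attached as
#'   attribute `"n_skipped"`.
#' @export
read_vcf <- function(path, ploidy_check = TRUE,
                     multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (ncol(v@gt) < 2) stop("VCF has no sample columns")
  fmt <- v@gt[, "FORMAT"]
  has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (!all(has_gt)) stop("VCF format error: GT missing from FORMAT field")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt, fixed = TRUE) | nchar(ref) != 1L | nchar(alt) != 1L |
    is.na(alt)
  if (any(bad) && multiallelic == "error")
    stop(sum(bad), " multiallelic or non-SNP record(s) present (strict mode)")
  n_skipped <- sum(bad)
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped, " multiallelic/non-SNP record(s)")
  keep <- !bad
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  key <- paste(chrom, pos, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate locus error: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  dos <- gt_to_dosage(gt, ploidy_check = ploidy_check)
  loci <- tibble::tibble(chrom = chrom, pos = pos,
                         ref = ref[keep], alt = alt[keep])
  out <- genotype_matrix(t(dos), loci, plants = colnames(gt), sort_loci = TRUE)
  attr(out, "n_skipped") <- n_skipped
  out
}

# GT string matrix (loci x samples) -> dosage matrix of the same shape.
# Vectorised through a lookup over the unique GT strings present.
gt_to_dosage <- function(gt, ploidy_check = TRUE) {
  u <- unique(as.vector(gt))
  decode <- function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (ploidy_check && length(alleles) != 2L)
      stop("non-diploid genotype '", g, "'")
    if (any(alleles == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a) || any(a < 0) || any(a > 1))
      stop("unsupported allele code in genotype '", g, "'")
    sum(a)
  }
  lut <- vapply(u, decode, integer(1))
  m <- matrix(lut[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Emits one biallelic SNP record per locus with a GT-only FORMAT column.
#' Dosage 0/1/2 become `0/0`, `0/1`, `1/1`; missing becomes `./.`.
#' `read_vcf(write_vcf(x))` is the identity on plants, loci and dosages.
#' Output is deterministic byte-for-byte, which the pipeline relies on for
#' reproducibility manifests.
#'
#' @param x A `geno_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  if (nrow(x$calls) == 0) stop("cannot write a VCF with no plants")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  calls <- x$calls
  gt <- matrix(gt_code[as.character(calls)], nrow = nrow(calls))
  gt[is.na(calls)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=duskit",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(calls)), collapse = "\t"))
  body <- paste(x$loci$chrom, x$loci$pos, ".", x$loci$ref, x$loci$alt,
                ".", ".", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample sheet mapping plants to declared cultivars
#'
#' @param path TSV file with header columns `plant_id` and `cultivar`.
#' @return A tibble with columns `plant_id`, `cultivar`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    plant_id = readr::col_character(), cultivar = readr::col_character()))
  if (!all(c("plant_id", "cultivar") %in% names(sheet)))
    stop("sample sheet must have columns plant_id and cultivar")
  if (anyDuplicated(sheet$plant_id))
    stop("duplicate plant ID in sample sheet: ",
         paste(unique(sheet$plant_id[duplicated(sheet$plant_id)]),
               collapse = ", "))
  sheet[, c("plant_id", "cultivar")]
}

#' Write a sample sheet
#' @param sheet Tibble with `plant_id`, `cultivar`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(sheet[, c("plant_id", "cultivar")], path)
  invisible(path)
}

#' Read an SSR fragment-size genotype table
#'
#' One row per plant x marker with the two allele fragment sizes in base
#' pairs. The allele pair is unordered: sizes are stored sorted
#' (`allele1_bp <= allele2_bp`), so `210 214` and `214 210` parse
#' identically. `NA` in either size column marks a missing call.
#'
#' @param path TSV with header columns `plant_id`, `marker`, `allele1_bp`,
#'   `allele2_bp` (an optional `chrom` column is carried through).
#' @return A tibble of class `ssr_table`.
#' @export
read_ssr_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    plant_id = readr::col_character(), marker = readr::col_character(),
    .default = readr::col_character()))
  req <- c("plant_id", "marker", "allele1_bp", "allele2_bp")
  if (!all(req %in% names(raw)))
    stop("SSR table must have columns ", paste(req, collapse = ", "))
  parse_size <- function(s) {
    out <- suppressWarnings(as.numeric(s))
    bad <- !is.na(s) & (is.na(out) | out != round(out) | out <= 0)
    if (any(bad))
      stop("malformed SSR allele size: ",
           paste(unique(s[bad]), collapse = ", "))
    as.integer(out)
  }
  a1 <- parse_size(raw$allele1_bp)
  a2 <- parse_size(raw$allele2_bp)
  miss <- is.na(a1) | is.na(a2)
  raw$allele1_bp <- ifelse(miss, NA_integer_, pmin(a1, a2))
  raw$allele2_bp <- ifelse(miss, NA_integer_, pmax(a1, a2))
  if (anyDuplicated(raw[, c("plant_id", "marker")]))
    stop("duplicate plant x marker row in SSR table")
  class(raw) <- c("ssr_table", class(raw))
  raw
}

#' Write an SSR fragment-size table
#' @param x An `ssr_table` (or compatible tibble).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ssr_table <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path)
  invisible(path)
}
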