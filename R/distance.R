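#' Plant-pairwise genetic distance from SNP dosages
#'
#' The default `"allele_sharing"` distance is the dosage p-distance on
#' alleles: `d(i,j) = sum_L |g_i - g_j| / (2 * n_shared(i,j))`, summed over
#' loci called in both plants (pairwise deletion of missing calls). It is 0
#' for identical plants, 1 for opposite homozygotes at every shared locus,
#' and bounded in `[0, 1]`. The alternative `"mismatch"` method is the
#' proportion of shared loci with differing genotype states.
#'
#' A pair of plants with no shared called locus has no defined distance;
#' by default this is an error (a DUS verdict must not rest on silently
#' imputed distances). With `allow_missing_pairs = TRUE` such entries are
#' filled with the mean of the defined off-diagonal distances, with a
#' warning.
#'
#' @param x A `geno_matrix` with at least two plants.
#' @param method `"allele_sharing"` (default) or `"mismatch"`.
#' @param allow_missing_pairs Impute undefined pairs instead of failing.
#' @return An object of class `plant_dist`: list with `d` (symmetric distance
#'   matrix, zero diagonal, plant IDs as dimnames), `n_used` (per-pair count
#'   of shared called loci) and `method`.
#' @export
snp_distance_matrix <- function(x, method = c("allele_sharing", "mismatch"),
                                allow_missing_pairs = FALSE) {
  stopifnot(inherits(x, "geno_matrix"))
  method <- match.arg(method)
  g <- x$calls
  if (nrow(g) < 2) stop("need at least two plants for a distance matrix")
  # dosage-class indicator matrices; missing contributes to none
  a0 <- (!is.na(g) & g == 0) * 1
  a1 <- (!is.na(g) & g == 1) * 1
  a2 <- (!is.na(g) & g == 2) * 1
  called <- a0 + a1 + a2
  n_shared <- called %*% t(called)
  if (method == "allele_sharing") {
    # |gi - gj| summed over shared loci: 1 per hom/het mismatch, 2 per
    # opposite-homozygote mismatch
    numer <- a0 %*% t(a1) + a1 %*% t(a0) +
      a1 %*% t(a2) + a2 %*% t(a1) +
      2 * (a0 %*% t(a2) + a2 %*% t(a0))
    denom <- 2 * n_shared
  } else {
    numer <- n_shared - (a0 %*% t(a0) + a1 %*% t(a1) + a2 %*% t(a2))
    denom <- n_shared
  }
  d <- numer / denom
  finalize_plant_dist(d, n_shared, method, allow_missing_pairs)
}

#' Plant-pairwise shared-allele distance from SSR fragment sizes
#'
#' Per marker, the number of shared alleles `s` between the two (unordered)
#' allele-size pairs is the size of their multiset intersection (0, 1 or 2);
#' the per-marker distance is `1 - s/2`. The plant-pair distance is the mean
#' over markers called in both plants (pairwise deletion).
#'
#' @param tab An `ssr_table` (see [read_ssr_table()]).
#' @param allow_missing_pairs As in [snp_distance_matrix()].
#' @return A `plant_dist` (method `"ssr_shared_allele"`); `n_used` counts
#'   shared markers per pair.
#' @export
ssr_distance_matrix <- function(tab, allow_missing_pairs = FALSE) {
  plants <- unique(tab$plant_id)
  markers <- unique(tab$marker)
  if (length(plants) < 2) stop("need at least two plants for a distance matrix")
  idx <- cbind(match(tab$plant_id, plants), match(tab$marker, markers))
  lo <- hi <- matrix(NA_integer_, length(plants), length(markers),
                     dimnames = list(plants, markers))
  lo[idx] <- tab$allele1_bp
  hi[idx] <- tab$allele2_bp
  n <- length(plants)
  d <- matrix(0, n, n, dimnames = list(plants, plants))
  n_used <- matrix(0L, n, n, dimnames = list(plants, plants))
  for (i in seq_len(n - 1)) {
    ai1 <- lo[i, ]; ai2 <- hi[i, ]
    for (j in (i + 1):n) {
      bj1 <- lo[j, ]; bj2 <- hi[j, ]
      shared <- !is.na(ai1) & !is.na(bj1)
      n_used[i, j] <- n_used[j, i] <- sum(shared)
      if (!any(shared)) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      s <- ifelse(ai1 == bj1 & ai2 == bj2, 2,
                  (ai1 == bj1) | (ai1 == bj2) | (ai2 == bj1) | (ai2 == bj2))
      d[i, j] <- d[j, i] <- mean(1 - s[shared] / 2)
    }
  }
  diag(n_used) <- as.integer(rowSums(!is.na(lo)))
  finalize_plant_dist(d, n_used, "ssr_shared_allele", allow_missing_pairs)
}

finalize_plant_dist <- function(d, n_used, method, allow_missing_pairs) {
  diag(d) <- 0
  off <- d[upper.tri(d)]
  if (anyNA(off)) {
    und <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    pairs <- paste(rownames(d)[und[, 1]], colnames(d)[und[, 2]], sep = " / ")
    if (!allow_missing_pairs)
      stop("undefined distance (no shared called loci) for pair(s): ",
           paste(pairs, collapse = "; "))
    warning("imputing matrix-wide mean distance for ", length(pairs),
            " undefined pair(s)")
    d[is.na(d)] <- mean(off, na.rm = TRUE)
  }
  structure(list(d = d, n_used = n_used, method = method),
            class = "plant_dist")
}

#' @export
print.plant_dist <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("<plant_dist> %d plants, method = %s\n", nrow(x$d), x$method))
  cat(sprintf("  distance range: %.4f - %.4f (mean %.4f)\n",
              min(off), max(off), mean(off)))
  invisible(x)
}

#' @export
as.matrix.plant_dist <- function(x, ...) x$d

#' @importFrom stats as.dist
#' @export
as.dist.plant_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' @export
tidy.plant_dist <- function(x, ...) {
  d <- x$d
  ut <- which(upper.tri(d), arr.ind = TRUE)
  tibble::tibble(plant_a = rownames(d)[ut[, 1]],
                 plant_b = colnames(d)[ut[, 2]],
                 distance = d[ut],
                 n_loci_used = x$n_used[ut])
}

#' Write a square distance matrix as TSV
#' @param x A `plant_dist` or square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(x, path) {
  d <- if (inherits(x, "plant_dist")) x$d else as.matrix(x)
  df <- tibble::as_tibble(d, rownames = "plant_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#' @param x A `plant_dist` or square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(x, path) {
  d <- if (inherits(x, "plant_dist")) x$d else as.matrix(x)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
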