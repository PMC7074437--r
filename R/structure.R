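#' Principal component analysis of genotype dosages
#'
#' Eigendecomposition of the covariance of the column-centered dosage matrix.
#' Missing dosages are mean-imputed per locus before centering (the distance
#' module instead uses pairwise deletion: imputation keeps the matrix dense
#' without inventing genotypes in distance space). Variance-explained
#' fractions are reported over all components and sum to 1. Component signs
#' are fixed deterministically: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param x A `geno_matrix`; plants with no called locus at all are an error.
#' @param k Number of components to return; clipped with a warning if larger
#'   than the number of available components.
#' @return Object of class `dus_pca`: list with `scores` (tibble `plant_id`,
#'   `PC1`, ...), `var_explained` (fractions over all components), `sdev`,
#'   and `k`.
#' @export
pca_genotypes <- function(x, k = 3) {
  stopifnot(inherits(x, "geno_matrix"))
  g <- x$calls
  all_missing_plant <- rowSums(!is.na(g)) == 0
  if (any(all_missing_plant))
    stop("plant(s) with no called locus: ",
         paste(rownames(g)[all_missing_plant], collapse = ", "))
  g <- impute_locus_means(g)
  keep <- apply(g, 2, function(col) any(col != col[1]))
  g <- g[, keep, drop = FALSE]
  if (ncol(g) == 0) stop("no polymorphic loci for PCA")
  p <- stats::prcomp(g, center = TRUE, scale. = FALSE)
  var_frac <- p$sdev^2 / sum(p$sdev^2)
  avail <- sum(p$sdev > p$sdev[1] * 1e-8)
  if (k > avail) {
    warning("k = ", k, " clipped to ", avail, " available component(s)")
    k <- avail
  }
  # deterministic sign: largest-|loading| entry positive per component
  for (c in seq_len(k)) {
    l <- p$rotation[, c]
    if (l[which.max(abs(l))] < 0) {
      p$rotation[, c] <- -l
      p$x[, c] <- -p$x[, c]
    }
  }
  scores <- tibble::as_tibble(p$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(plant_id = rownames(x$calls)),
                             scores)
  structure(list(scores = scores, var_explained = var_frac,
                 sdev = p$sdev, k = k),
            class = "dus_pca")
}

impute_locus_means <- function(g) {
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0 # all-missing locus carries no signal
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  g
}

#' @export
print.dus_pca <- function(x, ...) {
  v <- x$var_explained
  cat(sprintf("<dus_pca> %d plants, %d components kept\n",
              nrow(x$scores), x$k))
  cat(sprintf("  variance explained: PC1 %.1f%%, PC1-2 %.1f%%, PC1-3 %.1f%%\n",
              100 * v[1], 100 * sum(v[seq_len(min(2, length(v)))]),
              100 * sum(v[seq_len(min(3, length(v)))])))
  invisible(x)
}

#' @export
tidy.dus_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"plant_id", names_to = "component",
                      values_to = "score")
}

#' @export
glance.dus_pca <- function(x, ...) {
  v <- x$var_explained
  tibble::tibble(
    n_plants = nrow(x$scores), k = x$k,
    var_pc1 = v[1],
    cum_var_pc2 = sum(v[seq_len(min(2, length(v)))]),
    cum_var_pc3 = sum(v[seq_len(min(3, length(v)))]))
}

#' Genomic relationship (kinship) matrix
#'
#' VanRaden genomic relationship: with `Z` the per-locus mean-centered dosage
#' matrix and `p_l` the alternate-allele frequencies,
#' `K = Z Z' / (2 * sum(p_l (1 - p_l)))`. Missing dosages are mean-imputed
#' per locus (i.e. centered to zero, contributing no relationship signal).
#' Monomorphic loci contribute nothing to the denominator; a panel with only
#' monomorphic loci has an undefined kinship and is an error.
#'
#' @param x A `geno_matrix`.
#' @param method Currently only `"vanraden"`.
#' @return A symmetric plants x plants matrix of class `kinship_matrix` with
#'   the method recorded in attribute `"method"`.
#' @export
kinship_matrix <- function(x, method = "vanraden") {
  stopifnot(inherits(x, "geno_matrix"))
  method <- match.arg(method, "vanraden")
  st <- locus_stats(x)
  p <- st$p_alt
  denom <- 2 * sum(p * (1 - p), na.rm = TRUE)
  if (!is.finite(denom) || denom <= 0)
    stop("kinship undefined: all loci monomorphic or missing")
  g <- impute_locus_means(x$calls)
  Z <- sweep(g, 2, 2 * p, `-`)
  Z[, is.na(p)] <- 0
  K <- (Z %*% t(Z)) / denom
  structure(K, class = c("kinship_matrix", "matrix"), method = method)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d plants, method = %s\n", nrow(x),
              attr(x, "method")))
  cat(sprintf("  diagonal mean %.3f; off-diagonal range %.3f - %.3f\n",
              mean(diag(x)), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' @export
tidy.kinship_matrix <- function(x, ...) {
  m <- unclass(x)
  ut <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(plant_a = rownames(m)[ut[, 1]],
                 plant_b = colnames(m)[ut[, 2]],
                 kinship = m[ut])
}
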