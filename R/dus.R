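#' Per-plant genetic purity
#'
#' Purity is the fraction of a plant's called loci that are homozygous
#' (dosage 0 or 2); heterozygous calls (dosage 1) are impurities and missing
#' calls are excluded from both numerator and denominator. For inbred
#' cultivars propagated by repeated selfing, purity is the molecular
#' uniformity statistic: lines bred through g selfing generations are
#' expected to retain about `0.5^g` of their founder heterozygosity.
#'
#' @param x A `geno_matrix`; every plant must have at least one called locus.
#' @return A tibble: `plant_id`, `n_hom`, `n_het`, `n_missing`, `purity`.
#' @export
plant_purity <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  g <- x$calls
  n_het <- unname(rowSums(g == 1, na.rm = TRUE))
  n_missing <- unname(rowSums(is.na(g)))
  n_hom <- ncol(g) - n_het - n_missing
  called <- n_hom + n_het
  if (any(called == 0))
    stop("plant(s) with zero called loci: ",
         paste(rownames(g)[called == 0], collapse = ", "))
  tibble::tibble(plant_id = rownames(g),
                 n_hom = as.integer(n_hom), n_het = as.integer(n_het),
                 n_missing = as.integer(n_missing),
                 purity = n_hom / called)
}

#' Per-cultivar purity table
#'
#' Aggregates plant purities into the cultivar-level summary used in seed
#' purity certification: mean, minimum, maximum and sample standard
#' deviation, in percent. The purity of a cultivar is the average purity of
#' its plants. A single-plant cultivar gets a standard deviation of 0 and is
#' flagged.
#'
#' @param purities Output of [plant_purity()] (or a tibble with `plant_id`
#'   and `purity`).
#' @param sheet Sample sheet tibble (`plant_id`, `cultivar`); every plant
#'   must be labeled.
#' @return A tibble: `cultivar`, `n_plants`, `purity_pct`, `min_pct`,
#'   `max_pct`, `sd_pct`, `single_plant`.
#' @export
cultivar_purity_table <- function(purities, sheet) {
  joined <- dplyr::inner_join(purities, sheet, by = "plant_id")
  orphans <- setdiff(purities$plant_id, sheet$plant_id)
  if (length(orphans))
    stop("plants missing from sample sheet: ",
         paste(orphans, collapse = ", "))
  empty <- setdiff(unique(sheet$cultivar), unique(joined$cultivar))
  if (length(empty))
    warning("cultivar(s) with zero genotyped plants omitted: ",
            paste(empty, collapse = ", "))
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$cultivar),
    n_plants = dplyr::n(),
    purity_pct = 100 * mean(.data$purity),
    min_pct = 100 * min(.data$purity),
    max_pct = 100 * max(.data$purity),
    sd_pct = if (dplyr::n() > 1) 100 * stats::sd(.data$purity) else 0,
    .groups = "drop")
  dplyr::mutate(out, single_plant = .data$n_plants == 1L)
}

#' Stable heterozygous loci per cultivar and their sharing between cultivars
#'
#' A locus is *stable heterozygous* in a cultivar when every non-missing call
#' among that cultivar's plants is heterozygous and the within-cultivar call
#' rate is at least `min_within_callrate` (tolerant of sporadic missingness,
#' strict on zygosity). Returns the per-cultivar locus sets together with the
#' cultivar x cultivar count matrix: diagonal entries are set sizes,
#' off-diagonal entries are pairwise intersection sizes (never exceeding
#' either diagonal).
#'
#' @param x A `geno_matrix`.
#' @param sheet Sample sheet tibble labelling every plant.
#' @param min_within_callrate Minimum within-cultivar call rate; default 0.8.
#' @return Object of class `het_sharing`: list with `sets` (named list of
#'   locus keys per cultivar) and `counts` (symmetric integer matrix).
#' @export
stable_het_loci <- function(x, sheet, min_within_callrate = 0.8) {
  stopifnot(inherits(x, "geno_matrix"))
  cultivars <- unique(sheet$cultivar)
  sets <- lapply(cultivars, function(cv) {
    plants <- sheet$plant_id[sheet$cultivar == cv]
    plants <- intersect(plants, rownames(x$calls))
    if (!length(plants)) return(character(0))
    g <- x$calls[plants, , drop = FALSE]
    n_called <- colSums(!is.na(g))
    n_het <- colSums(g == 1, na.rm = TRUE)
    ok <- n_called > 0 &
      n_called / length(plants) >= min_within_callrate &
      n_het == n_called
    colnames(g)[ok]
  })
  names(sets) <- cultivars
  k <- length(cultivars)
  counts <- matrix(0L, k, k, dimnames = list(cultivars, cultivars))
  for (i in seq_len(k)) for (j in i:k) {
    counts[i, j] <- counts[j, i] <-
      length(intersect(sets[[i]], sets[[j]]))
  }
  structure(list(sets = sets, counts = counts), class = "het_sharing")
}

#' @export
print.het_sharing <- function(x, ...) {
  cat("<het_sharing> stable heterozygous loci per cultivar\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.het_sharing <- function(x, ...) {
  m <- x$counts
  ut <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(cultivar_a = rownames(m)[ut[, 1]],
                 cultivar_b = colnames(m)[ut[, 2]],
                 n_shared_het_loci = m[ut])
}

#' Classify off-type plants from patristic distances
#'
#' For each plant `p`, `r(p)` is the mean patristic distance from `p` to the
#' other plants carrying the same declared cultivar label. Off-type plants
#' (contaminants or mislabeled seed) sit far outside the within-cultivar
#' distance baseline, so `p` is flagged when both robust rules fire:
#' `r(p) > median + mad_k * MAD` and `r(p) > ratio_alpha * median`, where
#' median and MAD are taken over the cultivar's `r` values. The dual rule is
#' scale-free (invariant to rescaling all distances) and never fires on a
#' homogeneous cultivar where all plants are mutually equidistant. Cultivars
#' with fewer than 3 plants provide no baseline and are skipped with a
#' warning.
#'
#' Cultivar-level distance summaries (max/min/average within-cultivar
#' pairwise patristic distance) are computed excluding flagged plants.
#'
#' @param P Patristic distance matrix (see [patristic()]) or `plant_dist`.
#' @param sheet Sample sheet tibble labelling every plant in `P`.
#' @param mad_k MAD multiplier; default 5.
#' @param ratio_alpha Median-ratio multiplier; default 3.
#' @return Object of class `offtype_report`: list with `plants` (tibble
#'   `plant_id`, `cultivar`, `r`, `cultivar_median`, `cultivar_mad`,
#'   `flagged`) and `cultivars` (tibble `cultivar`, `n_plants`, `n_flagged`,
#'   `d_max`, `d_min`, `d_avg` over non-flagged plants).
#' @export
classify_offtypes <- function(P, sheet, mad_k = 5.0, ratio_alpha = 3.0) {
  if (inherits(P, "plant_dist")) P <- P$d
  P <- as.matrix(P)
  plants <- rownames(P)
  lab <- sheet$cultivar[match(plants, sheet$plant_id)]
  if (anyNA(lab))
    stop("plants missing from sample sheet: ",
         paste(plants[is.na(lab)], collapse = ", "))
  res <- list()
  summaries <- list()
  for (cv in unique(sheet$cultivar)) {
    members <- plants[lab == cv]
    if (length(members) < 3) {
      if (length(members) > 0)
        warning("cultivar '", cv, "' has fewer than 3 plants; off-type ",
                "assessment skipped")
      if (length(members))
        res[[cv]] <- tibble::tibble(plant_id = members, cultivar = cv,
                                    r = NA_real_, cultivar_median = NA_real_,
                                    cultivar_mad = NA_real_, flagged = FALSE)
      next
    }
    sub <- P[members, members, drop = FALSE]
    r <- rowSums(sub) / (length(members) - 1)
    med <- stats::median(r)
    md <- stats::mad(r)
    flagged <- r > med + mad_k * md & r > ratio_alpha * med
    res[[cv]] <- tibble::tibble(plant_id = members, cultivar = cv, r = r,
                                cultivar_median = med, cultivar_mad = md,
                                flagged = flagged)
    clean <- members[!flagged]
    pair <- sub[clean, clean, drop = FALSE][upper.tri(diag(length(clean)))]
    summaries[[cv]] <- tibble::tibble(
      cultivar = cv, n_plants = length(members),
      n_flagged = sum(flagged),
      d_max = if (length(pair)) max(pair) else NA_real_,
      d_min = if (length(pair)) min(pair) else NA_real_,
      d_avg = if (length(pair)) mean(pair) else NA_real_)
  }
  structure(list(plants = dplyr::bind_rows(res),
                 cultivars = dplyr::bind_rows(summaries),
                 mad_k = mad_k, ratio_alpha = ratio_alpha),
            class = "offtype_report")
}

#' @export
print.offtype_report <- function(x, ...) {
  n_fl <- sum(x$plants$flagged, na.rm = TRUE)
  cat(sprintf("<offtype_report> %d plants assessed, %d flagged off-type\n",
              nrow(x$plants), n_fl))
  if (n_fl)
    cat("  flagged:", paste(x$plants$plant_id[which(x$plants$flagged)],
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.offtype_report <- function(x, ...) x$plants

#' @export
glance.offtype_report <- function(x, ...) {
  tibble::tibble(n_plants = nrow(x$plants),
                 n_flagged = sum(x$plants$flagged, na.rm = TRUE),
                 mad_k = x$mad_k, ratio_alpha = x$ratio_alpha)
}

#' Flagged plant IDs of an off-type report
#' @param x An `offtype_report`.
#' @return Character vector of flagged plant IDs.
#' @export
offtype_plants <- function(x) {
  stopifnot(inherits(x, "offtype_report"))
  x$plants$plant_id[which(x$plants$flagged)]
}

#' Tree-based cultivar distinctness check
#'
#' A cultivar is *distinct* when its (non-excluded) plants are exactly one
#' side of some bipartition of the tree, i.e. one edge of the unrooted tree
#' separates precisely that cultivar from everything else. Two cultivars are
#' *separated* when some edge places all plants of one on one side and all
#' plants of the other on the other side. Both reads are scale-free: they
#' depend only on tree topology, matching how DUS examiners read cultivar
#' clusters off a phylogeny. Indistinguishable cultivar pairs (e.g. two
#' selections from the same cross) report as non-separated.
#'
#' @param tree A `phylo` tree over the labeled plants.
#' @param sheet Sample sheet tibble labelling every tip.
#' @param exclude Plants to drop before the check — typically flagged
#'   off-types; an `offtype_report` may be given directly.
#' @return Object of class `distinctness_report`: list with `cultivars`
#'   (tibble `cultivar`, `n_plants_assessed`, `distinct`), `pairs` (tibble
#'   `cultivar_a`, `cultivar_b`, `separated`) and `excluded`.
#' @export
distinctness_check <- function(tree, sheet, exclude = character(0)) {
  stopifnot(inherits(tree, "phylo"))
  if (inherits(exclude, "offtype_report")) exclude <- offtype_plants(exclude)
  miss <- setdiff(tree$tip.label, sheet$plant_id)
  if (length(miss))
    stop("tips missing from sample sheet: ", paste(miss, collapse = ", "))
  drop <- intersect(exclude, tree$tip.label)
  if (length(drop) > 0) tree <- ape::drop.tip(tree, drop)
  tips <- tree$tip.label
  lab <- sheet$cultivar[match(tips, sheet$plant_id)]
  sides <- tip_sides(tree)
  all_set <- sort(tips)
  cultivars <- unique(sheet$cultivar[sheet$plant_id %in% tips])
  sets <- lapply(cultivars, function(cv) sort(tips[lab == cv]))
  names(sets) <- cultivars
  is_side <- function(s) {
    any(vapply(sides, function(side)
      length(side) == length(s) && all(side == s), logical(1))) ||
      any(vapply(sides, function(side) {
        comp <- setdiff(all_set, side)
        length(comp) == length(s) && all(comp == s)
      }, logical(1)))
  }
  distinct <- vapply(sets, is_side, logical(1))
  cult_tbl <- tibble::tibble(cultivar = cultivars,
                             n_plants_assessed = lengths(sets),
                             distinct = distinct)
  pair_rows <- list()
  if (length(cultivars) > 1) {
    cmb <- utils::combn(cultivars, 2)
    sep <- vapply(seq_len(ncol(cmb)), function(q) {
      a <- sets[[cmb[1, q]]]; b <- sets[[cmb[2, q]]]
      any(vapply(sides, function(side) {
        (all(a %in% side) && !any(b %in% side)) ||
          (all(b %in% side) && !any(a %in% side))
      }, logical(1)))
    }, logical(1))
    pair_rows <- tibble::tibble(cultivar_a = cmb[1, ], cultivar_b = cmb[2, ],
                                separated = sep)
  } else {
    pair_rows <- tibble::tibble(cultivar_a = character(),
                                cultivar_b = character(),
                                separated = logical())
  }
  structure(list(cultivars = cult_tbl, pairs = pair_rows, excluded = drop),
            class = "distinctness_report")
}

# every bipartition side induced by an edge (including pendant edges),
# as sorted tip-label sets
tip_sides <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  desc <- descendant_tips(tree)
  lapply(seq_len(nrow(tree$edge)), function(e) {
    sort(tree$tip.label[desc[[tree$edge[e, 2]]]])
  })
}

#' @export
print.distinctness_report <- function(x, ...) {
  cat(sprintf("<distinctness_report> %d cultivars, %d distinct\n",
              nrow(x$cultivars), sum(x$cultivars$distinct)))
  ns <- x$pairs[!x$pairs$separated, , drop = FALSE]
  if (nrow(ns))
    cat("  non-separated pairs:",
        paste(ns$cultivar_a, ns$cultivar_b, sep = "/", collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.distinctness_report <- function(x, ...) x$cultivars

#' Robustness of DUS verdicts under SNP downsampling
#'
#' Emulates a low-marker-density re-analysis: for each subset size and
#' replicate, loci are sampled uniformly without replacement (with a
#' deterministic child seed derived from the master seed), the distance
#' matrix and NJ tree are rebuilt, and the off-type classification and
#' distinctness check are re-run. Used to establish how few SNPs still
#' support the full-panel verdicts.
#'
#' @param x A `geno_matrix`.
#' @param sheet Sample sheet tibble.
#' @param sizes Locus subset sizes; default `c(10000, 5000, 1000, 500)`.
#'   Every size must be `<=` the number of loci.
#' @param replicates Replicates per size; default 3.
#' @param seed Master seed; child seeds for each size x replicate are drawn
#'   deterministically from it and recorded for exact replay.
#' @param mad_k,ratio_alpha Off-type rule parameters, see
#'   [classify_offtypes()].
#' @return Object of class `robustness_report`: list of tibbles `runs`
#'   (size, replicate, child seed, locus subset hash), `cultivars`
#'   (distinct verdict per run), `pairs` (separation per run) and `offtypes`
#'   (flag per plant per run).
#' @export
downsample_robustness <- function(x, sheet,
                                  sizes = c(10000, 5000, 1000, 500),
                                  replicates = 3, seed = 1,
                                  mad_k = 5.0, ratio_alpha = 3.0) {
  stopifnot(inherits(x, "geno_matrix"))
  if (replicates < 1) stop("replicates must be >= 1")
  L <- ncol(x$calls)
  if (any(sizes > L))
    stop("subset size exceeds number of loci (", L, ")")
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), size = sizes)
  grid <- grid[, c("size", "replicate")]
  grid$child_seed <- sample.int(.Machine$integer.max - 1, nrow(grid))
  runs <- list(); cults <- list(); pairs <- list(); offs <- list()
  for (q in seq_len(nrow(grid))) {
    sz <- grid$size[q]; rep_i <- grid$replicate[q]
    set.seed(grid$child_seed[q])
    idx <- sort(sample.int(L, sz))
    sub <- subset_genotypes(x, loci = idx)
    D <- snp_distance_matrix(sub)
    tree <- nj_tree(D)
    P <- patristic(tree)
    ot <- suppressWarnings(classify_offtypes(P, sheet, mad_k = mad_k,
                                             ratio_alpha = ratio_alpha))
    dc <- distinctness_check(tree, sheet, exclude = ot)
    runs[[q]] <- tibble::tibble(size = sz, replicate = rep_i,
                                child_seed = grid$child_seed[q],
                                locus_hash = subset_hash(idx))
    cults[[q]] <- dplyr::mutate(dc$cultivars, size = sz, replicate = rep_i,
                                .before = 1)
    pairs[[q]] <- dplyr::mutate(dc$pairs, size = sz, replicate = rep_i,
                                .before = 1)
    offs[[q]] <- dplyr::mutate(
      ot$plants[, c("plant_id", "cultivar", "flagged")],
      size = sz, replicate = rep_i, .before = 1)
  }
  structure(list(runs = dplyr::bind_rows(runs),
                 cultivars = dplyr::bind_rows(cults),
                 pairs = dplyr::bind_rows(pairs),
                 offtypes = dplyr::bind_rows(offs),
                 seed = seed),
            class = "robustness_report")
}

# order-insensitive deterministic hash of a locus index subset
subset_hash <- function(idx) {
  idx <- sort(idx)
  h <- sum((idx %% 65521) * (seq_along(idx) %% 65521)) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %d runs (sizes: %s)\n",
              nrow(x$runs), paste(unique(x$runs$size), collapse = ", ")))
  agg <- dplyr::summarise(dplyr::group_by(x$cultivars, .data$size),
                          prop_distinct = mean(.data$distinct),
                          .groups = "drop")
  print(as.data.frame(agg))
  invisible(x)
}

#' @export
tidy.robustness_report <- function(x, ...) x$cultivars
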