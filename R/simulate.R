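#' Simulation configuration for a synthetic cultivar trial
#'
#' Describes a panel of inbred cultivars, each derived from a biparental
#' cross followed by `selfing_generations` rounds of single-seed descent,
#' genotyped at SNP loci scattered over a set of chromosomes. The default
#' configuration mirrors a five-cultivar DUS trial: 20 plants per cultivar;
#' one cultivar pair bred from the identical founder cross (and therefore
#' genetically indistinguishable — the classic "same variety under two
#' names" situation); one cultivar whose genetic core is derived from
#' another's (a close parent-offspring-like pair that must still separate);
#' two off-type plants injected from distant cultivars; light missingness
#' and genotyping error.
#'
#' Founder genomes are built by random allele flips: each cultivar core
#' diverges from a common ancestor at rate `core_divergence` (so two
#' unrelated cores differ at about `2q(1-q)` of loci), the derived core
#' diverges from its sibling core at `sibling_core_divergence`, and the two
#' parents of each cross each diverge from their cultivar core at
#' `parent_divergence` (so the founder pair differs at about
#' `2 * parent_divergence` of loci, which bounds the cross's segregating
#' heterozygosity).
#'
#' @param n_loci Number of SNP loci; default 2000.
#' @param n_chromosomes Number of chromosomes; default 20.
#' @param chrom_length Chromosome length in bp; default 5e7.
#' @param cultivars Cultivar names; default `cv1`..`cv5`.
#' @param plants_per_cultivar Plants sampled per cultivar; default 20.
#' @param selfing_generations Selfing generations g after the cross;
#'   default 6 (released inbred lines are bred through at least six
#'   selfings, putting expected residual heterozygosity at `0.5^6` of the
#'   founder-differing loci).
#' @param core_divergence Ancestor-to-core flip rate; default 0.18.
#' @param parent_divergence Core-to-parent flip rate; default 0.02.
#' @param sibling_core_divergence Flip rate between the derived core and its
#'   sibling; default 0.15.
#' @param shared_cross_pair Indices into `cultivars` of the pair bred from
#'   the identical founder cross; `NULL` for none. Default `c(1, 2)`.
#' @param derived_core_pair Indices of the (source, derived) core pair;
#'   `NULL` for none. Default `c(3, 4)`.
#' @param n_stable_het Number of pinned stable-heterozygous loci per
#'   cultivar; default 8.
#' @param offtypes Tibble with columns `host`, `donor`, `k`: inject `k`
#'   plants drawn from the donor cultivar into the host cultivar (relabeled
#'   as host). Default: one off-type each into the first two cultivars.
#' @param missing_rate Per-call missing probability; default 0.02.
#' @param error_rate Per-call genotyping error probability; default 0.002.
#' @param seed Master seed; every stage seed is derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 2000, n_chromosomes = 20, chrom_length = 5e7,
                       cultivars = paste0("cv", 1:5),
                       plants_per_cultivar = 20,
                       selfing_generations = 6,
                       core_divergence = 0.18,
                       parent_divergence = 0.02,
                       sibling_core_divergence = 0.15,
                       shared_cross_pair = c(1, 2),
                       derived_core_pair = c(3, 4),
                       n_stable_het = 8,
                       offtypes = NULL,
                       missing_rate = 0.02,
                       error_rate = 0.002,
                       seed = 1) {
  rates <- c(core_divergence, parent_divergence, sibling_core_divergence,
             missing_rate, error_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (selfing_generations < 0) stop("selfing_generations must be >= 0")
  k <- length(cultivars)
  if (!is.null(shared_cross_pair) && any(shared_cross_pair > k))
    shared_cross_pair <- NULL
  if (!is.null(derived_core_pair) && any(derived_core_pair > k))
    derived_core_pair <- NULL
  if (is.null(offtypes)) {
    offtypes <- if (k >= 5) {
      tibble::tibble(host = cultivars[c(1, 2)],
                     donor = cultivars[c(5, 3)], k = c(1L, 1L))
    } else {
      tibble::tibble(host = character(), donor = character(), k = integer())
    }
  }
  structure(list(
    n_loci = n_loci, n_chromosomes = n_chromosomes,
    chrom_length = chrom_length, cultivars = cultivars,
    plants_per_cultivar = plants_per_cultivar,
    selfing_generations = selfing_generations,
    core_divergence = core_divergence,
    parent_divergence = parent_divergence,
    sibling_core_divergence = sibling_core_divergence,
    shared_cross_pair = shared_cross_pair,
    derived_core_pair = derived_core_pair,
    n_stable_het = n_stable_het, offtypes = offtypes,
    missing_rate = missing_rate, error_rate = error_rate, seed = seed
  ), class = "sim_config")
}

#' Flip alleles of a homozygous founder genome
#'
#' Elementary founder-divergence primitive: each locus of the 0/1 allele
#' vector is flipped independently with probability `divergence`, so the
#' realized differing fraction is binomial around `divergence`. Divergence 0
#' returns an identical genome; divergence 1 the full complement.
#'
#' @param genome Integer vector of 0/1 founder alleles.
#' @param divergence Per-locus flip probability in `[0, 1]`.
#' @return Integer 0/1 vector of the same length. Uses the current RNG
#'   stream (call [set.seed()] for reproducibility).
#' @export
diverge_genome <- function(genome, divergence) {
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  flip <- stats::runif(length(genome)) < divergence
  out <- genome
  out[flip] <- 1L - out[flip]
  out
}

#' Simulate founder genomes and the locus panel
#'
#' Places `n_loci` SNPs uniformly (without positional collision) on the
#' configured chromosomes and builds fully homozygous founder genomes for
#' every cultivar cross according to the core/parent divergence model of
#' [sim_config()].
#'
#' @param config A `sim_config`.
#' @param seed Seed (defaults to the config's master seed).
#' @return A list with `loci` (tibble `chrom`, `pos`, `ref`, `alt`),
#'   `founders` (named list of 0/1 allele vectors) and `founder_pairs`
#'   (named list: cultivar -> the two founder names of its cross).
#' @export
simulate_founders <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  loci <- simulate_loci(config)
  k <- length(config$cultivars)
  ancestor <- integer(config$n_loci)
  # one core per cultivar; the shared-cross pair shares one, the derived
  # core is a flip of its sibling
  core_of <- seq_len(k)
  if (!is.null(config$shared_cross_pair))
    core_of[config$shared_cross_pair[2]] <- config$shared_cross_pair[1]
  cores <- vector("list", k)
  for (i in seq_len(k)) {
    if (core_of[i] != i) next
    if (!is.null(config$derived_core_pair) && i == config$derived_core_pair[2]) {
      src <- config$derived_core_pair[1]
      cores[[i]] <- diverge_genome(cores[[src]],
                                   config$sibling_core_divergence)
    } else {
      cores[[i]] <- diverge_genome(ancestor, config$core_divergence)
    }
  }
  founders <- list()
  founder_pairs <- list()
  for (i in seq_len(k)) {
    cv <- config$cultivars[i]
    if (core_of[i] != i) { # identical founder cross as its partner
      founder_pairs[[cv]] <- founder_pairs[[config$cultivars[core_of[i]]]]
      next
    }
    pa <- paste0(cv, "_a"); pb <- paste0(cv, "_b")
    founders[[pa]] <- diverge_genome(cores[[i]], config$parent_divergence)
    founders[[pb]] <- diverge_genome(cores[[i]], config$parent_divergence)
    founder_pairs[[cv]] <- c(pa, pb)
  }
  list(loci = loci, founders = founders, founder_pairs = founder_pairs)
}

simulate_loci <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom <- sample(chroms, config$n_loci, replace = TRUE)
  pos <- integer(config$n_loci)
  for (c in chroms) {
    i <- chrom == c
    pos[i] <- sort(sample.int(config$chrom_length, sum(i)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, config$n_loci, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  loci <- tibble::tibble(chrom = chrom, pos = pos, ref = ref,
                         alt = unname(alt))
  loci[locus_order(loci$chrom, loci$pos), ]
}

#' Simulate one cultivar population by single-seed descent
#'
#' The F1 of the founder cross is heterozygous exactly at founder-differing
#' loci. Each plant is an independent single-seed-descent lineage: after g
#' selfing generations a segregating locus is still heterozygous with
#' probability `0.5^g` and otherwise fixed for either parental homozygote
#' with equal probability (homozygous loci are absorbing). The g-step
#' marginal is sampled in closed form, which is distributionally exact for
#' independent lineages and loci. Loci in `stable_het_idx` are pinned
#' heterozygous in every plant — a phenomenological stand-in for loci under
#' balancing maintenance that stay heterozygous in released lines.
#'
#' @param founder_a,founder_b 0/1 allele vectors of the two (homozygous)
#'   parents.
#' @param g Number of selfing generations (>= 0).
#' @param n_plants Number of independent lineages to draw.
#' @param stable_het_idx Locus indices pinned heterozygous; must be a subset
#'   of the founder-differing loci.
#' @param seed RNG seed.
#' @param plant_ids Optional plant names (default `plant1`..).
#' @return A list of class `sim_population`: `calls` (dosage matrix, no
#'   missingness), `plant_ids`, `diff_idx` (founder-differing loci),
#'   `stable_het_idx`, `g`.
#' @export
simulate_cultivar_population <- function(founder_a, founder_b, g, n_plants,
                                         stable_het_idx = integer(0),
                                         seed = 1, plant_ids = NULL) {
  if (length(founder_a) != length(founder_b))
    stop("founder genomes differ in length")
  if (!all(founder_a %in% 0:1) || !all(founder_b %in% 0:1))
    stop("founders must be homozygous 0/1 allele vectors")
  diff_idx <- which(founder_a != founder_b)
  if (!all(stable_het_idx %in% diff_idx))
    stop("stable_het_idx must be a subset of founder-differing loci")
  if (is.null(plant_ids)) plant_ids <- paste0("plant", seq_len(n_plants))
  L <- length(founder_a)
  set.seed(seed)
  base <- 2L * founder_a # correct wherever founders agree
  calls <- matrix(rep(base, each = n_plants), nrow = n_plants,
                  dimnames = list(plant_ids, NULL))
  seg <- setdiff(diff_idx, stable_het_idx)
  if (length(seg)) {
    p_het <- 0.5^g
    u <- matrix(stats::runif(n_plants * length(seg)), nrow = n_plants)
    state <- matrix(1L, n_plants, length(seg)) # het
    fix_a <- u >= p_het & u < p_het + (1 - p_het) / 2
    fix_b <- u >= p_het + (1 - p_het) / 2
    a_dos <- matrix(rep(2L * founder_a[seg], each = n_plants), nrow = n_plants)
    b_dos <- matrix(rep(2L * founder_b[seg], each = n_plants), nrow = n_plants)
    state[fix_a] <- a_dos[fix_a]
    state[fix_b] <- b_dos[fix_b]
    calls[, seg] <- state
  }
  if (length(stable_het_idx)) calls[, stable_het_idx] <- 1L
  structure(list(calls = calls, plant_ids = plant_ids, diff_idx = diff_idx,
                 stable_het_idx = stable_het_idx, g = g),
            class = "sim_population")
}

#' Inject off-type plants from a donor population
#'
#' Replaces `k` randomly chosen host plants with plants drawn (without
#' replacement) from a donor cultivar's population. The replacements keep
#' the host plant IDs — they are contaminant seed carrying the host label —
#' and are recorded in the returned truth table.
#'
#' @param population Host `sim_population`.
#' @param donor Donor `sim_population` (must not be the host object itself).
#' @param k Number of plants to replace; must satisfy `0 <= k < n_plants`
#'   (replacing every host plant leaves no baseline and is an error).
#' @param seed RNG seed.
#' @return The host `sim_population` with an added/updated `offtype` tibble
#'   (`plant_id`, `donor_plant`).
#' @export
inject_offtypes <- function(population, donor, k, seed = 1) {
  stopifnot(inherits(population, "sim_population"),
            inherits(donor, "sim_population"))
  if (identical(population, donor))
    stop("donor population must differ from the host population")
  n <- nrow(population$calls)
  if (k >= n) stop("k must leave at least one host plant (k < ", n, ")")
  if (k == 0) return(population)
  set.seed(seed)
  victims <- sample.int(n, k)
  donors <- sample.int(nrow(donor$calls), k)
  population$calls[victims, ] <- donor$calls[donors, , drop = FALSE]
  off <- tibble::tibble(plant_id = population$plant_ids[victims],
                        donor_plant = donor$plant_ids[donors])
  population$offtype <- dplyr::bind_rows(population$offtype, off)
  population
}

#' Apply missingness and genotyping error to dosage calls
#'
#' Each call is independently set missing with probability `missing_rate`;
#' each surviving call is perturbed with probability `error_rate` — a
#' homozygote becomes heterozygous, a heterozygote becomes a random
#' homozygote (the two dominant error modes of reduced-representation
#' genotype calling).
#'
#' @param x A dosage matrix, `geno_matrix` or `sim_population`.
#' @param missing_rate,error_rate Probabilities in `[0, 1]`.
#' @param seed RNG seed.
#' @return Same type as `x`, with noisy calls.
#' @export
apply_noise <- function(x, missing_rate = 0, error_rate = 0, seed = 1) {
  if (any(c(missing_rate, error_rate) < 0 | c(missing_rate, error_rate) > 1))
    stop("rates must lie in [0, 1]")
  if (inherits(x, "geno_matrix")) {
    x$calls <- apply_noise(x$calls, missing_rate, error_rate, seed)
    return(x)
  }
  if (inherits(x, "sim_population")) {
    x$calls <- apply_noise(x$calls, missing_rate, error_rate, seed)
    return(x)
  }
  g <- x
  set.seed(seed)
  n <- length(g)
  miss <- stats::runif(n) < missing_rate
  err <- !miss & stats::runif(n) < error_rate
  if (any(err)) {
    e <- which(err)
    hom <- !is.na(g[e]) & g[e] != 1L
    g[e][hom] <- 1L
    het <- !is.na(g[e]) & !hom
    g[e][het] <- 2L * (stats::runif(sum(het)) < 0.5)
  }
  g[miss] <- NA_integer_
  g
}

#' Simulate an SSR marker panel for the configured trial
#'
#' Each cultivar core carries one homozygous fragment-size allele per
#' marker; plants of a cultivar are identical up to missingness, and
#' cultivars bred from the same cross share every allele. At least one
#' marker is placed on each chromosome.
#'
#' @param config A `sim_config`.
#' @param n_markers Number of SSR markers (default 42); must be at least
#'   `n_chromosomes`.
#' @param seed RNG seed.
#' @param truth Optional truth tibble (`plant_id`, `true_cultivar`) from
#'   [simulate_experiment()]; off-type plants then carry their true
#'   cultivar's alleles. When `NULL` a clean design is generated.
#' @return An `ssr_table` tibble (`plant_id`, `marker`, `chrom`,
#'   `allele1_bp`, `allele2_bp`).
#' @export
simulate_ssr_panel <- function(config, n_markers = 42, seed = config$seed,
                               truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_markers < config$n_chromosomes)
    stop("n_markers must be >= n_chromosomes")
  set.seed(seed)
  k <- length(config$cultivars)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  marker <- sprintf("SSR%03d", seq_len(n_markers))
  chrom <- c(chroms, sample(chroms, n_markers - length(chroms),
                            replace = TRUE))
  core_of <- seq_len(k)
  if (!is.null(config$shared_cross_pair))
    core_of[config$shared_cross_pair[2]] <- config$shared_cross_pair[1]
  # per marker: distinct allele sizes for distinct cores
  allele <- matrix(0L, k, n_markers,
                   dimnames = list(config$cultivars, marker))
  for (m in seq_len(n_markers)) {
    base <- sample(120:280, 1)
    pool <- base + 2L * sample.int(20, k)
    allele[, m] <- pool[core_of]
  }
  if (is.null(truth)) {
    truth <- tibble::tibble(
      plant_id = unlist(lapply(config$cultivars, function(cv)
        paste0(cv, "-", seq_len(config$plants_per_cultivar)))),
      true_cultivar = rep(config$cultivars,
                          each = config$plants_per_cultivar))
  }
  tab <- tidyr::expand_grid(plant_id = truth$plant_id, marker = marker)
  tab$chrom <- chrom[match(tab$marker, marker)]
  cv_idx <- match(truth$true_cultivar[match(tab$plant_id, truth$plant_id)],
                  config$cultivars)
  size <- allele[cbind(cv_idx, match(tab$marker, marker))]
  miss <- stats::runif(nrow(tab)) < config$missing_rate
  tab$allele1_bp <- ifelse(miss, NA_integer_, size)
  tab$allele2_bp <- ifelse(miss, NA_integer_, size)
  class(tab) <- c("ssr_table", class(tab))
  tab
}

#' Simulate a complete synthetic DUS trial
#'
#' Runs the whole generator: founder genomes, one single-seed-descent
#' population per cultivar (with pinned stable-heterozygous loci), off-type
#' injection, missingness/error noise, and an SSR panel consistent with the
#' truth. All stage seeds derive from the config's master seed, so the same
#' config reproduces the experiment byte for byte.
#'
#' @param config A `sim_config`.
#' @param out_dir If non-`NULL`, write `genotypes.vcf`, `samples.tsv`,
#'   `ssr.tsv`, `truth_plants.tsv`, `truth_calls.tsv` and
#'   `truth_stable_het.tsv` into this directory.
#' @return Object of class `dus_experiment`: list with `genotypes`
#'   (`geno_matrix` with noise applied), `sheet` (declared labels), `ssr`
#'   (`ssr_table`) and `truth` (list: `plants` tibble with `plant_id`,
#'   `cultivar`, `true_cultivar`, `off_type`; `calls` pre-noise dosage
#'   matrix; `stable_het` named list of locus keys per cultivar).
#' @export
simulate_experiment <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_stage <- 4 + 3 * length(config$cultivars) + nrow(config$offtypes)
  stage_seed <- sample.int(.Machine$integer.max - 1, n_stage)
  s <- 0L
  next_seed <- function() {
    s <<- s + 1L
    stage_seed[s]
  }
  fnd <- simulate_founders(config, seed = next_seed())
  k <- length(config$cultivars)
  pops <- list()
  stable_sets <- list()
  for (i in seq_len(k)) {
    cv <- config$cultivars[i]
    pair <- fnd$founder_pairs[[cv]]
    fa <- fnd$founders[[pair[1]]]
    fb <- fnd$founders[[pair[2]]]
    diff_idx <- which(fa != fb)
    set.seed(next_seed())
    n_pin <- min(config$n_stable_het, length(diff_idx))
    pin <- sort(sample(diff_idx, n_pin))
    # a cultivar pair bred from the identical cross with zero post-cross
    # divergence is one line under two names: same stable-het loci too
    if (!is.null(config$shared_cross_pair) &&
        i == config$shared_cross_pair[2])
      pin <- stable_sets[[config$cultivars[config$shared_cross_pair[1]]]]
    stable_sets[[cv]] <- pin
    pops[[cv]] <- simulate_cultivar_population(
      fa, fb, config$selfing_generations, config$plants_per_cultivar,
      stable_het_idx = pin, seed = next_seed(),
      plant_ids = paste0(cv, "-", seq_len(config$plants_per_cultivar)))
    next_seed() # reserve one slot per cultivar for future stages
  }
  off_truth <- list()
  if (nrow(config$offtypes)) {
    for (q in seq_len(nrow(config$offtypes))) {
      host <- config$offtypes$host[q]
      donor <- config$offtypes$donor[q]
      pops[[host]] <- inject_offtypes(pops[[host]], pops[[donor]],
                                      config$offtypes$k[q],
                                      seed = next_seed())
      off_truth[[q]] <- tibble::tibble(
        plant_id = utils::tail(pops[[host]]$offtype$plant_id,
                               config$offtypes$k[q]),
        true_cultivar = donor)
    }
  }
  off_truth <- dplyr::bind_rows(off_truth)
  calls <- do.call(rbind, lapply(pops, `[[`, "calls"))
  declared <- rep(config$cultivars,
                  times = vapply(pops, function(p) nrow(p$calls), integer(1)))
  truth_plants <- tibble::tibble(
    plant_id = rownames(calls), cultivar = declared,
    true_cultivar = declared, off_type = FALSE)
  if (nrow(off_truth)) {
    hit <- match(off_truth$plant_id, truth_plants$plant_id)
    truth_plants$true_cultivar[hit] <- off_truth$true_cultivar
    truth_plants$off_type[hit] <- TRUE
  }
  noisy <- apply_noise(calls, config$missing_rate, config$error_rate,
                       seed = next_seed())
  geno <- genotype_matrix(noisy, fnd$loci, plants = rownames(calls),
                          sort_loci = FALSE)
  sheet <- truth_plants[, c("plant_id", "cultivar")]
  ssr <- simulate_ssr_panel(config, seed = next_seed(),
                            truth = truth_plants[, c("plant_id",
                                                     "true_cultivar")])
  stable_keys <- lapply(stable_sets, function(ix) geno$loci$key[ix])
  out <- structure(list(
    genotypes = geno, sheet = sheet, ssr = ssr,
    truth = list(plants = truth_plants,
                 calls = calls,
                 stable_het = stable_keys),
    config = config), class = "dus_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' Write a simulated experiment to plain-text files
#'
#' @param x A `dus_experiment`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_experiment <- function(x, out_dir) {
  stopifnot(inherits(x, "dus_experiment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(x$genotypes, file.path(out_dir, "genotypes.vcf"))
  write_sample_sheet(x$sheet, file.path(out_dir, "samples.tsv"))
  write_ssr_table(x$ssr, file.path(out_dir, "ssr.tsv"))
  readr::write_tsv(x$truth$plants, file.path(out_dir, "truth_plants.tsv"))
  calls <- x$truth$calls
  colnames(calls) <- x$genotypes$loci$key
  tc <- tibble::as_tibble(calls, rownames = "plant_id")
  readr::write_tsv(tc, file.path(out_dir, "truth_calls.tsv"))
  sh <- tibble::tibble(
    cultivar = rep(names(x$truth$stable_het),
                   lengths(x$truth$stable_het)),
    locus = unlist(x$truth$stable_het, use.names = FALSE))
  readr::write_tsv(sh, file.path(out_dir, "truth_stable_het.tsv"))
  invisible(out_dir)
}

#' @export
print.dus_experiment <- function(x, ...) {
  cat(sprintf("<dus_experiment> %d plants, %d loci, %d cultivars, %d off-type(s)\n",
              nrow(x$genotypes$calls), ncol(x$genotypes$calls),
              length(unique(x$sheet$cultivar)),
              sum(x$truth$plants$off_type)))
  invisible(x)
}
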