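#' Run the full molecular DUS pipeline
#'
#' Chains every stage on a VCF + sample sheet: marker filtering, gap
#' statistics, allele-sharing distances, NJ tree (optionally with bootstrap
#' support), patristic distances, off-type classification, distinctness
#' check, purity tables, stable-heterozygous-locus sharing, PCA, kinship and
#' (optionally) the downsampling robustness study. All reports are written
#' as TSV into `out_dir` together with a JSON summary and, last, a
#' reproducibility manifest recording the tool version, input hashes, every
#' threshold and seed, per-stage record counts and output hashes. Given
#' identical inputs and config the output files are byte-identical.
#'
#' @param vcf Path to the genotype VCF.
#' @param samples Path to the sample sheet TSV (`plant_id`, `cultivar`).
#' @param out_dir Output directory (created if needed).
#' @param maf_min,integrity_min Marker filter thresholds (see
#'   [filter_markers()]).
#' @param gap_threshold_bp Gap summary threshold (see [gap_stats()]).
#' @param mad_k,ratio_alpha Off-type rule parameters (see
#'   [classify_offtypes()]).
#' @param bootstrap Bootstrap replicates for tree support; 0 (default)
#'   skips bootstrapping.
#' @param sizes Locus subset sizes for [downsample_robustness()]; `NULL`
#'   (default) skips the robustness study.
#' @param replicates Robustness replicates per size.
#' @param pca_k Number of principal components to report.
#' @param seed Master seed for all seeded stages.
#' @return Invisibly, a list with every stage result plus `manifest`.
#' @export
run_dus_pipeline <- function(vcf, samples, out_dir,
                             maf_min = 0.05, integrity_min = 0.8,
                             gap_threshold_bp = 150000,
                             mad_k = 5.0, ratio_alpha = 3.0,
                             bootstrap = 0, sizes = NULL, replicates = 3,
                             pca_k = 3, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("duskit: ", ...)

  log_stage("reading inputs")
  geno <- read_vcf(vcf)
  sheet <- read_sample_sheet(samples)
  only_vcf <- setdiff(plant_ids(geno), sheet$plant_id)
  only_sheet <- setdiff(sheet$plant_id, plant_ids(geno))
  if (length(only_vcf) || length(only_sheet))
    stop("plant sets of VCF and sample sheet differ; ",
         "only in VCF: [", paste(only_vcf, collapse = ", "),
         "]; only in sheet: [", paste(only_sheet, collapse = ", "), "]")

  log_stage("filtering markers")
  filt <- filter_markers(geno, maf_min = maf_min,
                         integrity_min = integrity_min)
  readr::write_tsv(filter_report(filt), file.path(out_dir, "filter_report.tsv"))
  gaps <- gap_stats(filt, threshold_bp = gap_threshold_bp)
  readr::write_tsv(glance(gaps), file.path(out_dir, "gap_stats.tsv"))
  readr::write_tsv(gaps$per_chrom, file.path(out_dir, "loci_per_chrom.tsv"))

  log_stage("distance matrix and NJ tree")
  D <- snp_distance_matrix(filt)
  write_distance_tsv(D, file.path(out_dir, "distance.tsv"))
  tree <- if (bootstrap > 0) {
    bootstrap_support(filt, replicates = bootstrap, seed = seed)
  } else {
    nj_tree(D)
  }
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  P <- patristic(tree, plants = plant_ids(filt))
  write_distance_tsv(P, file.path(out_dir, "patristic.tsv"))

  log_stage("off-type classification and distinctness")
  offtypes <- classify_offtypes(P, sheet, mad_k = mad_k,
                                ratio_alpha = ratio_alpha)
  readr::write_tsv(offtypes$plants, file.path(out_dir, "offtypes.tsv"))
  readr::write_tsv(offtypes$cultivars,
                   file.path(out_dir, "within_cultivar_distances.tsv"))
  distinct <- distinctness_check(tree, sheet, exclude = offtypes)
  readr::write_tsv(distinct$cultivars, file.path(out_dir, "distinctness.tsv"))
  readr::write_tsv(distinct$pairs,
                   file.path(out_dir, "cultivar_separation.tsv"))

  log_stage("purity and heterozygosity")
  purities <- plant_purity(filt)
  readr::write_tsv(purities, file.path(out_dir, "purity_plants.tsv"))
  purity_tbl <- cultivar_purity_table(purities, sheet)
  readr::write_tsv(purity_tbl, file.path(out_dir, "purity_cultivars.tsv"))
  hets <- stable_het_loci(filt, sheet)
  readr::write_tsv(tidy(hets), file.path(out_dir, "het_sharing.tsv"))

  log_stage("PCA and kinship")
  pca <- pca_genotypes(filt, k = pca_k)
  readr::write_tsv(pca$scores, file.path(out_dir, "pca_scores.tsv"))
  readr::write_tsv(
    tibble::tibble(component = paste0("PC", seq_along(pca$var_explained)),
                   var_explained = pca$var_explained),
    file.path(out_dir, "pca_variance.tsv"))
  kin <- kinship_matrix(filt)
  write_distance_tsv(unclass(kin), file.path(out_dir, "kinship.tsv"))

  robustness <- NULL
  if (!is.null(sizes)) {
    log_stage("downsampling robustness")
    robustness <- downsample_robustness(filt, sheet, sizes = sizes,
                                        replicates = replicates, seed = seed,
                                        mad_k = mad_k,
                                        ratio_alpha = ratio_alpha)
    readr::write_tsv(robustness$cultivars,
                     file.path(out_dir, "robustness_distinctness.tsv"))
    readr::write_tsv(robustness$pairs,
                     file.path(out_dir, "robustness_separation.tsv"))
    readr::write_tsv(robustness$offtypes,
                     file.path(out_dir, "robustness_offtypes.tsv"))
    readr::write_tsv(robustness$runs, file.path(out_dir, "robustness_runs.tsv"))
  }

  summary <- list(
    n_plants = n_plants(geno),
    n_loci_input = n_loci(geno),
    n_loci_retained = n_loci(filt),
    mean_gap_bp = gaps$mean_gap,
    frac_gaps_below_threshold = gaps$frac_below,
    cultivar_purity = purity_tbl,
    offtype_flagged = offtype_plants(offtypes),
    n_distinct_cultivars = sum(distinct$cultivars$distinct),
    non_separated_pairs = distinct$pairs[!distinct$pairs$separated, ],
    pca_var_explained = pca$var_explained[seq_len(pca$k)])
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  params <- list(maf_min = maf_min, integrity_min = integrity_min,
                 gap_threshold_bp = gap_threshold_bp, mad_k = mad_k,
                 ratio_alpha = ratio_alpha, bootstrap = bootstrap,
                 sizes = sizes, replicates = replicates, pca_k = pca_k,
                 seed = seed)
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    tool = "duskit",
    version = as.character(utils::packageVersion("duskit")),
    inputs = as.list(tools::md5sum(c(vcf = vcf, samples = samples))),
    parameters = params,
    counts = list(n_plants = n_plants(geno),
                  n_loci_input = n_loci(geno),
                  n_loci_retained = n_loci(filt),
                  n_offtypes_flagged = length(offtype_plants(offtypes))),
    outputs = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done; manifest written")

  invisible(list(genotypes = filt, sheet = sheet, gaps = gaps, distance = D,
                 tree = tree, patristic = P, offtypes = offtypes,
                 distinctness = distinct, purity_plants = purities,
                 purity_cultivars = purity_tbl, het_sharing = hets,
                 pca = pca, kinship = kin, robustness = robustness,
                 manifest = manifest))
}
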