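#' Configuration for the synthetic methylome simulator
#'
#' Bundles every tunable of the multi-generation bisulfite simulator into a
#' validated list. The defaults emulate a compact plant-like genome:
#' gene-dense chromosome arms flanking a TE-dense pericentromere, a subset of
#' genes carrying CG-only gene-body methylation (gbM) with a mid-body dome,
#' TEs methylated in all three contexts, and ectopic CG-only gains biased
#' toward gene bodies and less accessible chromatin that are inherited
#' region-wise across generations with retention probability `retention_rate_r`.
#'
#' @param seed Integer seed controlling every stochastic step.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp. Should be a
#'   multiple of `bin_size` so the analysis grid tiles it exactly.
#' @param pericentromere_fraction Fraction (0,1) of each chromosome, centred,
#'   treated as pericentromeric heterochromatin: TEs are placed there and
#'   accessibility is low.
#' @param n_genes,n_tes Number of gene / transposable-element annotations.
#' @param gene_length_range Length-2 integer vector, uniform range of gene
#'   lengths in bp.
#' @param te_length_range Length-2 integer vector, TE lengths in bp.
#' @param fraction_gbm_genes Fraction of genes carrying gene-body CG
#'   methylation.
#' @param gbm_body_cg_level Mean true CG methylation probability over a gbM
#'   gene body (the dome shape is scaled so its body-wide mean equals this).
#' @param te_levels Named numeric vector `c(CG=, CHG=, CHH=)` of true
#'   methylation probabilities over TE cytosines.
#' @param background_levels Named numeric vector of true probabilities for
#'   cytosines outside gbM bodies and TEs (default 0 in all contexts).
#' @param ectopic_gain_rate Expected fraction of eligible 200-bp bins that
#'   acquire an ectopic CG gain.
#' @param ectopic_gain_n If not `NULL`, establish exactly this many gain
#'   regions (weighted sampling without replacement); overrides
#'   `ectopic_gain_rate`.
#' @param target_mean_cg_gain If not `NULL`, calibrate per-bin gain
#'   probabilities so the expected genome-wide mean CG-level gain (over all
#'   CG sites) equals this value; overrides `ectopic_gain_rate`.
#' @param ectopic_gain_level Probability added at each non-saturated CG site
#'   of a gained region (capped at 1).
#' @param accessibility_bias Non-negative weight coupling gain probability to
#'   the accessibility covariate: bin weight is
#'   `exp(-accessibility_bias * accessibility)`, so larger values concentrate
#'   gains in less accessible chromatin. 0 disables the coupling.
#' @param genebody_bias Non-negative multiplier favouring bins whose midpoint
#'   lies in a gene body: weight is multiplied by `1 + genebody_bias`.
#' @param saturation_level CG sites with true level at or above this are never
#'   eligible for ectopic gain.
#' @param min_region_gain Minimum achievable pooled CG-level gain of a region
#'   for it to be eligible (default: half of `ectopic_gain_level`). Regions
#'   whose CG sites are mostly saturated (heavily premethylated
#'   heterochromatin) cannot express a region-level gain and are skipped,
#'   so established regions are detectable on the analysis grid.
#' @param retention_rate_r Per-generation probability that an established gain
#'   region persists.
#' @param coverage_mean Mean sequencing depth per cytosine (Poisson).
#' @param read_length_cytosines Number of consecutive cytosines covered by
#'   one simulated read.
#' @param nonconversion_read_fraction Fraction of reads that are fully
#'   bisulfite-unconverted (every call methylated regardless of truth).
#' @param bin_size Analysis grid width in bp (200 to match the pipeline).
#' @param gain_region_bins Width of a gain region in bins (regions stay
#'   aligned to the grid).
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length_bp = 50000)
#' cfg$n_genes
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 200000L,
                       pericentromere_fraction = 0.2,
                       n_genes = 60L,
                       n_tes = 30L,
                       gene_length_range = c(1000L, 3000L),
                       te_length_range = c(400L, 2000L),
                       fraction_gbm_genes = 0.3,
                       gbm_body_cg_level = 0.35,
                       te_levels = c(CG = 0.9, CHG = 0.7, CHH = 0.1),
                       background_levels = c(CG = 0, CHG = 0, CHH = 0),
                       ectopic_gain_rate = 0.1,
                       ectopic_gain_n = NULL,
                       target_mean_cg_gain = NULL,
                       ectopic_gain_level = 0.5,
                       accessibility_bias = 2,
                       genebody_bias = 1,
                       saturation_level = 0.9,
                       min_region_gain = NULL,
                       retention_rate_r = 0.8,
                       coverage_mean = 10,
                       read_length_cytosines = 10L,
                       nonconversion_read_fraction = 0,
                       bin_size = 200L,
                       gain_region_bins = 1L) {
  cfg <- list(
    seed = assert_positive_int(seed, "seed"),
    n_chromosomes = assert_positive_int(n_chromosomes, "n_chromosomes"),
    chrom_length_bp = assert_positive_int(chrom_length_bp, "chrom_length_bp"),
    pericentromere_fraction = assert_fraction(pericentromere_fraction,
                                             "pericentromere_fraction",
                                             open = TRUE),
    n_genes = assert_positive_int(n_genes, "n_genes"),
    n_tes = assert_positive_int(n_tes, "n_tes"),
    gene_length_range = gene_length_range,
    te_length_range = te_length_range,
    fraction_gbm_genes = assert_fraction(fraction_gbm_genes,
                                         "fraction_gbm_genes"),
    gbm_body_cg_level = assert_fraction(gbm_body_cg_level,
                                        "gbm_body_cg_level"),
    te_levels = te_levels,
    background_levels = background_levels,
    ectopic_gain_rate = assert_fraction(ectopic_gain_rate,
                                        "ectopic_gain_rate"),
    ectopic_gain_n = if (!is.null(ectopic_gain_n))
      assert_positive_int(ectopic_gain_n, "ectopic_gain_n"),
    target_mean_cg_gain = if (!is.null(target_mean_cg_gain))
      assert_fraction(target_mean_cg_gain, "target_mean_cg_gain"),
    ectopic_gain_level = assert_fraction(ectopic_gain_level,
                                         "ectopic_gain_level"),
    accessibility_bias = accessibility_bias,
    genebody_bias = genebody_bias,
    saturation_level = assert_fraction(saturation_level, "saturation_level"),
    min_region_gain = if (is.null(min_region_gain))
      0.5 * assert_fraction(ectopic_gain_level, "ectopic_gain_level")
    else assert_fraction(min_region_gain, "min_region_gain"),
    retention_rate_r = assert_fraction(retention_rate_r, "retention_rate_r"),
    coverage_mean = coverage_mean,
    read_length_cytosines = assert_positive_int(read_length_cytosines,
                                                "read_length_cytosines"),
    nonconversion_read_fraction = assert_fraction(nonconversion_read_fraction,
                                                  "nonconversion_read_fraction"),
    bin_size = assert_positive_int(bin_size, "bin_size"),
    gain_region_bins = assert_positive_int(gain_region_bins,
                                           "gain_region_bins")
  )
  for (ctx in c("CG", "CHG", "CHH")) {
    assert_fraction(unname(cfg$te_levels[ctx]), paste0("te_levels[", ctx, "]"))
    assert_fraction(unname(cfg$background_levels[ctx]),
                    paste0("background_levels[", ctx, "]"))
  }
  if (length(cfg$gene_length_range) != 2 || any(cfg$gene_length_range < 1) ||
      diff(cfg$gene_length_range) < 0) {
    abort("`gene_length_range` must be an increasing length-2 positive vector")
  }
  if (length(cfg$te_length_range) != 2 || any(cfg$te_length_range < 1) ||
      diff(cfg$te_length_range) < 0) {
    abort("`te_length_range` must be an increasing length-2 positive vector")
  }
  if (cfg$chrom_length_bp %% cfg$bin_size != 0) {
    abort("`chrom_length_bp` must be a multiple of `bin_size`")
  }
  if (!is.numeric(cfg$accessibility_bias) || cfg$accessibility_bias < 0) {
    abort("`accessibility_bias` must be a non-negative number")
  }
  if (!is.numeric(cfg$genebody_bias) || cfg$genebody_bias < 0) {
    abort("`genebody_bias` must be a non-negative number")
  }
  if (!is.numeric(cfg$coverage_mean) || cfg$coverage_mean <= 0) {
    abort("`coverage_mean` must be a positive number")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %d bp (pericentromere %.0f%%)\n",
              x$n_chromosomes, x$chrom_length_bp,
              100 * x$pericentromere_fraction))
  cat(sprintf("  annotation: %d genes (%.0f%% gbM), %d TEs\n",
              x$n_genes, 100 * x$fraction_gbm_genes, x$n_tes))
  cat(sprintf("  gains: level %.2f, retention r = %.2f\n",
              x$ectopic_gain_level, x$retention_rate_r))
  cat(sprintf("  reads: coverage %.1fx, %d cytosines/read, %.1f%% unconverted\n",
              x$coverage_mean, x$read_length_cytosines,
              100 * x$nonconversion_read_fraction))
  invisible(x)
}
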