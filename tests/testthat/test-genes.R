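gene_fixture_annotation <- function() {
  tibble::tibble(
    id = c("geneA", "geneB", "te1"),
    chrom = "chr1", strand = c("+", "-", "+"),
    start = c(5000L, 20000L, 40000L), end = c(8000L, 23000L, 41000L),
    type = c("gene", "gene", "TE"),
    exons = list(tibble::tibble(start = c(5000L, 7000L),
                                end = c(6000L, 8000L)),
                 tibble::tibble(start = 20000L, end = 23000L),
                 tibble::tibble(start = 40000L, end = 41000L)))
}

test_that("gene-body methylation pools covered CG cytosines over the span", {
  ann <- gene_fixture_annotation()
  tab <- tibble::tibble(
    chrom = "chr1",
    pos = c(5500L, 6500L, 7500L, 20500L, 20600L),
    strand = "+", context = "CG",
    count_methylated = c(10L, 15L, 5L, 0L, 0L),
    count_total = c(40L, 40L, 20L, 30L, 3L))
  gb <- gene_body_methylation(tab, ann)
  expect_equal(gb$level[gb$gene_id == "geneA"], 30 / 100)
  ## fully unmethylated gene
  expect_equal(gb$level[gb$gene_id == "geneB"], 0)
  ## 3x site ignored everywhere
  expect_equal(gb$count_total[gb$gene_id == "geneB"], 30L)
  ## exons-only restriction drops the interior intron cytosine of geneA
  gbe <- gene_body_methylation(tab, ann, exons_only = TRUE)
  expect_equal(gbe$count_total[gbe$gene_id == "geneA"], 60L)
  ## no covered cytosine -> NA, and unknown ids error
  empty <- gene_body_methylation(tab[0, ], ann)
  expect_true(all(is.na(empty$level)))
  expect_error(gene_body_methylation(tab, ann, genes = "nope"), "unknown")
})

test_that("gbM-change labels obey the strict 3% / 10% thresholds", {
  eps <- 1e-6
  expect_equal(classify_gbm_change(0.01, 0.15), "de_novo")
  expect_equal(classify_gbm_change(0.20, 0.35), "enhanced")
  expect_equal(classify_gbm_change(0.01, 0.05), "unchanged")
  ## boundary behaviour around ref = 0.03 and gain = 0.10
  expect_equal(classify_gbm_change(0.03 - eps, 0.30), "de_novo")
  expect_equal(classify_gbm_change(0.03 + eps, 0.30), "enhanced")
  expect_equal(classify_gbm_change(0.03, 0.90), "unchanged")  # exactly 3%
  expect_equal(classify_gbm_change(0.02, 0.12), "unchanged")  # gain = 0.10
  expect_equal(classify_gbm_change(0.02, 0.12 + eps), "de_novo")
  ## mutual exclusivity over a sweep
  set.seed(1)
  lab <- classify_gbm_change(runif(500), runif(500))
  expect_true(all(lab %in% c("de_novo", "enhanced", "unchanged")))
})

test_that("fwa gbM status follows the strict 40% / 1% thresholds", {
  eps <- 1e-6
  expect_equal(classify_fwa_gbm(0.50, 0.005), "lost")
  expect_equal(classify_fwa_gbm(0.005, 0.004), "no_gbm")
  expect_equal(classify_fwa_gbm(0.45, 0.42), "maintained")
  expect_equal(classify_fwa_gbm(0.30, 0.20), "other")
  expect_equal(classify_fwa_gbm(0.40, 0.50), "other")      # exactly 40%
  expect_equal(classify_fwa_gbm(0.41, 0.009), "lost")
  expect_equal(classify_fwa_gbm(0.40 + eps, 0.01 - eps), "lost")
  expect_equal(classify_fwa_gbm(0.009, 0.008), "no_gbm")
})

test_that("control genes are percentile-matched and avoid DMR overlap", {
  set.seed(3)
  n <- 300
  ann <- tibble::tibble(
    id = sprintf("g%03d", 1:n), chrom = "chr1", strand = "+",
    start = (0:(n - 1)) * 1000L, end = (0:(n - 1)) * 1000L + 800L,
    type = "gene")
  levels <- tibble::tibble(gene_id = ann$id, level = sort(runif(n)))
  targets <- sample(ann$id, 40)
  ## DMR bins overlapping 20 mid-ranked genes
  dmr_ids <- paste0("chr1:", (140:159) * 1000L)

  picks <- select_control_genes(levels, targets, ann, dmr_ids, seed = 5,
                                tolerance = 5)
  expect_equal(nrow(picks), 40)
  expect_true(all(abs(picks$target_percentile -
                        picks$control_percentile) <= 5))
  expect_false(any(picks$control_gene %in% targets))
  expect_false(any(duplicated(picks$control_gene)))
  expect_false(any(picks$control_gene %in% ann$id[141:160]))

  ## over seeds the matched distribution tracks the targets
  tgt_lv <- levels$level[match(targets, levels$gene_id)]
  ctl_lv <- unlist(lapply(1:5, function(s)
    levels$level[match(select_control_genes(levels, targets, ann, dmr_ids,
                                            seed = s)$control_gene,
                       levels$gene_id)]))
  ks <- suppressWarnings(stats::ks.test(tgt_lv, ctl_lv))
  expect_lt(unname(ks$statistic), 0.3)
})

test_that("feature annotation follows the precedence and the windows", {
  ann <- gene_fixture_annotation()
  regions <- tibble::tibble(
    chrom = "chr1",
    start = c(4450L,   # mid 4500: 500 bp upstream of geneA TSS -> promoter
              6400L,   # mid 6450: intron of geneA (between exons)
              5450L,   # mid 5500: geneA exon1 (outside promoter window)
              8400L,   # mid 8450: within 1 kb downstream of geneA end -> TTS
              22950L,  # mid 23000+? actually mid 23000: geneB minus-strand
              40450L,  # mid 40500: te1
              30000L), # intergenic
    end = c(4550L, 6500L, 5550L, 8500L, 23050L, 40550L, 30100L))
  cat_ <- annotate_features(regions, ann)$category
  expect_equal(as.character(cat_[1]), "promoter")
  expect_equal(as.character(cat_[2]), "intron")
  expect_equal(as.character(cat_[3]), "exon")
  expect_equal(as.character(cat_[4]), "TTS")
  ## minus-strand gene: promoter sits right of the 3' coordinate end
  expect_equal(as.character(cat_[5]), "promoter")
  expect_equal(as.character(cat_[6]), "TE")
  expect_equal(as.character(cat_[7]), "intergenic")
  ## totality: one category per region
  expect_false(any(is.na(cat_)))
  expect_error(annotate_features(
    tibble::tibble(chrom = "chr1", start = 99000L, end = 101000L), ann,
    chrom_lengths = c(chr1 = 100000L)), "off the chromosome")
})

test_that("observed/expected enrichment ratios behave", {
  ann <- gene_fixture_annotation()
  regions <- tibble::tibble(chrom = "chr1", start = c(5450L, 7450L),
                            end = c(5550L, 7550L))   # both exonic
  ## identity: regions vs themselves -> all defined ratios are 1
  oe_id <- observed_expected_enrichment(regions, regions, ann)
  expect_true(all(oe_id$oe_ratio[!is.na(oe_id$oe_ratio)] == 1))

  ## all-exon set against a uniform 6-category background -> exon O/E = 6
  obs <- tibble::tibble(category = rep("exon", 12))
  bg <- tibble::tibble(category = rep(c("promoter", "TTS", "exon", "intron",
                                        "TE", "intergenic"), 2))
  oe <- observed_expected_enrichment(obs, bg)
  expect_equal(oe$oe_ratio[oe$category == "exon"], 6)
  expect_equal(oe$oe_ratio[oe$category == "intron"], 0)
  expect_error(observed_expected_enrichment(obs, bg[0, ]), "empty")
})
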