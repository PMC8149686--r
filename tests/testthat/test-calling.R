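test_that("conversion filter removes runs of more than three methylated CHH", {
  four <- chh_read("bad4", c(TRUE, TRUE, TRUE, TRUE))
  three <- chh_read("ok3", c(TRUE, TRUE, TRUE, FALSE, TRUE))
  clean <- chh_read("clean", c(FALSE, FALSE))

  out <- filter_nonconverted_reads(dplyr::bind_rows(four, three, clean))
  expect_equal(attr(out, "n_removed"), 1L)
  expect_setequal(unique(out$read_id), c("ok3", "clean"))

  ## exactly three consecutive methylated CHH always survives
  out3 <- filter_nonconverted_reads(three)
  expect_equal(attr(out3, "n_removed"), 0L)

  ## empty input is a no-op
  out0 <- filter_nonconverted_reads(four[0, ])
  expect_equal(nrow(out0), 0)
  expect_equal(attr(out0, "n_removed"), 0L)
})

test_that("intervening CG/CHG calls do not break a CHH run by default", {
  mixed <- make_read("r1", c("CHH", "CHH", "CG", "CHH", "CHH"),
                     c(TRUE, TRUE, TRUE, TRUE, TRUE))
  ## run of 4 among CHH calls -> removed under the default
  expect_equal(attr(filter_nonconverted_reads(mixed), "n_removed"), 1L)
  ## the strict-adjacency alternative keeps it (max adjacent run is 2)
  expect_equal(attr(filter_nonconverted_reads(mixed, within = "all_calls"),
                    "n_removed"), 0L)
})

test_that("unordered calls are rejected", {
  bad <- make_read("r1", c("CHH", "CHH"), c(TRUE, TRUE), pos = c(20L, 10L))
  expect_error(filter_nonconverted_reads(bad), "ordered")
})

test_that("aggregation counts methylated and total calls per site", {
  cmap <- tibble::tibble(chrom = "chr1", pos = c(10L, 13L), strand = "+",
                         context = c("CG", "CHH"))
  reads <- dplyr::bind_rows(
    make_read("r1", c("CG", "CHH"), c(TRUE, FALSE), pos = c(10L, 13L)),
    make_read("r2", "CG", FALSE, pos = 10L))
  tab <- aggregate_cytosines(reads, cmap)
  site <- tab[tab$pos == 10, ]
  expect_equal(site$count_methylated, 1L)
  expect_equal(site$count_total, 2L)
  expect_equal(site$context, "CG")
  ## uncovered sites are absent
  expect_equal(nrow(tab), 2)

  ## unknown position errors with the coordinate
  off <- make_read("r3", "CG", TRUE, pos = 99L)
  expect_error(aggregate_cytosines(off, cmap), "99")
})

test_that("filtering never increases aggregated counts sitewise", {
  sim <- fixture_sim()
  m0 <- fixture_baseline()
  cfg <- small_config(coverage_mean = 3, nonconversion_read_fraction = 0.1,
                      read_length_cytosines = 8L)
  rd <- sample_reads(m0, cfg, seed = 2)
  cmap <- fixture_context_map()
  before <- aggregate_cytosines(rd, cmap)
  after <- aggregate_cytosines(filter_nonconverted_reads(rd), cmap)
  j <- dplyr::left_join(before, after, by = c("chrom", "pos", "strand"),
                        suffix = c("_b", "_a"))
  j$count_total_a[is.na(j$count_total_a)] <- 0L
  j$count_methylated_a[is.na(j$count_methylated_a)] <- 0L
  expect_true(all(j$count_total_a <= j$count_total_b))
  expect_true(all(j$count_methylated_a <= j$count_methylated_b))
})

test_that("the filter suppresses nonconversion-inflated CHH levels", {
  ## true CHH level 0 everywhere; 10% unconverted reads with >=5 CHH calls
  cfg <- small_config(coverage_mean = 10, nonconversion_read_fraction = 0.1,
                      read_length_cytosines = 12L, fraction_gbm_genes = 0,
                      n_tes = 1L, te_length_range = c(300L, 400L))
  sim <- simulate_genome(cfg)
  m0 <- suppressMessages(simulate_baseline_methylome(sim))
  rd <- sample_reads(m0, cfg, seed = 8)
  cmap <- suppressMessages(cytosine_contexts(sim$genome))

  tes <- dplyr::filter(sim$annotation, type == "TE")
  outside_te <- !(cmap$chrom == tes$chrom[1] & cmap$pos > tes$start[1] &
                    cmap$pos <= tes$end[1])

  lvl <- function(tab) {
    tab <- dplyr::semi_join(tab, cmap[outside_te, ],
                            by = c("chrom", "pos", "strand"))
    chh <- tab[tab$context == "CHH", ]
    sum(chh$count_methylated) / sum(chh$count_total)
  }
  before <- lvl(aggregate_cytosines(rd, cmap))
  after <- lvl(aggregate_cytosines(filter_nonconverted_reads(rd), cmap))
  expect_gt(before, 0.05)        # nonconversion inflates the raw level
  expect_lt(after, 0.1 / 10)     # filtered level < f / 10
})

test_that("region methylation applies the coverage cut and pools by counts", {
  tab <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L), strand = "+", context = "CG",
    count_methylated = c(2L, 8L, 5L), count_total = c(10L, 10L, 19L))
  rm20 <- region_methylation(tab, "chr1", 0, 100, min_coverage = 10)
  expect_equal(rm20$n_sites, 3)
  ## 19x site excluded at the amplicon threshold
  rm <- region_methylation(tab, "chr1", 0, 100, min_coverage = 20)
  expect_equal(rm$n_sites, 0)
  expect_true(is.na(rm$level))

  pooled <- region_methylation(tab[1:2, ], "chr1", 0, 100, min_coverage = 4)
  expect_equal(pooled$level, 10 / 20)  # (2+8)/(10+10), count-weighted
  unw <- region_methylation(tab[1:2, ], "chr1", 0, 100, min_coverage = 4,
                            weighted = FALSE)
  expect_equal(unw$level, mean(c(0.2, 0.8)))

  ones <- dplyr::mutate(tab, count_methylated = count_total)
  expect_equal(region_methylation(ones, "chr1", 0, 100,
                                  min_coverage = 4)$level, 1.0)
})

test_that("genome-wide difference is a mean over shared covered cytosines", {
  mk <- function(m, t) tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L), strand = "+", context = "CG",
    count_methylated = m, count_total = t)
  a <- mk(c(2L, 4L, 6L), c(10L, 10L, 10L))
  b <- mk(c(1L, 4L, 3L), c(10L, 10L, 10L))
  d <- genome_wide_difference(a, b, "CG")
  expect_equal(d$mean_difference, mean(c(0.1, 0, 0.3)))
  expect_equal(d$n_sites, 3)
  ## identity and antisymmetry
  expect_equal(genome_wide_difference(a, a, "CG")$mean_difference, 0)
  expect_equal(genome_wide_difference(b, a, "CG")$mean_difference,
               -d$mean_difference)
  ## no shared context errors
  expect_error(genome_wide_difference(a, b, "CHH"), "CHH")
})
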