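test_that("baseline methylome follows the configured landscape", {
  sim <- fixture_sim()
  m0 <- fixture_baseline()
  sites <- m0$sites
  cfg <- sim$config

  ## TE cytosines sit exactly at te_levels per context
  tes <- dplyr::filter(sim$annotation, type == "TE")
  in_te <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(tes))) {
    in_te <- in_te | (sites$chrom == tes$chrom[i] &
                        sites$pos > tes$start[i] & sites$pos <= tes$end[i])
  }
  for (ctx in c("CG", "CHG", "CHH")) {
    lv <- sites$prob[in_te & sites$context == ctx]
    expect_gt(length(lv), 100)
    expect_lt(abs(mean(lv) - cfg$te_levels[[ctx]]), 0.02)
  }

  ## CHH (and CHG) outside TEs equal the configured background of 0
  expect_equal(max(sites$prob[!in_te & sites$context == "CHH"]), 0)
  expect_equal(max(sites$prob[!in_te & sites$context == "CHG"]), 0)

  ## gbM dome: body mean near the configured level, peak at 40-80% of length
  genes <- dplyr::filter(sim$annotation, id %in% m0$gbm_genes)
  expect_gt(nrow(genes), 0)
  g <- genes[which.max(genes$end - genes$start), ]
  idx <- which(sites$chrom == g$chrom & sites$context == "CG" &
                 sites$pos > g$start & sites$pos <= g$end)
  body <- sites$prob[idx]
  expect_lt(abs(mean(body) - cfg$gbm_body_cg_level), 0.1)
  rel <- (sites$pos[idx] - g$start) / (g$end - g$start)
  if (g$strand == "-") rel <- 1 - rel
  expect_gt(rel[which.max(body)], 0.4)
  expect_lt(rel[which.max(body)], 0.8)
})

test_that("without gbM genes every gene body is CG-unmethylated", {
  cfg <- small_config(fraction_gbm_genes = 0)
  sim <- simulate_genome(cfg)
  m0 <- suppressMessages(simulate_baseline_methylome(sim))
  genes <- dplyr::filter(sim$annotation, type == "gene")
  for (i in seq_len(nrow(genes))) {
    idx <- m0$sites$chrom == genes$chrom[i] & m0$sites$context == "CG" &
      m0$sites$pos > genes$start[i] & m0$sites$pos <= genes$end[i]
    expect_true(all(m0$sites$prob[idx] < 0.01))
  }
})

test_that("ectopic gain is CG-only, avoids saturated sites, honours rate 0", {
  sim <- fixture_sim()
  m0 <- fixture_baseline()

  cfg0 <- small_config(ectopic_gain_rate = 0)
  m_none <- simulate_ectopic_gain(m0, sim, cfg0)
  expect_identical(m_none$sites$prob, m0$sites$prob)
  expect_equal(nrow(m_none$registry), 0)

  m1 <- simulate_ectopic_gain(m0, sim)
  expect_gt(nrow(m1$registry), 0)
  ## CHG/CHH untouched
  non_cg <- m0$sites$context != "CG"
  expect_identical(m1$sites$prob[non_cg], m0$sites$prob[non_cg])
  ## saturated sites never rise
  sat <- m0$sites$prob >= sim$config$saturation_level
  expect_identical(m1$sites$prob[sat], m0$sites$prob[sat])
  ## gains only within registered regions
  changed <- which(m1$sites$prob != m0$sites$prob)
  key <- paste0(m0$sites$chrom[changed], ":",
                ((m0$sites$pos[changed] - 1L) %/% 200L) * 200L)
  expect_true(all(key %in% m1$registry$region_id))
})

test_that("gains prefer less accessible chromatin", {
  cfg <- sim_config(seed = 11L, n_chromosomes = 2L, chrom_length_bp = 200000L,
                    n_genes = 40L, n_tes = 16L,
                    te_length_range = c(300L, 900L),
                    ectopic_gain_n = 250L, accessibility_bias = 3)
  sim <- simulate_genome(cfg)
  m0 <- suppressMessages(simulate_baseline_methylome(sim))
  m1 <- simulate_ectopic_gain(m0, sim)
  expect_gte(nrow(m1$registry), 200)
  acc <- sim$accessibility
  gained_acc <- acc$accessibility[paste0(acc$chrom, ":", acc$start) %in%
                                    m1$registry$region_id]
  expect_lt(mean(gained_acc), mean(acc$accessibility))
})

test_that("propagation keeps all regions at r = 1 and reverts all at r = 0", {
  sim <- fixture_sim()
  m0 <- fixture_baseline()
  m1 <- simulate_ectopic_gain(m0, sim)

  keep_all <- propagate_generation(m1, 1, seed = 5)
  expect_identical(keep_all$sites$prob, m1$sites$prob)
  expect_true(all(keep_all$registry$retained))
  expect_equal(keep_all$generation, "G2")

  lose_all <- propagate_generation(m1, 0, seed = 5)
  expect_identical(lose_all$sites$prob, m0$sites$prob)
  expect_false(any(lose_all$registry$retained))

  ## conservation: no new regions, no resurrection
  again <- propagate_generation(lose_all, 1, seed = 6)
  expect_false(any(again$registry$retained))
  expect_equal(nrow(again$registry), nrow(m1$registry))

  expect_error(propagate_generation(m1, 1.2, seed = 1), "probability")
})

test_that("retention of 1000 regions at r = 0.8 falls in the binomial band", {
  m <- registry_methylome(1000)
  m2 <- propagate_generation(m, 0.8, seed = 77)
  kept <- sum(m2$registry$retained)
  ## exact central 99% binomial interval for n = 1000, p = 0.8
  expect_gte(kept, qbinom(0.005, 1000, 0.8))
  expect_lte(kept, qbinom(0.995, 1000, 0.8))
  expect_gte(kept, 766)
  expect_lte(kept, 832)
  ## lost regions reverted to baseline, kept regions untouched
  lost_ids <- m2$registry$region_id[!m2$registry$retained]
  lost_sites <- paste0("chr1:", ((m2$sites$pos - 1L) %/% 200L) * 200L) %in%
    lost_ids
  expect_true(all(m2$sites$prob[lost_sites] == m2$sites$baseline[lost_sites]))
  expect_true(all(m2$sites$prob[!lost_sites] == 0.6))
})
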