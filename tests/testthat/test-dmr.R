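test_that("the exact bin test agrees with enumeration and fisher.test", {
  ## frozen worked example: [[8,2],[2,8]] has two-sided p = 2 * 2126 / 184756
  expect_equal(bin_fisher_test(8, 2, 2, 8), 2 * 2126 / 184756,
               tolerance = 1e-12)
  expect_equal(bin_fisher_test(5, 5, 5, 5), 1.0)
  ## transposition symmetry
  expect_equal(bin_fisher_test(7, 3, 1, 9), bin_fisher_test(1, 9, 7, 3))

  ## exhaustive check against the choose()-based oracle, margins <= 12
  for (n1 in 0:12) for (n2 in 0:12) {
    if (n1 + n2 == 0) next
    m1 <- rep(0:n1, each = n2 + 1)
    m2 <- rep(0:n2, times = n1 + 1)
    p <- bin_fisher_test(m1, n1 - m1, m2, n2 - m2)
    oracle <- mapply(fisher_enum_oracle, m1, n1 - m1, m2, n2 - m2)
    expect_lt(max(abs(p - oracle)), 1e-9)
  }

  ## spot-check against stats::fisher.test on larger random tables
  set.seed(4)
  for (i in 1:50) {
    m1 <- rpois(1, 20); u1 <- rpois(1, 20)
    m2 <- rpois(1, 20); u2 <- rpois(1, 20)
    if (m1 + u1 == 0 || m2 + u2 == 0) next
    expect_equal(bin_fisher_test(m1, u1, m2, u2),
                 stats::fisher.test(matrix(c(m1, u1, m2, u2), 2,
                                           byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  expect_error(bin_fisher_test(-1, 2, 3, 4), "non-negative")
})

test_that("the DMR rule applies coverage, effect-size and p filters jointly", {
  ## bins: (1) too few cytosines, (2) small difference, (3) clear hyper
  test <- bins_from_counts(c(40L, 27L, 40L), total = rep(50L, 3),
                           n_cyt = c(3L, 5L, 4L))
  ref <- bins_from_counts(c(5L, 23L, 10L), total = rep(50L, 3),
                          n_cyt = c(6L, 5L, 4L))
  d <- call_dmrs(test, ref)
  expect_equal(nrow(d), 1)
  expect_equal(d$bin_id, "chr1:400")
  expect_equal(d$direction, "hyper")
  expect_equal(d$difference, 0.6)
  expect_lt(d$p_value, 1e-8)
  expect_equal(d$p_value, fisher_enum_oracle(40, 10, 10, 40),
               tolerance = 1e-12)

  ## a significant bin under 10% difference is never a DMR
  t2 <- bins_from_counts(540L, 3000L, 6L)
  r2 <- bins_from_counts(300L, 3000L, 6L)
  expect_lt(bin_fisher_test(540, 2460, 300, 2700), 1e-6)
  expect_equal(nrow(call_dmrs(t2, r2)), 0)

  expect_error(call_dmrs(test, ref, context = "CHH"), "CHH")
})

test_that("hyper DMRs of A vs B equal hypo DMRs of B vs A", {
  set.seed(7)
  n <- 60
  test <- bins_from_counts(rbinom(n, 100, runif(n)), rep(100L, n), 5L)
  ref <- bins_from_counts(rbinom(n, 100, runif(n)), rep(100L, n), 5L)
  ab <- call_dmrs(test, ref)
  ba <- call_dmrs(ref, test)
  hyper_ab <- dplyr::arrange(ab[ab$direction == "hyper", ], bin_id)
  hypo_ba <- dplyr::arrange(ba[ba$direction == "hypo", ], bin_id)
  expect_equal(hyper_ab$bin_id, hypo_ba$bin_id)
  expect_equal(hyper_ab$p_value, hypo_ba$p_value)
  expect_equal(hyper_ab$difference, -hypo_ba$difference)
})

test_that("line intersection then generation union combines DMR sets", {
  comb <- combine_line_generation(list(
    T2 = list(c("a", "b", "c"), c("b", "c", "d")),
    T3 = list(c("c", "e"), c("c", "e", "f"))))
  expect_setequal(comb$per_generation$T2, c("b", "c"))
  expect_setequal(comb$per_generation$T3, c("c", "e"))
  expect_setequal(comb$combined, c("b", "c", "e"))
  ## a single line is its own intersection
  one <- combine_line_generation(list(T2 = list(c("a", "b"))))
  expect_setequal(one$per_generation$T2, c("a", "b"))
})

test_that("cluster partition of DMRs conserves the total", {
  dmrs <- tibble::tibble(bin_id = c("chr1:0", "chr1:200", "chr1:999000"),
                         chrom = "chr1", bin_start = c(0L, 200L, 999000L),
                         direction = "hyper", p_value = 0.01,
                         difference = 0.2)
  clusters <- assign_clusters(tibble::tibble(
    bin_id = c("chr1:0", "chr1:200"), chrom = "chr1",
    bin_start = c(0L, 200L), level = c(0.9, 0.1), rank = 1:2,
    percentile = c(10L, 90L)))
  part <- partition_by_cluster(dmrs, clusters)
  expect_equal(part$cluster, c(1L, 4L, NA))
  expect_equal(sum(!is.na(part$cluster)) + sum(is.na(part$cluster)),
               nrow(dmrs))
})

test_that("heritability chains intersect targets with their references", {
  sets <- list(T2p = c("a", "b", "c", "d"), T2m = c("a", "b", "x"),
               T3m = c("a", "d", "y"))
  rep1 <- heritability_chain(sets, list(
    list(target = "T2m", references = "T2p")))
  expect_equal(rep1$n_heritable, 2)
  expect_equal(rep1$pct_reference, 100 * 2 / 4)
  expect_equal(rep1$pct_target, 100 * 2 / 3)

  ## reference = target -> 100% heritable
  self <- heritability_chain(sets, list(
    list(target = "T2p", references = "T2p")))
  expect_equal(self$pct_reference, 100)

  ## chains compose: a later entry resolves an earlier target to its
  ## heritable set
  rep2 <- heritability_chain(sets, list(
    list(target = "T2m", references = "T2p"),
    list(target = "T3m", references = "T2m")))
  her <- attr(rep2, "heritable_sets")
  expect_setequal(her$T2m, c("a", "b"))
  expect_setequal(her$T3m, "a")   # T3m with heritable(T2m) = {a,b}

  expect_error(heritability_chain(sets, list(
    list(target = "T9", references = "T2p"))), "unknown")
})
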