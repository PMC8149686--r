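## shared fixtures, built once per test run

small_config <- function(...) {
  args <- list(seed = 42L, n_chromosomes = 2L, chrom_length_bp = 60000L,
               n_genes = 16L, n_tes = 8L, gene_length_range = c(800L, 2000L),
               te_length_range = c(300L, 900L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

.fixtures <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_genome(small_config())
  }
  .fixtures$sim
}

fixture_baseline <- function() {
  if (is.null(.fixtures$m0)) {
    .fixtures$m0 <- suppressMessages(simulate_baseline_methylome(fixture_sim()))
  }
  .fixtures$m0
}

fixture_context_map <- function() {
  if (is.null(.fixtures$cmap)) {
    .fixtures$cmap <- suppressMessages(cytosine_contexts(fixture_sim()$genome))
  }
  .fixtures$cmap
}

## hand-built reads: one row per call
make_read <- function(id, contexts, meth, chrom = "chr1", strand = "+",
                      pos = NULL) {
  n <- length(contexts)
  if (is.null(pos)) pos <- seq(10L, by = 3L, length.out = n)
  tibble::tibble(read_id = id, chrom = chrom, start = pos[1], strand = strand,
                 pos = pos, context = contexts, methylated = meth)
}

chh_read <- function(id, meth) make_read(id, rep("CHH", length(meth)), meth)

## independent exact-Fisher oracle: exhaustive enumeration with choose()
fisher_enum_oracle <- function(m1, u1, m2, u2) {
  n1 <- m1 + u1; n2 <- m2 + u2; K <- m1 + m2
  ks <- max(0, K - n2):min(K, n1)
  pr <- choose(n1, ks) * choose(n2, K - ks) / choose(n1 + n2, K)
  obs <- pr[ks == m1]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

## bin methylome built straight from pooled per-bin counts
bins_from_counts <- function(m, total, n_cyt, context = "CG",
                             chrom = "chr1", sample_id = NULL) {
  n <- length(m)
  as_bin_methylome(tibble::tibble(
    chrom = chrom, bin_start = (seq_len(n) - 1L) * 200L, context = context,
    count_methylated = m, count_total = total, n_cytosines = n_cyt),
    sample_id = sample_id)
}

## synthetic true methylome with k single-bin gain regions (for retention
## tests that do not need a genome)
registry_methylome <- function(k, prob = 0.6, baseline = 0.1) {
  starts <- (seq_len(k) - 1L) * 200L
  sites <- tibble::tibble(
    chrom = "chr1", pos = starts + 100L, strand = "+", context = "CG",
    trinucleotide = "CGA", baseline = baseline, prob = prob)
  registry <- tibble::tibble(
    region_id = paste0("chr1:", starts), chrom = "chr1",
    start = starts, end = starts + 200L, established = "G1",
    retained = TRUE, lost_generation = NA_character_)
  new_true_methylome(sites, registry, "G1", character(0))
}
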