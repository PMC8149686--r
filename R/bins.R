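#' Pool a cytosine table onto the fixed bin grid
#'
#' Divides each chromosome into fixed-width bins (200 bp by default, aligned
#' to position 0) and pools, per bin and context, the methylated/total counts
#' of every cytosine covered at least `min_coverage` times, together with the
#' tally of covered cytosines. Empty bins are retained with zero counts so
#' all samples share one grid.
#'
#' @param table Cytosine table (`chrom`, `pos`, `strand`, `context`,
#'   `count_methylated`, `count_total`).
#' @param chrom_lengths Named vector of chromosome lengths (or a
#'   `DNAStringSet`).
#' @param bin_size Bin width in bp (default 200).
#' @param min_coverage Per-cytosine depth below which a cytosine does not
#'   contribute (default 4, the DMR-rule coverage).
#' @param sample_id Optional label stored as an attribute.
#' @return A tibble of class `bin_methylome`: `bin_id`, `chrom`,
#'   `bin_start` (0-based), `context`, `count_methylated`, `count_total`,
#'   `n_cytosines`, `level` (`NA` where no counts).
#' @export
bin_methylome <- function(table, chrom_lengths, bin_size = 200,
                          min_coverage = 4, sample_id = NULL) {
  assert_columns(table, c("chrom", "pos", "context",
                          "count_methylated", "count_total"), "table")
  lens <- chrom_lengths_of(chrom_lengths)
  bad <- table$pos > lens[table$chrom] | table$pos < 1
  if (anyNA(bad) || any(bad)) {
    i <- which(is.na(bad) | bad)[1]
    abort(sprintf("cytosine at %s:%d lies beyond the chromosome end",
                  table$chrom[i], table$pos[i]))
  }
  bin_size <- as.integer(bin_size)
  grid <- purrr::imap_dfr(as.list(lens), function(len, ch) {
    tibble(chrom = ch,
           bin_start = seq(0L, as.integer(len) - 1L, by = bin_size))
  }) |>
    tidyr::expand_grid(context = c("CG", "CHG", "CHH"))

  pooled <- table |>
    filter(.data$count_total >= min_coverage) |>
    mutate(bin_start = as.integer(((.data$pos - 1L) %/% bin_size) * bin_size)) |>
    group_by(.data$chrom, .data$bin_start, .data$context) |>
    summarise(count_methylated = sum(.data$count_methylated),
              count_total = sum(.data$count_total),
              n_cytosines = dplyr::n(), .groups = "drop")

  out <- left_join(grid, pooled, by = c("chrom", "bin_start", "context")) |>
    mutate(count_methylated = tidyr::replace_na(.data$count_methylated, 0L),
           count_total = tidyr::replace_na(.data$count_total, 0L),
           n_cytosines = tidyr::replace_na(.data$n_cytosines, 0L),
           level = ifelse(.data$count_total > 0,
                          .data$count_methylated / .data$count_total,
                          NA_real_),
           bin_id = bin_id(.data$chrom, .data$bin_start)) |>
    select("bin_id", "chrom", "bin_start", "context",
           "count_methylated", "count_total", "n_cytosines", "level") |>
    arrange(.data$chrom, .data$bin_start, .data$context)
  structure(out, class = c("bin_methylome", class(out)),
            sample_id = sample_id, bin_size = bin_size,
            min_coverage = min_coverage)
}

#' Validate a pre-binned count table as a `bin_methylome`
#'
#' For callers that already have pooled per-bin counts (e.g. simulated bins
#' or external pipelines). Adds `bin_id` and `level` columns if absent.
#'
#' @param df Tibble with `chrom`, `bin_start`, `context`,
#'   `count_methylated`, `count_total`, `n_cytosines`.
#' @param sample_id,bin_size Stored as attributes.
#' @return A `bin_methylome` tibble.
#' @export
as_bin_methylome <- function(df, sample_id = NULL, bin_size = 200) {
  assert_columns(df, c("chrom", "bin_start", "context",
                       "count_methylated", "count_total", "n_cytosines"),
                 "df")
  out <- df |>
    mutate(bin_id = bin_id(.data$chrom, .data$bin_start),
           level = ifelse(.data$count_total > 0,
                          .data$count_methylated / .data$count_total,
                          NA_real_)) |>
    arrange(.data$chrom, .data$bin_start, .data$context)
  structure(out, class = unique(c("bin_methylome", class(out))),
            sample_id = sample_id, bin_size = bin_size)
}

same_grid <- function(bins_list, context) {
  ids <- lapply(bins_list, function(b) {
    b <- filter(b, .data$context == !!context)
    b$bin_id
  })
  ref <- ids[[1]]
  for (other in ids[-1]) {
    if (length(other) != length(ref) || !all(other == ref)) {
      abort("bin methylomes are not on the same bin grid")
    }
  }
  invisible(TRUE)
}

#' Retain bins with CG methylation in at least one genotype
#'
#' A bin is kept iff at least one of the supplied samples has a CG bin level
#' strictly above zero (evaluated after the per-cytosine coverage filter
#' built into the bins; uncovered bins count as unmethylated).
#'
#' @param bins_list List of `bin_methylome` objects on one grid.
#' @param context Context used for the test (default `"CG"`).
#' @return Character vector of retained `bin_id`s in genome order.
#' @export
filter_unmethylated_bins <- function(bins_list, context = "CG") {
  stopifnot(is.list(bins_list), length(bins_list) >= 1)
  same_grid(bins_list, context)
  lv <- lapply(bins_list, function(b) {
    b <- filter(b, .data$context == !!context)
    tidyr::replace_na(b$level, 0)
  })
  any_meth <- Reduce(`|`, lapply(lv, function(x) x > 0))
  b1 <- filter(bins_list[[1]], .data$context == !!context)
  b1$bin_id[any_meth]
}

#' Rank retained bins into percentiles of reference CG methylation
#'
#' Sorts retained bins by the reference sample's CG level in descending
#' order (percentile 1 = most methylated) and splits them into
#' `n_percentiles` contiguous groups whose sizes differ by at most one bin.
#' Ties are broken by genomic order (chromosome, start) so the assignment is
#' deterministic.
#'
#' @param reference `bin_methylome` of the reference (wild-type) sample.
#' @param retained_ids Bin ids from [filter_unmethylated_bins()].
#' @param n_percentiles Number of rank groups (default 100).
#' @return Tibble: `bin_id`, `chrom`, `bin_start`, `level`, `rank`,
#'   `percentile`.
#' @export
rank_percentiles <- function(reference, retained_ids, n_percentiles = 100) {
  if (length(retained_ids) < n_percentiles) {
    abort(sprintf(
      "only %d retained bins for %d percentiles; lower `n_percentiles`",
      length(retained_ids), n_percentiles))
  }
  ref <- reference |>
    filter(.data$context == "CG", .data$bin_id %in% retained_ids) |>
    mutate(level = tidyr::replace_na(.data$level, 0)) |>
    arrange(dplyr::desc(.data$level), .data$chrom, .data$bin_start)
  n <- nrow(ref)
  ref |>
    mutate(rank = dplyr::row_number(),
           percentile = as.integer(((.data$rank - 1L) * n_percentiles) %/% n) + 1L) |>
    select("bin_id", "chrom", "bin_start", "level", "rank", "percentile")
}

#' Assign ranked percentiles to the four methylation clusters
#'
#' With the default boundaries, cluster 1 = percentiles 1-13 (heavily
#' methylated heterochromatin), cluster 2 = 14-25, cluster 3 = 26-43,
#' cluster 4 = 44-100 (essentially unmethylated in the reference). The
#' boundaries are dataset-derived defaults, configurable for other genomes.
#'
#' @param percentiles Output of [rank_percentiles()].
#' @param boundaries Increasing integer vector of upper percentile bounds of
#'   clusters 1..k-1 (default `c(13, 25, 43)` for four clusters).
#' @return The input tibble with an integer `cluster` column, classed
#'   `cluster_assignment`.
#' @export
assign_clusters <- function(percentiles, boundaries = c(13, 25, 43)) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    abort("`boundaries` must be strictly increasing")
  }
  out <- mutate(percentiles,
                cluster = findInterval(.data$percentile - 1L, boundaries) + 1L)
  structure(out, class = unique(c("cluster_assignment", class(out))),
            boundaries = boundaries)
}

#' Sequence composition of genomic regions
#'
#' Per-region (C+G) fraction and CG/CHG/CHH cytosine-site densities, with
#' context sites counted on both strands.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genome Named `DNAStringSet`.
#' @param context_map Optional precomputed [cytosine_contexts()] of the
#'   genome (computed on the fly otherwise).
#' @return The regions with `gc_fraction`, `cg_density`, `chg_density`,
#'   `chh_density` (sites per bp).
#' @export
sequence_composition <- function(regions, genome, context_map = NULL) {
  assert_columns(regions, c("chrom", "start", "end"), "regions")
  if (nrow(regions) == 0) abort("`regions` is empty")
  if (any(regions$end <= regions$start)) abort("regions must have positive length")
  if (is.null(context_map)) context_map <- cytosine_contexts(genome)

  width <- regions$end - regions$start
  sub <- Biostrings::DNAStringSet(genome[regions$chrom])
  sub <- Biostrings::subseq(sub, start = regions$start + 1L,
                            end = regions$end)
  gc <- Biostrings::letterFrequency(sub, letters = "CG", as.prob = TRUE)[, 1]

  counts <- matrix(0L, nrow(regions), 3,
                   dimnames = list(NULL, c("CG", "CHG", "CHH")))
  for (i in seq_len(nrow(regions))) {
    hit <- context_map$chrom == regions$chrom[i] &
      context_map$pos > regions$start[i] & context_map$pos <= regions$end[i]
    tb <- table(context_map$context[hit])
    counts[i, names(tb)] <- as.integer(tb)
  }
  regions |>
    mutate(gc_fraction = as.numeric(gc),
           cg_density = counts[, "CG"] / width,
           chg_density = counts[, "CHG"] / width,
           chh_density = counts[, "CHH"] / width)
}
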