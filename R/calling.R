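#' Remove reads that look bisulfite-unconverted
#'
#' Drops every read containing a run of more than `max_run` consecutive
#' methylated CHH calls. Failed bisulfite conversion leaves all cytosines of
#' a read reading as methylated; because CHH methylation is rare, a long run
#' of methylated CHH calls on one read is its signature.
#'
#' By default a run is counted among the read's CHH calls only, so
#' intervening CG/CHG calls do not break it (conversion failure affects the
#' whole molecule). Set `within = "all_calls"` to require the methylated CHH
#' calls to be strictly adjacent in the full call sequence.
#'
#' @param reads Per-call tibble as produced by [sample_reads()] /
#'   [read_read_calls()]: `read_id`, `chrom`, `pos`, `context`, `methylated`
#'   (other columns pass through). Calls must be ordered by position within
#'   each read.
#' @param max_run Longest tolerated run of methylated CHH calls; reads with
#'   a run strictly longer are removed (default 3, i.e. "more than three").
#' @param within `"chh_calls"` (default) or `"all_calls"`; see Details.
#' @return The surviving calls, with attributes `n_removed` (number of reads
#'   dropped) and `removed_reads` (their ids).
#' @examples
#' reads <- tibble::tibble(
#'   read_id = "r1", chrom = "chr1", pos = c(1, 4, 7, 9, 12),
#'   context = "CHH", methylated = c(TRUE, TRUE, TRUE, FALSE, TRUE))
#' attr(filter_nonconverted_reads(reads), "n_removed")  # 0: max run is 3
#' @export
filter_nonconverted_reads <- function(reads, max_run = 3,
                                      within = c("chh_calls", "all_calls")) {
  within <- match.arg(within)
  assert_columns(reads, c("read_id", "pos", "context", "methylated"), "reads")
  if (nrow(reads) == 0) {
    return(structure(reads, n_removed = 0L, removed_reads = character(0)))
  }
  ## pre-condition: calls ordered by position within each read
  if (nrow(reads) > 1 &&
      any(reads$pos[-1] <= reads$pos[-nrow(reads)] &
            reads$read_id[-1] == reads$read_id[-nrow(reads)])) {
    abort("read calls must be strictly ordered by position within each read")
  }

  if (within == "chh_calls") {
    sub <- reads[reads$context == "CHH", c("read_id", "methylated")]
    v <- sub$methylated
    id <- sub$read_id
  } else {
    v <- reads$methylated & reads$context == "CHH"
    id <- reads$read_id
  }
  bad <- character(0)
  if (length(v) > 0) {
    boundary <- c(TRUE, id[-1] != id[-length(id)] | v[-1] != v[-length(v)])
    run <- cumsum(boundary)
    run_len <- tabulate(run)
    run_meth <- v[boundary]
    long <- which(run_meth & run_len > max_run)
    bad <- unique(id[boundary][long])
  }
  out <- reads[!(reads$read_id %in% bad), , drop = FALSE]
  structure(out, n_removed = length(bad), removed_reads = bad)
}

#' Aggregate read calls into a per-cytosine count table
#'
#' Accumulates methylated / total counts per (chromosome, position, strand)
#' and attaches the genome-derived context. Methylation level is `#C/(#C+#T)`
#' and is computed lazily by downstream functions; zero-coverage sites are
#' simply absent.
#'
#' @param reads Per-call tibble (ideally after
#'   [filter_nonconverted_reads()]).
#' @param context_map Tibble from [cytosine_contexts()] (`chrom`, `pos`,
#'   `strand`, `context`); every covered position must appear in it.
#' @return A cytosine table: `chrom`, `pos`, `strand`, `context`,
#'   `count_methylated`, `count_total`.
#' @export
aggregate_cytosines <- function(reads, context_map) {
  assert_columns(reads, c("chrom", "pos", "strand", "methylated"), "reads")
  assert_columns(context_map, c("chrom", "pos", "strand", "context"),
                 "context_map")
  counts <- reads |>
    group_by(.data$chrom, .data$pos, .data$strand) |>
    summarise(count_methylated = sum(.data$methylated),
              count_total = dplyr::n(), .groups = "drop")
  out <- left_join(counts,
                   select(context_map, "chrom", "pos", "strand", "context"),
                   by = c("chrom", "pos", "strand"))
  if (anyNA(out$context)) {
    miss <- out[is.na(out$context), ][1, ]
    abort(sprintf("no cytosine in context map at %s:%d (%s)",
                  miss$chrom, miss$pos, miss$strand))
  }
  select(out, "chrom", "pos", "strand", "context",
         "count_methylated", "count_total") |>
    arrange(.data$chrom, .data$pos, .data$strand)
}

#' Add the per-cytosine methylation level column
#'
#' @param table A cytosine table.
#' @return The table with a `level = count_methylated / count_total` column.
#' @export
add_level <- function(table) {
  mutate(table, level = ifelse(.data$count_total > 0,
                               .data$count_methylated / .data$count_total,
                               NA_real_))
}

#' Methylation over a genomic region (amplicon-style readout)
#'
#' Per-cytosine levels and the pooled, count-weighted level over one region,
#' after dropping cytosines below a coverage threshold. The default
#' `min_coverage = 20` matches deep amplicon (BS-PCR-seq style) analysis;
#' use 4 for WGBS-scale data. The pooled level is total-count weighted,
#' `sum(#C) / sum(#C + #T)`; set `weighted = FALSE` for the unweighted mean
#' of per-cytosine levels.
#'
#' @param table A cytosine table.
#' @param chrom Chromosome name.
#' @param start,end Region as 0-based half-open interval.
#' @param context Optional context filter (`"CG"`, `"CHG"`, `"CHH"`).
#' @param min_coverage Minimum reads per cytosine (default 20).
#' @param weighted Pool by counts (default) or average per-cytosine levels.
#' @return A list of class `region_methylation`: `sites` (per-cytosine
#'   tibble with `level`), `level` (pooled; `NA` when no cytosine survives),
#'   `n_sites`, and the region coordinates. A region with no surviving
#'   cytosine is a well-defined "no data" result, not an error.
#' @export
region_methylation <- function(table, chrom, start, end, context = NULL,
                               min_coverage = 20, weighted = TRUE) {
  assert_columns(table, c("chrom", "pos", "strand", "context",
                          "count_methylated", "count_total"), "table")
  sites <- table |>
    filter(.data$chrom == !!chrom, .data$pos > !!start, .data$pos <= !!end,
           .data$count_total >= min_coverage)
  if (!is.null(context)) sites <- filter(sites, .data$context == !!context)
  sites <- add_level(sites)
  lev <- if (nrow(sites) == 0) NA_real_ else if (weighted) {
    sum(sites$count_methylated) / sum(sites$count_total)
  } else {
    mean(sites$level)
  }
  structure(list(sites = sites, level = lev, n_sites = nrow(sites),
                 chrom = chrom, start = start, end = end,
                 min_coverage = min_coverage),
            class = "region_methylation")
}

#' @export
print.region_methylation <- function(x, ...) {
  cat(sprintf("<region_methylation> %s:%d-%d: %d cytosine(s) at >=%dx, pooled level %s\n",
              x$chrom, x$start, x$end, x$n_sites, x$min_coverage,
              if (is.na(x$level)) "no data" else sprintf("%.4f", x$level)))
  invisible(x)
}

#' Genome-wide mean methylation difference between two samples
#'
#' Over cytosines of one context covered at `min_coverage` or more in both
#' samples, the mean of per-cytosine `level_a - level_b`, plus per-chromosome
#' means for chromosome-scale summaries.
#'
#' @param table_a,table_b Cytosine tables on the same genome.
#' @param context Context to compare (`"CG"`, `"CHG"` or `"CHH"`).
#' @param min_coverage Minimum depth in each sample (default 4).
#' @return List: `mean_difference`, `n_sites`, `per_chromosome` tibble.
#' @export
genome_wide_difference <- function(table_a, table_b, context,
                                   min_coverage = 4) {
  a <- filter(table_a, .data$context == !!context,
              .data$count_total >= min_coverage)
  b <- filter(table_b, .data$context == !!context,
              .data$count_total >= min_coverage)
  shared <- inner_join(
    a |> add_level() |> select("chrom", "pos", "strand", level_a = "level"),
    b |> add_level() |> select("chrom", "pos", "strand", level_b = "level"),
    by = c("chrom", "pos", "strand"))
  if (nrow(shared) == 0) {
    abort(sprintf("no %s cytosine covered >=%dx in both samples",
                  context, min_coverage))
  }
  d <- shared$level_a - shared$level_b
  per_chrom <- shared |>
    mutate(difference = d) |>
    group_by(.data$chrom) |>
    summarise(mean_difference = mean(.data$difference),
              n_sites = dplyr::n(), .groups = "drop")
  list(mean_difference = mean(d), n_sites = nrow(shared),
       per_chromosome = per_chrom)
}
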