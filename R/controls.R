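#' Sample mCG-equivalent control regions
#'
#' For each ranked percentile holding `k` DMR bins, draws `k` bins uniformly
#' without replacement from the retained non-DMR bins of that same
#' percentile. The control set therefore reproduces the DMR set's
#' reference-methylation percentile histogram exactly while being disjoint
#' from it, making it the natural background for composition and
#' feature-enrichment comparisons.
#'
#' @param dmrs A `dmr_set` (or character vector of bin ids).
#' @param percentiles Percentile map from [rank_percentiles()] covering the
#'   retained bins; every DMR bin must appear in it.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param exclude Additional `dmr_set`s/bin-id vectors to remove from the
#'   eligible pool (e.g. the hypo DMRs of the same comparison, so controls
#'   are non-differential in either direction).
#' @param allow_shortfall If a percentile holds fewer eligible bins than
#'   needed, take all of them and report the deficit (default is an error).
#' @return A tibble of class `control_set`: `bin_id`, `chrom`, `bin_start`,
#'   `percentile`; attributes `seed` and `shortfall`.
#' @export
sample_mcg_equivalent <- function(dmrs, percentiles, seed,
                                  exclude = list(),
                                  allow_shortfall = FALSE) {
  dmr_ids <- dmr_bins(dmrs)
  if (!all(dmr_ids %in% percentiles$bin_id)) {
    missing <- setdiff(dmr_ids, percentiles$bin_id)[1]
    abort(sprintf("DMR bin %s is not covered by the percentile map", missing))
  }
  if (is.data.frame(exclude) || is.character(exclude)) exclude <- list(exclude)
  excluded <- unique(c(dmr_ids, unlist(lapply(exclude, dmr_bins))))

  need <- percentiles |>
    filter(.data$bin_id %in% dmr_ids) |>
    count(.data$percentile, name = "k")
  pool <- percentiles |>
    filter(!(.data$bin_id %in% excluded))

  shortfall <- 0L
  picks <- with_seed(seed, {
    out <- vector("list", nrow(need))
    for (i in seq_len(nrow(need))) {
      pc <- need$percentile[i]
      k <- need$k[i]
      avail <- pool$bin_id[pool$percentile == pc]
      if (length(avail) < k) {
        if (!allow_shortfall) {
          abort(sprintf(
            "percentile %d needs %d control bins but only %d are eligible (use allow_shortfall)",
            pc, k, length(avail)))
        }
        shortfall <- shortfall + (k - length(avail))
        k <- length(avail)
      }
      out[[i]] <- sample_safely(avail, k)
    }
    out
  })
  ids <- unlist(picks, use.names = FALSE)
  out <- percentiles |>
    filter(.data$bin_id %in% ids) |>
    select("bin_id", "chrom", "bin_start", "percentile") |>
    arrange(.data$chrom, .data$bin_start)
  if (shortfall > 0) {
    warn(sprintf("control sampling short by %d bin(s) across percentiles",
                 shortfall))
  }
  structure(out, class = unique(c("control_set", class(out))),
            seed = seed, shortfall = shortfall)
}
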