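## interval-track helpers ----------------------------------------------------

#' Per-cytosine level track from a cytosine table
#'
#' @param table Cytosine table.
#' @param context Context to keep.
#' @param min_coverage Minimum depth (default 4).
#' @return Signal-track tibble: `chrom`, `start`, `end` (0-based half-open,
#'   width 1), `value` (methylation level).
#' @export
level_track <- function(table, context, min_coverage = 4) {
  table |>
    filter(.data$context == !!context, .data$count_total >= min_coverage) |>
    add_level() |>
    transmute(chrom = .data$chrom, start = .data$pos - 1L, end = .data$pos,
              value = .data$level)
}

track_granges <- function(track) {
  assert_columns(track, c("chrom", "start", "end", "value"), "track")
  if (any(!is.finite(track$value))) abort("track values must be finite")
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end))
  S4Vectors::mcols(gr)$value <- track$value
  gr
}

## overlap-width-weighted mean of a track over query intervals (NA if none)
weighted_interval_means <- function(track_gr, chrom, start, end) {
  keep <- end > start
  q <- GenomicRanges::GRanges(chrom[keep],
                              IRanges::IRanges(start[keep] + 1L,
                                               pmax(end[keep], start[keep] + 1L)))
  hits <- GenomicRanges::findOverlaps(q, track_gr)
  out <- rep(NA_real_, length(chrom))
  if (length(hits) > 0) {
    ov <- IRanges::pintersect(q[S4Vectors::queryHits(hits)],
                              track_gr[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    v <- S4Vectors::mcols(track_gr)$value[S4Vectors::subjectHits(hits)]
    num <- tapply(w * v, S4Vectors::queryHits(hits), sum)
    den <- tapply(w, S4Vectors::queryHits(hits), sum)
    res <- rep(NA_real_, sum(keep))
    res[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
    out[keep] <- res
  }
  out
}

#' Scaled metaplot of a signal over a region set
#'
#' Classic gene/TE/DMR metaplot: each region's body is rescaled to
#' `n_body_bins` equal relative slices, flanks are absolute
#' (`flank_bp` split into `n_flank_bins` on each side), minus-strand regions
#' are flipped so every profile reads 5'->3' left to right, and per-slice
#' means and standard errors are taken across regions. Regions shorter than
#' `n_body_bins` positions are skipped with a message; regions with no data
#' in a slice are skipped for that slice only.
#'
#' @param track Signal-track tibble (`chrom`, `start`, `end`, `value`),
#'   e.g. from [level_track()] or [read_bedgraph()].
#' @param regions Tibble with `chrom`, `start`, `end` and `strand`.
#' @param n_body_bins Relative slices over the region body (default 20).
#' @param flank_bp Flank extent in bp on each side (default 2000).
#' @param n_flank_bins Slices per flank (default 10).
#' @return Tibble of class `meta_profile`: `bin` (1..total, 5'->3'),
#'   `zone` (upstream/body/downstream), `mean`, `se`, `n` (regions with
#'   data).
#' @export
metaplot <- function(track, regions, n_body_bins = 20, flank_bp = 2000,
                     n_flank_bins = 10) {
  assert_columns(regions, c("chrom", "start", "end", "strand"), "regions")
  if (flank_bp < 0) abort("`flank_bp` must be >= 0")
  track_gr <- track_granges(track)

  short <- (regions$end - regions$start) < n_body_bins
  if (any(short)) {
    inform(sprintf("skipping %d region(s) shorter than %d bp",
                   sum(short), n_body_bins))
    regions <- regions[!short, , drop = FALSE]
  }
  n_regions <- nrow(regions)
  if (n_regions == 0) abort("no usable region")
  use_flanks <- flank_bp > 0 && n_flank_bins > 0
  n_fl <- if (use_flanks) n_flank_bins else 0L
  total_bins <- n_body_bins + 2L * n_fl

  ## slice boundaries per region x bin, in genomic coordinates
  slices <- tidyr::expand_grid(region = seq_len(n_regions),
                               bin = seq_len(total_bins))
  rs <- regions$start[slices$region]
  re <- regions$end[slices$region]
  w <- re - rs
  minus <- regions$strand[slices$region] == "-"
  ## bin index counted 5'->3'; flip for minus-strand regions
  b <- ifelse(minus, total_bins + 1L - slices$bin, slices$bin)
  fl_w <- if (use_flanks) flank_bp / n_fl else 0

  in_up <- b <= n_fl
  in_down <- b > n_fl + n_body_bins
  in_body <- !in_up & !in_down
  k <- b - n_fl  # body slice index 1..n_body_bins
  s <- numeric(length(b))
  e <- numeric(length(b))
  s[in_up] <- rs[in_up] - flank_bp + (b[in_up] - 1) * fl_w
  e[in_up] <- rs[in_up] - flank_bp + b[in_up] * fl_w
  s[in_body] <- rs[in_body] + floor((k[in_body] - 1) * w[in_body] / n_body_bins)
  e[in_body] <- rs[in_body] + floor(k[in_body] * w[in_body] / n_body_bins)
  kd <- b - n_fl - n_body_bins
  s[in_down] <- re[in_down] + (kd[in_down] - 1) * fl_w
  e[in_down] <- re[in_down] + kd[in_down] * fl_w
  s <- floor(s); e <- ceiling(e)

  vals <- weighted_interval_means(track_gr, regions$chrom[slices$region],
                                  pmax(s, 0), pmax(e, 0))
  prof <- tibble(bin = slices$bin, value = vals) |>
    group_by(.data$bin) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              se = stats::sd(.data$value, na.rm = TRUE) /
                sqrt(sum(!is.na(.data$value))),
              n = sum(!is.na(.data$value)), .groups = "drop") |>
    mutate(mean = ifelse(.data$n > 0, .data$mean, NA_real_),
           se = ifelse(.data$n > 1, .data$se, ifelse(.data$n == 1, 0, NA_real_)),
           zone = dplyr::case_when(.data$bin <= n_fl ~ "upstream",
                                   .data$bin > n_fl + n_body_bins ~ "downstream",
                                   TRUE ~ "body")) |>
    select("bin", "zone", "mean", "se", "n")
  structure(prof, class = unique(c("meta_profile", class(prof))),
            n_regions = n_regions, n_body_bins = n_body_bins,
            flank_bp = flank_bp, n_flank_bins = n_fl)
}

#' Compare a signal between two genotype groups over regions
#'
#' Per region, the overlap-weighted mean signal over the full region or its
#' strand-aware 3' half ("last 50%"); replicate tracks within a group are
#' averaged per region first, then an unpaired Welch two-sample t-test is
#' run between the groups across regions. A zero-variance degenerate input
#' yields statistic 0 and p = 1 with a warning rather than an error.
#'
#' @param tracks_a,tracks_b A signal-track tibble or list of replicate
#'   tibbles per group.
#' @param regions Tibble with `chrom`, `start`, `end`, `strand`.
#' @param fraction `"full"` or `"last_half"` (3' half in transcriptional
#'   orientation).
#' @return List of class `signal_comparison`: `per_region` tibble,
#'   `statistic`, `p_value`, `mean_a`, `mean_b`, `n`, `fraction`.
#' @export
compare_signal <- function(tracks_a, tracks_b, regions,
                           fraction = c("full", "last_half")) {
  fraction <- match.arg(fraction)
  assert_columns(regions, c("chrom", "start", "end", "strand"), "regions")
  if (fraction == "last_half") {
    half <- (regions$end - regions$start) %/% 2
    s <- ifelse(regions$strand == "-", regions$start, regions$end - half)
    e <- ifelse(regions$strand == "-", regions$start + half, regions$end)
  } else {
    s <- regions$start
    e <- regions$end
  }
  group_means <- function(tracks) {
    if (is.data.frame(tracks)) tracks <- list(tracks)
    if (length(tracks) == 0) abort("each group needs at least one track")
    per_track <- vapply(tracks, function(tr) {
      weighted_interval_means(track_granges(tr), regions$chrom, s, e)
    }, numeric(nrow(regions)))
    rowMeans(matrix(per_track, nrow = nrow(regions)), na.rm = TRUE)
  }
  va <- group_means(tracks_a)
  vb <- group_means(tracks_b)
  keep <- is.finite(va) & is.finite(vb)
  va <- va[keep]; vb <- vb[keep]
  if (length(va) == 0) abort("no region with signal in both groups")

  if (length(va) < 2 || (sd(va) == 0 && sd(vb) == 0)) {
    warn("zero-variance signal in both groups; reporting statistic 0, p = 1")
    statistic <- 0; p <- 1
  } else {
    tt <- t.test(va, vb)
    statistic <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(
    per_region = tibble(region = which(keep), mean_a = va, mean_b = vb),
    statistic = statistic, p_value = p,
    mean_a = mean(va), mean_b = mean(vb),
    n = length(va), fraction = fraction),
    class = "signal_comparison")
}

#' @export
print.signal_comparison <- function(x, ...) {
  cat(sprintf("<signal_comparison> %s regions, fraction '%s'\n  group means %.4f vs %.4f; Welch t = %.3f, p = %.3g\n",
              x$n, x$fraction, x$mean_a, x$mean_b, x$statistic, x$p_value))
  invisible(x)
}

#' Windowed genome-wide methylation difference
#'
#' Mean per-cytosine level difference (a minus b) in fixed genomic windows,
#' for chromosome-scale curves. Windows with no shared covered cytosine get
#' `NA`; the last window of a chromosome may be short.
#'
#' @param table_a,table_b Cytosine tables on one genome.
#' @param context Context to compare.
#' @param chrom_lengths Named chromosome lengths (or `DNAStringSet`).
#' @param window_bp Window width (default 1e5).
#' @param min_coverage Minimum depth in each sample (default 4).
#' @return Tibble: `chrom`, `start`, `end`, `mean_difference`, `n_sites`.
#' @export
windowed_genome_difference <- function(table_a, table_b, context,
                                       chrom_lengths, window_bp = 1e5,
                                       min_coverage = 4) {
  if (window_bp <= 0) abort("`window_bp` must be positive")
  lens <- chrom_lengths_of(chrom_lengths)
  a <- filter(table_a, .data$context == !!context,
              .data$count_total >= min_coverage) |> add_level()
  b <- filter(table_b, .data$context == !!context,
              .data$count_total >= min_coverage) |> add_level()
  shared <- inner_join(select(a, "chrom", "pos", "strand", level_a = "level"),
                       select(b, "chrom", "pos", "strand", level_b = "level"),
                       by = c("chrom", "pos", "strand"))
  grid <- purrr::imap_dfr(as.list(lens), function(len, ch) {
    starts <- seq(0, len - 1, by = window_bp)
    tibble(chrom = ch, start = starts,
           end = pmin(starts + window_bp, len))
  })
  win <- shared |>
    mutate(start = ((.data$pos - 1) %/% window_bp) * window_bp,
           difference = .data$level_a - .data$level_b) |>
    group_by(.data$chrom, .data$start) |>
    summarise(mean_difference = mean(.data$difference),
              n_sites = dplyr::n(), .groups = "drop")
  left_join(grid, win, by = c("chrom", "start")) |>
    mutate(n_sites = tidyr::replace_na(.data$n_sites, 0L))
}
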