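#' @export
tidy.dmr_set <- function(x, ...) as_tibble(x)

#' @export
glance.dmr_set <- function(x, ...) {
  tibble(n_hyper = sum(x$direction == "hyper"),
         n_hypo = sum(x$direction == "hypo"),
         context = attr(x, "context") %||% NA_character_,
         min_diff = attr(x, "min_diff") %||% NA_real_,
         alpha = attr(x, "alpha") %||% NA_real_,
         method = attr(x, "method") %||% NA_character_,
         label = attr(x, "label") %||% NA_character_)
}

#' @export
print.dmr_set <- function(x, ...) {
  g <- glance.dmr_set(x)
  cat(sprintf("<dmr_set%s> %d hyper / %d hypo %s bins (|diff| > %.2f, p < %.2g, %s)\n",
              if (!is.na(g$label)) paste0(" ", g$label) else "",
              g$n_hyper, g$n_hypo, g$context, g$min_diff, g$alpha, g$method))
  NextMethod()
}

#' @export
tidy.heritability_report <- function(x, ...) as_tibble(x)

#' @export
glance.heritability_report <- function(x, ...) {
  tibble(n_targets = nrow(x),
         mean_pct_reference = mean(x$pct_reference, na.rm = TRUE),
         min_pct_reference = min(x$pct_reference, na.rm = TRUE),
         max_pct_reference = max(x$pct_reference, na.rm = TRUE))
}

#' @export
tidy.signal_comparison <- function(x, ...) x$per_region

#' @export
glance.signal_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         mean_a = x$mean_a, mean_b = x$mean_b, n = x$n,
         fraction = x$fraction)
}

#' @export
tidy.meta_profile <- function(x, ...) as_tibble(x)

#' @export
tidy.region_methylation <- function(x, ...) x$sites

#' @export
glance.region_methylation <- function(x, ...) {
  tibble(chrom = x$chrom, start = x$start, end = x$end,
         level = x$level, n_sites = x$n_sites,
         min_coverage = x$min_coverage)
}
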