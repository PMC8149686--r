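#' Call differentially methylated 200-bp bins
#'
#' A bin is a hyper DMR iff, in the chosen context, (i) it holds at least
#' `min_cytosines` covered cytosines in both samples (each cytosine already
#' filtered to `min_coverage` depth when the bins were built), (ii) the
#' test-minus-reference pooled level difference exceeds `min_diff`, and
#' (iii) the exact Fisher p-value on the pooled counts is below `alpha`.
#' Hypo DMRs mirror the rule with difference below `-min_diff`. All three
#' filters are conjunctive. By default p-values are used raw (no
#' multiple-testing correction), mirroring a plain per-bin significance
#' cut-off; pass `correct = "BH"` for FDR adjustment over all
#' coverage-passing bins.
#'
#' @param test,reference `bin_methylome` objects on one grid.
#' @param context Context to test (default `"CG"`).
#' @param min_cytosines Minimum covered cytosines per bin in each sample
#'   (default 4).
#' @param min_diff Minimum absolute level difference, exclusive (default
#'   0.10).
#' @param alpha Significance threshold, exclusive (default 0.05).
#' @param method `"fisher"` (exact, default) or `"score"` (normal
#'   approximation, for sensitivity analysis).
#' @param correct `"none"` (default) or `"BH"`.
#' @param label Provenance label (e.g. `"T2plus_line1"`) stored as an
#'   attribute.
#' @return A tibble of class `dmr_set`: `bin_id`, `chrom`, `bin_start`,
#'   `direction` (hyper/hypo), `p_value`, `difference`, `level_test`,
#'   `level_reference`, and the pooled counts used.
#' @export
call_dmrs <- function(test, reference, context = "CG",
                      min_cytosines = 4, min_diff = 0.10, alpha = 0.05,
                      method = c("fisher", "score"),
                      correct = c("none", "BH"), label = NULL) {
  method <- match.arg(method)
  correct <- match.arg(correct)
  tb <- filter(test, .data$context == !!context)
  rb <- filter(reference, .data$context == !!context)
  if (nrow(tb) == 0 || nrow(rb) == 0) {
    abort(sprintf("context '%s' absent from the bin methylomes", context))
  }
  same_grid(list(test, reference), context)

  j <- tibble(bin_id = tb$bin_id, chrom = tb$chrom, bin_start = tb$bin_start,
              m_test = tb$count_methylated, t_test = tb$count_total,
              n_cyt_test = tb$n_cytosines,
              m_ref = rb$count_methylated, t_ref = rb$count_total,
              n_cyt_ref = rb$n_cytosines) |>
    filter(.data$n_cyt_test >= min_cytosines,
           .data$n_cyt_ref >= min_cytosines,
           .data$t_test > 0, .data$t_ref > 0) |>
    mutate(level_test = .data$m_test / .data$t_test,
           level_reference = .data$m_ref / .data$t_ref,
           difference = .data$level_test - .data$level_reference)

  if (correct == "BH") {
    j$p_value <- p.adjust(
      test_p(j$m_test, j$t_test - j$m_test,
             j$m_ref, j$t_ref - j$m_ref, method),
      method = "BH")
  } else {
    ## p only needed where the effect-size filter can pass
    j$p_value <- NA_real_
    cand <- abs(j$difference) > min_diff
    if (any(cand)) {
      j$p_value[cand] <- test_p(j$m_test[cand], j$t_test[cand] - j$m_test[cand],
                                j$m_ref[cand], j$t_ref[cand] - j$m_ref[cand],
                                method)
    }
  }
  out <- j |>
    filter(abs(.data$difference) > min_diff, .data$p_value < alpha) |>
    mutate(direction = ifelse(.data$difference > 0, "hyper", "hypo")) |>
    select("bin_id", "chrom", "bin_start", "direction", "p_value",
           "difference", "level_test", "level_reference",
           "m_test", "t_test", "m_ref", "t_ref")
  structure(out, class = unique(c("dmr_set", class(out))),
            context = context, min_cytosines = min_cytosines,
            min_diff = min_diff, alpha = alpha, method = method,
            correct = correct, label = label)
}

test_p <- function(m1, u1, m2, u2, method) {
  if (length(m1) == 0) return(numeric(0))
  if (method == "fisher") bin_fisher_test(m1, u1, m2, u2)
  else bin_score_test(m1, u1, m2, u2)
}

#' Bin ids of a DMR set, optionally restricted to one direction
#'
#' @param x A `dmr_set`, or a character vector of bin ids (returned as-is).
#' @param direction `"hyper"`, `"hypo"` or `NULL` for all.
#' @return Character vector of bin ids.
#' @export
dmr_bins <- function(x, direction = NULL) {
  if (is.character(x)) return(x)
  stopifnot(inherits(x, "dmr_set") || is.data.frame(x))
  if (!is.null(direction)) x <- filter(x, .data$direction == !!direction)
  x$bin_id
}

#' Intersect DMR sets across lines, then union across generations
#'
#' Reproducible-hit logic for multi-line, multi-generation designs: within
#' each generation the DMRs of all lines are intersected (a bin must be
#' called in every line), and the per-generation sets are then unioned
#' across generations so no reproducible site is dropped. All sets must
#' carry the same direction.
#'
#' @param sets_by_generation Named list (one element per generation), each a
#'   list of `dmr_set` objects or bin-id vectors (one per line).
#' @param direction Direction to extract from `dmr_set` inputs (default
#'   `"hyper"`).
#' @return List: `per_generation` (named list of intersected bin-id
#'   vectors), `combined` (their union, genome-order sorted).
#' @export
combine_line_generation <- function(sets_by_generation,
                                    direction = "hyper") {
  per_gen <- lapply(sets_by_generation, function(lines) {
    if (!is.list(lines)) lines <- list(lines)
    ids <- lapply(lines, dmr_bins, direction = direction)
    Reduce(intersect, ids)
  })
  list(per_generation = per_gen,
       combined = sort(unique(unlist(per_gen, use.names = FALSE))))
}

#' Partition a DMR set by bin cluster
#'
#' @param dmrs A `dmr_set`.
#' @param clusters A `cluster_assignment` (from [assign_clusters()]).
#' @return The DMR tibble with `percentile` and `cluster` columns; DMRs on
#'   bins outside the retained/clustered set get `NA` cluster ("unassigned").
#' @export
partition_by_cluster <- function(dmrs, clusters) {
  left_join(as_tibble(dmrs),
            select(as_tibble(clusters), "bin_id", "percentile", "cluster"),
            by = "bin_id")
}

#' Track heritable DMRs through an intersection chain
#'
#' For each plan entry the heritable set is
#' `target intersect (intersection of its reference sets)`. A reference name
#' resolves first to the heritable set of an earlier plan entry (so chains
#' like "T5(-) against heritable T4(-)" compose), then to a raw input set.
#' Two percentages are reported because the denominator of a "percent
#' heritable" is ambiguous: `pct_reference` (heritable / chained reference,
#' the primary readout: of the previously established DMRs, how many
#' persist) and `pct_target` (heritable / target).
#'
#' @param sets Named list of `dmr_set` objects or bin-id vectors.
#' @param plan List of entries `list(target = "name", references =
#'   c("name", ...))`, in evaluation order.
#' @param direction Direction used when extracting bins from `dmr_set`
#'   inputs.
#' @return A tibble of class `heritability_report`: `target`, `n_target`,
#'   `n_reference`, `n_heritable`, `pct_reference`, `pct_target`. The
#'   heritable bin-id sets are attached as attribute `heritable_sets`.
#' @export
heritability_chain <- function(sets, plan, direction = "hyper") {
  resolved <- lapply(sets, dmr_bins, direction = direction)
  heritable <- list()
  rows <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    entry <- plan[[i]]
    if (is.null(entry$target) || is.null(entry$references)) {
      abort("each plan entry needs `target` and `references`")
    }
    lookup <- function(nm) {
      if (nm %in% names(heritable)) heritable[[nm]]
      else if (nm %in% names(resolved)) resolved[[nm]]
      else abort(sprintf("plan references unknown set '%s'", nm))
    }
    target_set <- lookup(entry$target)
    refs <- lapply(entry$references, lookup)
    ref_set <- Reduce(intersect, refs)
    her <- intersect(target_set, ref_set)
    heritable[[entry$target]] <- her
    n_tgt <- length(target_set)
    n_ref <- length(ref_set)
    n_her <- length(her)
    rows[[i]] <- tibble(
      target = entry$target,
      n_target = n_tgt,
      n_reference = n_ref,
      n_heritable = n_her,
      pct_reference = if (n_ref > 0) 100 * n_her / n_ref else NA_real_,
      pct_target = if (n_tgt > 0) 100 * n_her / n_tgt else NA_real_)
  }
  out <- bind_rows(rows)
  structure(out, class = unique(c("heritability_report", class(out))),
            heritable_sets = heritable, direction = direction)
}
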