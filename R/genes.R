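#' Gene-body CG methylation per gene
#'
#' Pooled, count-weighted CG level (`sum(#C)/sum(#C+#T)`) over the cytosines
#' of each gene's annotated span that reach `min_coverage`. The full
#' transcribed unit (start to end) is used by default; set
#' `exons_only = TRUE` to restrict to exonic cytosines.
#'
#' @param table Cytosine table.
#' @param annotation Annotation tibble (`id`, `chrom`, `strand`, `start`,
#'   `end` 0-based half-open, `type`, optional `exons` list-column).
#' @param genes Optional character vector of gene ids (default: every
#'   `type == "gene"` record). Unknown ids error.
#' @param context Context pooled (default `"CG"`).
#' @param min_coverage Minimum per-cytosine depth (default 4).
#' @param exons_only Restrict to exon intervals (requires the `exons`
#'   column).
#' @return Tibble: `gene_id`, `count_methylated`, `count_total`, `n_sites`,
#'   `level` (`NA` when no cytosine survives — such genes are excluded from
#'   classification downstream).
#' @export
gene_body_methylation <- function(table, annotation, genes = NULL,
                                  context = "CG", min_coverage = 4,
                                  exons_only = FALSE) {
  assert_columns(annotation, c("id", "chrom", "strand", "start", "end"),
                 "annotation")
  ann <- annotation
  if ("type" %in% names(ann) && is.null(genes)) {
    ann <- filter(ann, .data$type == "gene")
  }
  if (!is.null(genes)) {
    unknown <- setdiff(genes, ann$id)
    if (length(unknown) > 0) {
      abort(sprintf("unknown gene id(s): %s",
                    paste(head(unknown, 3), collapse = ", ")))
    }
    ann <- filter(ann, .data$id %in% genes)
  }
  if (exons_only) {
    if (!"exons" %in% names(ann)) abort("`exons_only` needs an `exons` column")
    spans <- ann |>
      select("id", "chrom", "exons") |>
      tidyr::unnest("exons")
  } else {
    spans <- select(ann, "id", "chrom", "start", "end")
  }

  sites <- table |>
    filter(.data$context == !!context, .data$count_total >= min_coverage)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, width = 1))
  span_gr <- GenomicRanges::GRanges(spans$chrom,
                                    IRanges::IRanges(spans$start + 1L,
                                                     spans$end))
  hits <- GenomicRanges::findOverlaps(site_gr, span_gr)
  agg <- tibble(
    gene_id = spans$id[S4Vectors::subjectHits(hits)],
    m = sites$count_methylated[S4Vectors::queryHits(hits)],
    t = sites$count_total[S4Vectors::queryHits(hits)]) |>
    group_by(.data$gene_id) |>
    summarise(count_methylated = sum(.data$m), count_total = sum(.data$t),
              n_sites = dplyr::n(), .groups = "drop")
  tibble(gene_id = ann$id) |>
    left_join(agg, by = "gene_id") |>
    mutate(count_methylated = tidyr::replace_na(.data$count_methylated, 0L),
           count_total = tidyr::replace_na(.data$count_total, 0L),
           n_sites = tidyr::replace_na(.data$n_sites, 0L),
           level = ifelse(.data$count_total > 0,
                          .data$count_methylated / .data$count_total,
                          NA_real_))
}

#' Classify gene-body methylation change between reference and test
#'
#' Strict-inequality thresholding: `de_novo` when the reference level is
#' below 3% and the gain (test minus reference, in absolute level) exceeds
#' 10 percentage points; `enhanced` when the reference level is above 3%
#' with the same gain requirement; everything else (including a reference
#' level of exactly 3%) is `unchanged`. Vectorised.
#'
#' @param ref_level,test_level Numeric gene-body CG levels in \[0,1\].
#' @param ref_threshold De novo / enhanced boundary on the reference level
#'   (default 0.03).
#' @param gain_threshold Minimum level gain, exclusive (default 0.10).
#' @return Character vector in `{"de_novo", "enhanced", "unchanged"}`
#'   (`NA` where either level is `NA`).
#' @export
classify_gbm_change <- function(ref_level, test_level,
                                ref_threshold = 0.03,
                                gain_threshold = 0.10) {
  gain <- test_level - ref_level
  dplyr::case_when(
    is.na(ref_level) | is.na(test_level) ~ NA_character_,
    ref_level < ref_threshold & gain > gain_threshold ~ "de_novo",
    ref_level > ref_threshold & gain > gain_threshold ~ "enhanced",
    TRUE ~ "unchanged")
}

#' Classify gbM status between wild type and an epiallele mutant
#'
#' `no_gbm`: below 1% in both; `lost`: above 40% in wild type but below 1%
#' in the mutant; `maintained`: above 40% in both; anything else `other`.
#' Strict inequalities throughout. Vectorised.
#'
#' @param wt_level,mut_level Gene-body CG levels in wild type and mutant.
#' @param gbm_threshold High-gbM boundary (default 0.40).
#' @param no_gbm_threshold Unmethylated boundary (default 0.01).
#' @return Character vector in `{"no_gbm", "lost", "maintained", "other"}`.
#' @export
classify_fwa_gbm <- function(wt_level, mut_level,
                             gbm_threshold = 0.40,
                             no_gbm_threshold = 0.01) {
  dplyr::case_when(
    is.na(wt_level) | is.na(mut_level) ~ NA_character_,
    wt_level < no_gbm_threshold & mut_level < no_gbm_threshold ~ "no_gbm",
    wt_level > gbm_threshold & mut_level < no_gbm_threshold ~ "lost",
    wt_level > gbm_threshold & mut_level > gbm_threshold ~ "maintained",
    TRUE ~ "other")
}

#' Select control genes matched on reference gbM percentile
#'
#' For each target gene, draws (seeded, without replacement) an unused
#' non-target gene whose reference gene-body methylation percentile lies
#' within `tolerance` percentiles of the target's and whose span overlaps no
#' hyper-DMR bin — i.e. genes with similar pre-existing methylation that did
#' not gain.
#'
#' @param gene_levels Tibble with `gene_id` and reference `level` for every
#'   candidate gene (genes with `NA` level are ignored).
#' @param targets Character vector of target gene ids.
#' @param annotation Annotation tibble (for gene spans).
#' @param dmrs `dmr_set` (or bin-id vector) whose bins controls must avoid.
#' @param seed Integer seed.
#' @param tolerance Percentile half-window (default 5).
#' @param bin_size Bin width used to map bin ids to intervals (default 200).
#' @param allow_shortfall Return fewer controls (with a warning) when a
#'   band is exhausted instead of erroring.
#' @return Tibble: `target_gene`, `control_gene`, `target_percentile`,
#'   `control_percentile`.
#' @export
select_control_genes <- function(gene_levels, targets, annotation, dmrs,
                                 seed, tolerance = 5, bin_size = 200,
                                 allow_shortfall = FALSE) {
  assert_columns(gene_levels, c("gene_id", "level"), "gene_levels")
  pool <- gene_levels |>
    filter(!is.na(.data$level)) |>
    mutate(percentile = as.integer(ceiling(dplyr::percent_rank(.data$level) * 99)) + 1L)

  dmr_ids <- dmr_bins(dmrs)
  overlaps_dmr <- rep(FALSE, nrow(pool))
  if (length(dmr_ids) > 0) {
    parts <- stringr::str_match(dmr_ids, "^(.*):(\\d+)$")
    dmr_gr <- GenomicRanges::GRanges(parts[, 2],
                                     IRanges::IRanges(as.integer(parts[, 3]) + 1L,
                                                      width = bin_size))
    ann <- annotation[match(pool$gene_id, annotation$id), ]
    gene_gr <- GenomicRanges::GRanges(ann$chrom,
                                      IRanges::IRanges(ann$start + 1L, ann$end))
    overlaps_dmr <- GenomicRanges::countOverlaps(gene_gr, dmr_gr) > 0
  }
  pool$overlaps_dmr <- overlaps_dmr

  tgt <- filter(pool, .data$gene_id %in% targets)
  if (nrow(tgt) == 0) {
    return(tibble(target_gene = character(0), control_gene = character(0),
                  target_percentile = integer(0),
                  control_percentile = integer(0)))
  }
  eligible <- filter(pool, !(.data$gene_id %in% targets), !.data$overlaps_dmr)

  with_seed(seed, {
    used <- character(0)
    rows <- vector("list", nrow(tgt))
    for (i in seq_len(nrow(tgt))) {
      band <- eligible |>
        filter(abs(.data$percentile - tgt$percentile[i]) <= tolerance,
               !(.data$gene_id %in% used))
      if (nrow(band) == 0) {
        if (!allow_shortfall) {
          abort(sprintf(
            "no eligible control gene within %d percentiles of %s (use allow_shortfall)",
            tolerance, tgt$gene_id[i]))
        }
        next
      }
      pick <- band[sample.int(nrow(band), 1), ]
      used <- c(used, pick$gene_id)
      rows[[i]] <- tibble(target_gene = tgt$gene_id[i],
                          control_gene = pick$gene_id,
                          target_percentile = tgt$percentile[i],
                          control_percentile = pick$percentile)
    }
    out <- bind_rows(rows)
    if (nrow(out) < nrow(tgt)) {
      warn(sprintf("%d target gene(s) left unmatched", nrow(tgt) - nrow(out)))
    }
    out
  })
}
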