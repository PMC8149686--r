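feature_categories <- c("promoter", "TTS", "exon", "intron", "TE",
                        "intergenic")

#' Annotate regions to genomic feature categories
#'
#' Each region is assigned by its midpoint with precedence
#' promoter > TTS > exon > intron > TE > intergenic. The promoter is the
#' strand-aware window from 1 kb upstream to 100 bp downstream of the TSS;
#' the TTS window mirrors it (100 bp upstream to 1 kb downstream of the
#' 3' end). Window extents are configurable.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param annotation Annotation tibble with `id`, `chrom`, `strand`,
#'   `start`, `end`, `type` (gene/TE) and an `exons` list-column for genes.
#' @param chrom_lengths Optional named lengths; regions beyond a chromosome
#'   end error when supplied.
#' @param promoter_up,promoter_down Promoter extent around the TSS
#'   (defaults 1000 and 100 bp).
#' @param tts_up,tts_down TTS-window extent around the 3' end (defaults 100
#'   and 1000 bp).
#' @return The regions with a `category` factor column; every region gets
#'   exactly one category.
#' @export
annotate_features <- function(regions, annotation, chrom_lengths = NULL,
                              promoter_up = 1000, promoter_down = 100,
                              tts_up = 100, tts_down = 1000) {
  assert_columns(regions, c("chrom", "start", "end"), "regions")
  assert_columns(annotation, c("id", "chrom", "strand", "start", "end",
                               "type"), "annotation")
  if (!is.null(chrom_lengths)) {
    lens <- chrom_lengths_of(chrom_lengths)
    bad <- regions$end > lens[regions$chrom] | regions$start < 0
    if (anyNA(bad) || any(bad)) {
      i <- which(is.na(bad) | bad)[1]
      abort(sprintf("region %s:%d-%d lies off the chromosome",
                    regions$chrom[i], regions$start[i], regions$end[i]))
    }
  }
  mid <- (regions$start + regions$end) %/% 2
  mid_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(mid + 1L, width = 1))

  genes <- filter(annotation, .data$type == "gene")
  tes <- filter(annotation, .data$type == "TE")
  plus <- genes$strand == "+"
  ## 0-based half-open windows, clipped at 0
  prom_start <- ifelse(plus, genes$start - promoter_up,
                       genes$end - promoter_down)
  prom_end <- ifelse(plus, genes$start + promoter_down,
                     genes$end + promoter_up)
  tts_start <- ifelse(plus, genes$end - tts_up, genes$start - tts_down)
  tts_end <- ifelse(plus, genes$end + tts_down, genes$start + tts_up)

  window_gr <- function(chrom, s, e) {
    s <- pmax(s, 0)
    keep <- e > s
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(s[keep] + 1L, e[keep]))
  }
  in_any <- function(gr) GenomicRanges::countOverlaps(mid_gr, gr) > 0

  exons <- genes |>
    select("chrom", "exons") |>
    tidyr::unnest("exons")

  hit_promoter <- if (nrow(genes)) in_any(window_gr(genes$chrom, prom_start,
                                                    prom_end)) else FALSE
  hit_tts <- if (nrow(genes)) in_any(window_gr(genes$chrom, tts_start,
                                               tts_end)) else FALSE
  hit_exon <- if (nrow(exons)) in_any(window_gr(exons$chrom, exons$start,
                                                exons$end)) else FALSE
  hit_gene <- if (nrow(genes)) in_any(window_gr(genes$chrom, genes$start,
                                                genes$end)) else FALSE
  hit_te <- if (nrow(tes)) in_any(window_gr(tes$chrom, tes$start,
                                            tes$end)) else FALSE

  category <- dplyr::case_when(
    hit_promoter ~ "promoter",
    hit_tts ~ "TTS",
    hit_exon ~ "exon",
    hit_gene ~ "intron",
    hit_te ~ "TE",
    TRUE ~ "intergenic")
  mutate(regions, category = factor(category, levels = feature_categories))
}

#' Observed/expected genomic-feature enrichment
#'
#' Category frequency of a region set relative to a background set (e.g.
#' hyper DMRs against their mCG-equivalent controls):
#' `O/E = freq(category | regions) / freq(category | background)`.
#'
#' @param regions,background Region tibbles (`chrom`, `start`, `end`) — or
#'   tibbles already carrying a `category` column from
#'   [annotate_features()].
#' @param annotation Annotation tibble (ignored when both inputs carry
#'   `category`).
#' @param ... Passed on to [annotate_features()].
#' @return Tibble: `category`, `n_observed`, `freq_observed`,
#'   `n_background`, `freq_background`, `oe_ratio` (`NA` where the
#'   background frequency is zero: undefined).
#' @export
observed_expected_enrichment <- function(regions, background,
                                         annotation = NULL, ...) {
  if (nrow(background) == 0) abort("`background` is empty")
  if (!"category" %in% names(regions)) {
    regions <- annotate_features(regions, annotation, ...)
  }
  if (!"category" %in% names(background)) {
    background <- annotate_features(background, annotation, ...)
  }
  obs <- table(factor(regions$category, levels = feature_categories))
  bg <- table(factor(background$category, levels = feature_categories))
  tibble(
    category = factor(feature_categories, levels = feature_categories),
    n_observed = as.integer(obs),
    freq_observed = as.numeric(obs) / sum(obs),
    n_background = as.integer(bg),
    freq_background = as.numeric(bg) / sum(bg),
    oe_ratio = ifelse(as.numeric(bg) > 0, (as.numeric(obs) / sum(obs)) /
                        (as.numeric(bg) / sum(bg)), NA_real_))
}
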