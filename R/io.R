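## Readers/writers for the pipeline's on-disk formats. Standard formats go
## through Biostrings/rtracklayer; the cytosine-report and read-calls TSV
## dialects are simulator-defined and handled with readr.

#' Write / read the per-cytosine report TSV
#'
#' Columns: chrom, pos (1-based), strand, count_methylated,
#' count_unmethylated, context, trinucleotide.
#'
#' @param table Cytosine table (`count_total` is split into
#'   methylated/unmethylated on disk). A `trinucleotide` column is written
#'   when present, `NA` otherwise.
#' @param path File path.
#' @return `write_cytosine_report()` returns `path` invisibly;
#'   `read_cytosine_report()` returns the cytosine table.
#' @export
write_cytosine_report <- function(table, path) {
  out <- table |>
    mutate(count_unmethylated = .data$count_total - .data$count_methylated,
           trinucleotide = if ("trinucleotide" %in% names(table))
             .data$trinucleotide else NA_character_) |>
    select("chrom", "pos", "strand", "count_methylated",
           "count_unmethylated", "context", "trinucleotide")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_cytosine_report
#' @export
read_cytosine_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    strand = readr::col_character(),
    count_methylated = readr::col_integer(),
    count_unmethylated = readr::col_integer(),
    context = readr::col_character(),
    trinucleotide = readr::col_character())) |>
    mutate(count_total = .data$count_methylated + .data$count_unmethylated) |>
    select("chrom", "pos", "strand", "context", "count_methylated",
           "count_total", "trinucleotide")
}

#' Write / read per-read methylation calls
#'
#' One row per read: read_id, chrom, start (1-based), strand, and the
#' ordered calls as comma-separated `pos:context:M|U` triples.
#'
#' @param reads Per-call tibble ([sample_reads()] layout).
#' @param path File path.
#' @return `write_read_calls()` returns `path` invisibly;
#'   `read_read_calls()` returns the per-call tibble.
#' @export
write_read_calls <- function(reads, path) {
  rows <- reads |>
    group_by(.data$read_id, .data$chrom, .data$start, .data$strand) |>
    summarise(calls = paste0(.data$pos, ":", .data$context, ":",
                             ifelse(.data$methylated, "M", "U"),
                             collapse = ","),
              .groups = "drop") |>
    arrange(.data$read_id)
  readr::write_tsv(rows, path)
  invisible(path)
}

#' @rdname write_read_calls
#' @export
read_read_calls <- function(path) {
  rows <- readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_integer(), strand = readr::col_character(),
    calls = readr::col_character()))
  if (nrow(rows) == 0) {
    return(tibble(read_id = character(0), chrom = character(0),
                  start = integer(0), strand = character(0),
                  pos = integer(0), context = character(0),
                  methylated = logical(0)))
  }
  parts <- stringr::str_split(rows$calls, ",")
  n <- lengths(parts)
  flat <- stringr::str_match(unlist(parts), "^(\\d+):(CG|CHG|CHH):(M|U)$")
  if (anyNA(flat[, 1])) abort("malformed call triple in read-calls file")
  tibble(
    read_id = rep.int(rows$read_id, n),
    chrom = rep.int(rows$chrom, n),
    start = rep.int(rows$start, n),
    strand = rep.int(rows$strand, n),
    pos = as.integer(flat[, 2]),
    context = flat[, 3],
    methylated = flat[, 4] == "M")
}

#' Write genome FASTA
#' @param genome Named `DNAStringSet`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write / read the gene-and-TE annotation as GFF3 (1-based inclusive)
#'
#' Genes carry their exons as child features; TEs are single features.
#'
#' @param annotation Annotation tibble (0-based half-open in memory).
#' @param path File path.
#' @return `write_annotation_gff3()` returns `path` invisibly;
#'   `read_annotation_gff3()` returns the annotation tibble.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  feat <- annotation |>
    mutate(ftype = ifelse(.data$type == "TE", "transposable_element", "gene"))
  parent_gr <- GenomicRanges::GRanges(
    feat$chrom, IRanges::IRanges(feat$start + 1L, feat$end),
    strand = feat$strand, type = feat$ftype, ID = feat$id)
  grs <- list(parent_gr)
  genes <- filter(feat, .data$type == "gene")
  if (nrow(genes) > 0 && "exons" %in% names(genes)) {
    ex <- genes |>
      select("id", "chrom", "strand", "exons") |>
      tidyr::unnest("exons")
    if (nrow(ex) > 0) {
      grs <- c(grs, list(GenomicRanges::GRanges(
        ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end),
        strand = ex$strand, type = "exon",
        ID = paste0(ex$id, ".exon", stats::ave(seq_len(nrow(ex)), ex$id,
                                               FUN = seq_along)),
        Parent = ex$id)))
    }
  }
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  parents <- df |>
    filter(.data$type %in% c("gene", "transposable_element")) |>
    transmute(id = as.character(.data$ID),
              chrom = as.character(.data$seqnames),
              strand = as.character(.data$strand),
              start = .data$start - 1L, end = .data$end,
              type = ifelse(.data$type == "gene", "gene", "TE"))
  exons <- df |>
    filter(.data$type == "exon") |>
    transmute(parent = as.character(.data$Parent),
              start = .data$start - 1L, end = .data$end)
  parents$exons <- lapply(parents$id, function(id) {
    ex <- exons[exons$parent == id, c("start", "end")]
    if (nrow(ex) == 0) {
      p <- parents[parents$id == id, ]
      ex <- tibble(start = p$start, end = p$end)
    }
    as_tibble(ex[order(ex$start), ])
  })
  arrange(parents, .data$chrom, .data$start)
}

#' Write a signal track as bedGraph
#' @param track Tibble `chrom`, `start`, `end`, `value` (0-based half-open).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph into a signal-track tibble
#' @param path File path.
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         value = S4Vectors::mcols(gr)$score)
}

#' Write bins/DMRs/controls as BED (0-based half-open)
#'
#' BED6 plus any extra columns supplied: name = bin id, score column
#' selectable (e.g. the methylation difference).
#'
#' @param regions Tibble with `chrom` and `bin_start` (width
#'   `bin_size`) or `start`/`end`.
#' @param path File path.
#' @param bin_size Width used when only `bin_start` is present.
#' @param score,name Optional column names for the BED score/name fields.
#' @param extra Character vector of additional columns to append.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, bin_size = 200, score = NULL,
                      name = "bin_id", extra = NULL) {
  df <- as_tibble(regions)
  if (!"start" %in% names(df)) {
    df$start <- df$bin_start
    df$end <- df$bin_start + bin_size
  }
  out <- tibble(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if (!is.null(name) && name %in% names(df)) df[[name]] else ".",
    score = if (!is.null(score) && score %in% names(df)) df[[score]] else 0,
    strand = if ("strand" %in% names(df)) df$strand else ".")
  for (col in extra %||% character(0)) out[[col]] <- df[[col]]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write a heritability report as TSV and JSON
#' @param report A `heritability_report`.
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_heritability_report <- function(report, path_tsv = NULL,
                                      path_json = NULL) {
  if (!is.null(path_tsv)) readr::write_tsv(as_tibble(report), path_tsv)
  if (!is.null(path_json)) {
    jsonlite::write_json(as_tibble(report), path_json, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(report)
}

#' Write the full set of simulator outputs
#'
#' FASTA genome, GFF3 annotation, accessibility bedGraph, the ground-truth
#' gain registry TSV, and (when supplied) the cytosine-report and
#' read-calls TSVs. Round-tripping the files reproduces the in-memory
#' objects.
#'
#' @param sim A `sim_genome`.
#' @param outdir Output directory (created if needed).
#' @param methylome Optional `true_methylome` (registry + true-probability
#'   table).
#' @param reads Optional per-call tibble.
#' @param table Optional cytosine table.
#' @param prefix File-name prefix (default `"sim"`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim_outputs <- function(sim, outdir, methylome = NULL, reads = NULL,
                              table = NULL, prefix = "sim") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- function(ext) file.path(outdir, paste0(prefix, ext))
  paths <- c(genome = f(".fa"), annotation = f(".gff3"),
             accessibility = f(".accessibility.bedGraph"))
  write_genome_fasta(sim$genome, paths["genome"])
  write_annotation_gff3(sim$annotation, paths["annotation"])
  write_bedgraph(dplyr::rename(sim$accessibility,
                               value = "accessibility"),
                 paths["accessibility"])
  if (!is.null(methylome)) {
    paths["registry"] <- f(".gain_registry.tsv")
    readr::write_tsv(methylome$registry, paths["registry"])
    paths["truth"] <- f(".true_methylome.tsv")
    readr::write_tsv(methylome$sites, paths["truth"])
  }
  if (!is.null(reads)) {
    paths["reads"] <- f(".read_calls.tsv")
    write_read_calls(reads, paths["reads"])
  }
  if (!is.null(table)) {
    paths["cytosine_report"] <- f(".cytosine_report.tsv")
    write_cytosine_report(table, paths["cytosine_report"])
  }
  invisible(paths)
}
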