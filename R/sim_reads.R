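#' Sample bisulfite reads from a true methylome
#'
#' Emulates aligned bisulfite reads as runs of consecutive cytosines on one
#' strand. Read starts are Poisson so that per-cytosine depth is
#' approximately Poisson(`coverage_mean`); each covered cytosine's call is
#' Bernoulli(true probability). A `nonconversion_read_fraction` of reads is
#' fully unconverted: every call comes out methylated regardless of truth,
#' which is the canonical signature (runs of methylated CHH) that the
#' conversion filter must catch.
#'
#' @param methylome A `true_methylome`.
#' @param config A [sim_config()] supplying `coverage_mean`,
#'   `read_length_cytosines` and `nonconversion_read_fraction`.
#' @param seed Seed; defaults to `config$seed + 3`.
#' @return A tibble of per-call records (one row per cytosine call):
#'   `read_id`, `chrom`, `start` (1-based position of the read's first call),
#'   `strand`, `pos`, `context`, `methylated`.
#' @export
sample_reads <- function(methylome, config, seed = config$seed + 3L) {
  stopifnot(inherits(methylome, "true_methylome"))
  sites <- arrange(methylome$sites, .data$chrom, .data$strand, .data$pos)
  L <- config$read_length_cytosines
  with_seed(seed, {
    grp <- paste(sites$chrom, sites$strand)
    n <- nrow(sites)
    ## reads starting at each cytosine index; depth ~= Poisson(coverage_mean)
    n_starts <- rpois(n, config$coverage_mean / L)
    start_idx <- rep.int(seq_len(n), n_starts)
    if (length(start_idx) == 0) {
      return(tibble(read_id = character(0), chrom = character(0),
                    start = integer(0), strand = character(0),
                    pos = integer(0), context = character(0),
                    methylated = logical(0)))
    }
    ## truncate each read at the end of its chromosome+strand block
    blocks <- rle(grp)
    grp_end <- cumsum(blocks$lengths)
    block_end <- grp_end[match(grp[start_idx], blocks$values)]
    read_len <- pmin(L, block_end - start_idx + 1L)
    read_id <- sprintf("r%07d", seq_along(start_idx))

    call_idx <- start_idx[rep.int(seq_along(start_idx), read_len)] +
      sequence(read_len) - 1L
    call_read <- rep.int(seq_along(start_idx), read_len)
    unconverted <- runif(length(start_idx)) < config$nonconversion_read_fraction
    meth <- runif(length(call_idx)) < sites$prob[call_idx]
    meth[unconverted[call_read]] <- TRUE

    tibble(
      read_id = read_id[call_read],
      chrom = sites$chrom[start_idx][call_read],
      start = sites$pos[start_idx][call_read],
      strand = sites$strand[start_idx][call_read],
      pos = sites$pos[call_idx],
      context = sites$context[call_idx],
      methylated = meth
    )
  })
}

#' Sample a per-cytosine count table directly (no read structure)
#'
#' Fast path for genome-scale simulations where read-level structure is
#' irrelevant: per-cytosine depth is Poisson(`coverage`), methylated counts
#' are Binomial(depth, true probability). Equivalent to
#' [sample_reads()] + [aggregate_cytosines()] with no unconverted reads.
#'
#' @param methylome A `true_methylome`.
#' @param coverage Mean depth per cytosine.
#' @param seed Seed.
#' @param contexts Optional subset of contexts to sample (e.g. `"CG"` for
#'   CG-only analyses).
#' @return A cytosine table tibble: `chrom`, `pos`, `strand`, `context`,
#'   `count_methylated`, `count_total` (zero-depth sites are dropped).
#' @export
sample_cytosine_counts <- function(methylome, coverage, seed,
                                   contexts = NULL) {
  stopifnot(inherits(methylome, "true_methylome"))
  sites <- methylome$sites
  if (!is.null(contexts)) sites <- filter(sites, .data$context %in% contexts)
  with_seed(seed, {
    depth <- rpois(nrow(sites), coverage)
    keep <- depth > 0
    tibble(
      chrom = sites$chrom[keep],
      pos = sites$pos[keep],
      strand = sites$strand[keep],
      context = sites$context[keep],
      count_methylated = rbinom(sum(keep), depth[keep], sites$prob[keep]),
      count_total = depth[keep]
    )
  })
}
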