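#' Simulate a toy genome with annotation and an accessibility covariate
#'
#' Generates random chromosome sequences with a plant-like base composition,
#' places gene models (with exons) on the chromosome arms and transposable
#' elements inside a centred pericentromeric window, and lays down a per-bin
#' chromatin-accessibility covariate: high over the arms, low over the
#' pericentromere and over a random subset of gene bodies. The covariate
#' exists so that "ectopic gain prefers less accessible chromatin" is a
#' testable property of the gain sampler, not a model of any real assay.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome` with elements
#'   `genome` (named [Biostrings::DNAStringSet]),
#'   `annotation` (tibble: `id`, `chrom`, `strand`, `start`, `end` 0-based
#'   half-open, `type` gene/TE, `exons` list-column of tibbles),
#'   `accessibility` (tibble on the bin grid: `chrom`, `start`, `end`,
#'   `accessibility` in \[0,1\]),
#'   `pericentromere` (tibble of the heterochromatic windows), and `config`.
#' @examples
#' sim <- simulate_genome(sim_config(seed = 7, n_chromosomes = 1,
#'                                   chrom_length_bp = 50000,
#'                                   n_genes = 10, n_tes = 5))
#' table(sim$annotation$type)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  L <- config$chrom_length_bp
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  base_probs <- c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)

  seqs <- vapply(chroms, function(ch) {
    paste(sample(names(base_probs), L, replace = TRUE, prob = base_probs),
          collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  peri_len <- round(config$pericentromere_fraction * L / config$bin_size) *
    config$bin_size
  peri_start <- ((L - peri_len) %/% 2 %/% config$bin_size) * config$bin_size
  pericentromere <- tibble(chrom = chroms,
                           start = peri_start,
                           end = peri_start + peri_len)

  genes <- place_features(chroms, config$n_genes, config$gene_length_range,
                          arms = TRUE, peri_start, peri_start + peri_len, L,
                          prefix = "gene")
  tes <- place_features(chroms, config$n_tes, config$te_length_range,
                        arms = FALSE, peri_start, peri_start + peri_len, L,
                        prefix = "TE")
  genes$type <- "gene"
  tes$type <- "TE"
  genes$exons <- purrr::pmap(list(genes$start, genes$end), make_exons)
  tes$exons <- purrr::map2(tes$start, tes$end,
                           ~ tibble(start = .x, end = .y))
  annotation <- bind_rows(genes, tes) |>
    arrange(.data$chrom, .data$start)

  accessibility <- accessibility_track(chroms, L, config$bin_size,
                                       peri_start, peri_start + peri_len,
                                       genes)

  structure(list(genome = genome,
                 annotation = annotation,
                 accessibility = accessibility,
                 pericentromere = pericentromere,
                 config = config),
            class = "sim_genome")
}

## Non-overlapping placement by slotting: the available space (arms or
## pericentromere) is cut into one slot per feature and each feature sits at
## a random offset inside its slot.
place_features <- function(chroms, n, length_range, arms,
                           peri_start, peri_end, L, prefix) {
  n_chrom <- length(chroms)
  per_chrom <- diff(c(0, round(seq_len(n_chrom) * n / n_chrom)))
  out <- vector("list", n_chrom)
  idx0 <- 0L
  for (i in seq_len(n_chrom)) {
    k <- per_chrom[i]
    if (k == 0) { out[[i]] <- NULL; next }
    if (arms) {
      spaces <- tibble(s = c(0, peri_end), e = c(peri_start, L))
    } else {
      spaces <- tibble(s = peri_start, e = peri_end)
    }
    spaces <- spaces[spaces$e > spaces$s, , drop = FALSE]
    total <- sum(spaces$e - spaces$s)
    k_per_space <- diff(c(0, round(cumsum(spaces$e - spaces$s) * k / total)))
    rows <- list()
    fid <- 0L
    for (j in seq_len(nrow(spaces))) {
      kj <- k_per_space[j]
      if (kj == 0) next
      slot <- (spaces$e[j] - spaces$s[j]) %/% kj
      if (slot <= length_range[2]) {
        abort(sprintf(
          "cannot place %d '%s' features of up to %d bp in %d bp of space; reduce counts or lengths",
          kj, prefix, length_range[2], spaces$e[j] - spaces$s[j]))
      }
      len <- sample(seq(length_range[1], length_range[2]), kj, replace = TRUE)
      offset <- vapply(slot - len, function(m) sample.int(m, 1) - 1L,
                       integer(1))
      start <- spaces$s[j] + (seq_len(kj) - 1L) * slot + offset
      rows[[j]] <- tibble(chrom = chroms[i], start = start,
                          end = start + len,
                          strand = sample(c("+", "-"), kj, replace = TRUE))
      fid <- fid + kj
    }
    out[[i]] <- bind_rows(rows)
    idx0 <- idx0 + k
  }
  feats <- bind_rows(out)
  feats$id <- sprintf("%s%04d", prefix, seq_len(nrow(feats)))
  feats[, c("id", "chrom", "strand", "start", "end")]
}

## 1-3 exons: odd-indexed segments between sorted interior cut points
make_exons <- function(start, end) {
  width <- end - start
  k <- sample(1:3, 1)
  if (k == 1 || width < 6 * k) {
    return(tibble(start = start, end = end))
  }
  cuts <- sort(sample(seq(start + 1, end - 1), 2 * (k - 1)))
  bounds <- c(start, cuts, end)
  idx <- seq(1, 2 * k - 1, by = 2)
  tibble(start = bounds[idx], end = bounds[idx + 1])
}

accessibility_track <- function(chroms, L, bin_size, peri_start, peri_end,
                                genes) {
  grid <- tidyr::expand_grid(chrom = chroms,
                             start = seq(0L, L - bin_size, by = bin_size)) |>
    mutate(end = .data$start + bin_size)
  mid <- grid$start + bin_size %/% 2
  in_peri <- mid >= peri_start & mid < peri_end
  acc <- ifelse(in_peri, 0.1, 0.8)

  ## a random ~30% of gene bodies are "closed": low accessibility on the arms
  if (nrow(genes) > 0) {
    closed <- genes[runif(nrow(genes)) < 0.3, , drop = FALSE]
    if (nrow(closed) > 0) {
      hit <- rep(FALSE, nrow(grid))
      for (i in seq_len(nrow(closed))) {
        hit <- hit | (grid$chrom == closed$chrom[i] &
                        mid >= closed$start[i] & mid < closed$end[i])
      }
      acc[hit] <- 0.2
    }
  }
  acc <- pmin(1, pmax(0, acc + runif(nrow(grid), -0.05, 0.05)))
  grid$accessibility <- acc
  grid
}

#' Enumerate cytosines and their sequence contexts on both strands
#'
#' Scans a genome and reports every cytosine (C on the plus strand, G on the
#' minus strand read as C 5'->3') with its CG/CHG/CHH context and
#' trinucleotide. Cytosines within two bases of a chromosome end, whose
#' context cannot be determined, are skipped with a message.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector).
#' @return Tibble: `chrom`, `pos` (1-based), `strand`, `context`,
#'   `trinucleotide`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TACGTAA"))
#' cytosine_contexts(g)
#' @export
cytosine_contexts <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chroms <- names(genome)
  if (is.null(chroms)) abort("`genome` must have named chromosomes")
  out <- vector("list", length(chroms))
  n_skipped <- 0L
  for (i in seq_along(chroms)) {
    s <- as.character(genome[[i]])
    n <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]

    cpos <- which(ch == "C")
    edge <- cpos > n - 2L
    n_skipped <- n_skipped + sum(edge)
    cpos <- cpos[!edge]
    n1 <- ch[cpos + 1L]
    n2 <- ch[cpos + 2L]
    ctx_p <- as.character(ifelse(n1 == "G", "CG",
                                 ifelse(n2 == "G", "CHG", "CHH")))
    tri_p <- if (length(cpos)) paste0("C", n1, n2) else character(0)

    gpos <- which(ch == "G")
    edge <- gpos < 3L
    n_skipped <- n_skipped + sum(edge)
    gpos <- gpos[!edge]
    p1 <- ch[gpos - 1L]
    p2 <- ch[gpos - 2L]
    ctx_m <- as.character(ifelse(p1 == "C", "CG",
                                 ifelse(p2 == "C", "CHG", "CHH")))
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    tri_m <- if (length(gpos)) paste0("C", unname(comp[p1]),
                                      unname(comp[p2])) else character(0)

    out[[i]] <- tibble(
      chrom = chroms[i],
      pos = c(cpos, gpos),
      strand = rep(c("+", "-"), c(length(cpos), length(gpos))),
      context = c(ctx_p, ctx_m),
      trinucleotide = c(tri_p, tri_m)
    ) |>
      arrange(.data$pos, .data$strand)
  }
  if (n_skipped > 0) {
    inform(sprintf("skipped %d cytosine(s) with undetermined context at chromosome edges",
                   n_skipped))
  }
  bind_rows(out)
}
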