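#' Baseline (wild-type) true methylome
#'
#' Assigns a true methylation probability to every cytosine: gbM genes get
#' CG-only body methylation following a smooth mid-body dome (scaled so the
#' body-wide mean equals `gbm_body_cg_level`), TEs get CG/CHG/CHH
#' methylation at `te_levels`, and everything else sits at the configured
#' background (0 by default). Which genes are gbM is drawn once, seeded.
#'
#' @param sim A `sim_genome` from [simulate_genome()], or a list with
#'   `genome` and `annotation`.
#' @param config A [sim_config()]; defaults to `sim$config`.
#' @param seed Seed for the gbM gene draw; defaults to `config$seed + 1`.
#' @return A `true_methylome`: list with `sites` (tibble: `chrom`, `pos`,
#'   `strand`, `context`, `trinucleotide`, `baseline`, `prob`), an empty
#'   `registry` of gain regions, `generation = "G0"`, and `gbm_genes`.
#' @export
simulate_baseline_methylome <- function(sim, config = sim$config,
                                        seed = config$seed + 1L) {
  sites <- cytosine_contexts(sim$genome)
  bg <- config$background_levels
  prob <- unname(bg[sites$context])
  prob[is.na(prob)] <- 0

  genes <- filter(sim$annotation, .data$type == "gene")
  gbm_ids <- character(0)
  if (nrow(genes) > 0 && config$fraction_gbm_genes > 0) {
    n_gbm <- round(config$fraction_gbm_genes * nrow(genes))
    gbm_ids <- with_seed(seed, sample_safely(genes$id, n_gbm))
  }
  gbm <- filter(genes, .data$id %in% gbm_ids)
  for (i in seq_len(nrow(gbm))) {
    idx <- which(sites$chrom == gbm$chrom[i] & sites$context == "CG" &
                   sites$pos > gbm$start[i] & sites$pos <= gbm$end[i])
    if (length(idx) == 0) next
    ## relative position in transcriptional orientation
    x <- (sites$pos[idx] - 0.5 - gbm$start[i]) / (gbm$end[i] - gbm$start[i])
    if (gbm$strand[i] == "-") x <- 1 - x
    prob[idx] <- pmin(1, config$gbm_body_cg_level * gbm_dome(x))
  }

  tes <- filter(sim$annotation, .data$type == "TE")
  for (i in seq_len(nrow(tes))) {
    idx <- which(sites$chrom == tes$chrom[i] &
                   sites$pos > tes$start[i] & sites$pos <= tes$end[i])
    prob[idx] <- unname(config$te_levels[sites$context[idx]])
  }

  sites$baseline <- prob
  sites$prob <- prob
  new_true_methylome(sites, empty_registry(), "G0", gbm_genes = gbm_ids)
}

## Smooth dome over relative gene position x in [0,1], unit mean, peaking at
## 60% of gene length (x^3 (1-x)^2 has mode 0.6 and integral B(4,3) = 1/60).
gbm_dome <- function(x) 60 * x^3 * (1 - x)^2

empty_registry <- function() {
  tibble(region_id = character(0), chrom = character(0),
         start = integer(0), end = integer(0),
         established = character(0), retained = logical(0),
         lost_generation = character(0))
}

new_true_methylome <- function(sites, registry, generation, gbm_genes) {
  structure(list(sites = sites, registry = registry,
                 generation = generation, gbm_genes = gbm_genes),
            class = "true_methylome")
}

#' @export
print.true_methylome <- function(x, ...) {
  cat(sprintf("<true_methylome> generation %s: %d cytosines, %d gain region(s) (%d retained)\n",
              x$generation, nrow(x$sites), nrow(x$registry),
              sum(x$registry$retained)))
  invisible(x)
}

#' Establish ectopic CG-only gains
#'
#' Samples gain regions on the analysis grid with probability increasing as
#' accessibility decreases (weight `exp(-accessibility_bias * accessibility)`)
#' and preferentially within gene bodies (`1 + genebody_bias` multiplier),
#' then raises each eligible CG site in a gained region by
#' `ectopic_gain_level` (capped at 1). CHG and CHH probabilities are never
#' touched, and CG sites already at or above `saturation_level` are never
#' eligible. The established regions are recorded in the gain registry so
#' heritability can be tracked through [propagate_generation()].
#'
#' Three establishment modes: a per-bin rate (`ectopic_gain_rate`), an exact
#' region count (`ectopic_gain_n`, weighted sampling without replacement), or
#' a genome-wide mean-gain target (`target_mean_cg_gain`, which calibrates
#' the weight scaling so the expected mean CG-level gain over all CG sites
#' hits the target, accounting for capping).
#'
#' @param methylome A baseline `true_methylome`.
#' @param sim The `sim_genome` (for annotation and accessibility).
#' @param config A [sim_config()].
#' @param seed Seed for region sampling; defaults to `config$seed + 2`.
#' @param generation Label for the generation of establishment.
#' @return A new `true_methylome` with updated `prob` and a populated
#'   gain registry.
#' @export
simulate_ectopic_gain <- function(methylome, sim, config = sim$config,
                                  seed = config$seed + 2L,
                                  generation = "G1") {
  stopifnot(inherits(methylome, "true_methylome"))
  sites <- methylome$sites
  region_bp <- config$bin_size * config$gain_region_bins

  cg <- sites$context == "CG"
  eligible_site <- cg & sites$prob < config$saturation_level
  region_start <- ((sites$pos - 1L) %/% region_bp) * region_bp

  ## per-region tallies of eligible CG sites and realisable gain mass
  key <- bin_id(sites$chrom, region_start)
  gain_at_site <- pmin(1, sites$prob + config$ectopic_gain_level) - sites$prob
  gain_at_site[!eligible_site] <- 0
  reg <- tibble(key = key, cg = cg, eligible = eligible_site,
                gmass = gain_at_site,
                chrom = sites$chrom, start = region_start) |>
    group_by(.data$key, .data$chrom, .data$start) |>
    summarise(n_eligible = sum(.data$eligible),
              n_cg = sum(.data$cg),
              gain_mass = sum(.data$gmass), .groups = "drop") |>
    ## a region must be able to express a visible pooled gain: mostly
    ## saturated (heterochromatic) regions are not establishment targets
    filter(.data$n_eligible > 0,
           .data$gain_mass / pmax(.data$n_cg, 1) > config$min_region_gain)

  if (nrow(reg) == 0 ||
      (is.null(config$ectopic_gain_n) && is.null(config$target_mean_cg_gain) &&
         config$ectopic_gain_rate == 0)) {
    return(new_true_methylome(sites, methylome$registry, generation,
                              methylome$gbm_genes))
  }

  ## sampling weights: low accessibility and gene bodies attract gains
  acc <- sim$accessibility
  acc_region <- acc |>
    mutate(rstart = (.data$start %/% region_bp) * region_bp) |>
    group_by(.data$chrom, rstart = .data$rstart) |>
    summarise(accessibility = mean(.data$accessibility), .groups = "drop")
  reg <- left_join(reg, acc_region,
                   by = c("chrom", "start" = "rstart"))
  reg$accessibility[is.na(reg$accessibility)] <- mean(acc$accessibility)

  genes <- filter(sim$annotation, .data$type == "gene")
  mid <- reg$start + region_bp / 2
  in_gene <- rep(FALSE, nrow(reg))
  for (i in seq_len(nrow(genes))) {
    in_gene <- in_gene | (reg$chrom == genes$chrom[i] &
                            mid >= genes$start[i] & mid < genes$end[i])
  }
  w <- exp(-config$accessibility_bias * reg$accessibility) *
    (1 + config$genebody_bias * in_gene)

  gained <- with_seed(seed, {
    if (!is.null(config$ectopic_gain_n)) {
      n <- config$ectopic_gain_n
      if (n > nrow(reg)) {
        abort(sprintf("ectopic_gain_n = %d exceeds the %d eligible regions",
                      n, nrow(reg)))
      }
      seq_len(nrow(reg)) %in% sample(seq_len(nrow(reg)), n, prob = w)
    } else if (!is.null(config$target_mean_cg_gain)) {
      ## quota sampling: take regions in weighted random order until the
      ## accumulated gain mass meets the genome-wide target, so the realised
      ## mean CG gain matches the target to within one region's mass
      required <- config$target_mean_cg_gain * sum(cg)
      if (required > sum(reg$gain_mass)) {
        abort("target_mean_cg_gain is unattainable: not enough eligible CG gain mass")
      }
      ord <- order(runif(nrow(reg))^(1 / w), decreasing = TRUE)
      cum <- cumsum(reg$gain_mass[ord])
      k <- min(findInterval(required, cum) + 1L, length(cum))
      ## drop the last region if stopping short lands closer to the target
      if (k > 1 && abs(cum[k - 1] - required) < abs(cum[k] - required)) {
        k <- k - 1L
      }
      seq_len(nrow(reg)) %in% ord[seq_len(k)]
    } else {
      p <- pmin(1, config$ectopic_gain_rate * w / mean(w))
      runif(nrow(reg)) < p
    }
  })

  reg_gained <- reg[gained, , drop = FALSE]
  new_regs <- tibble(
    region_id = bin_id(reg_gained$chrom, reg_gained$start),
    chrom = reg_gained$chrom,
    start = reg_gained$start,
    end = reg_gained$start + region_bp,
    established = generation,
    retained = TRUE,
    lost_generation = NA_character_
  )

  hit <- key %in% new_regs$region_id & eligible_site
  sites$prob[hit] <- pmin(1, sites$prob[hit] + config$ectopic_gain_level)

  new_true_methylome(sites, bind_rows(methylome$registry, new_regs),
                     generation, methylome$gbm_genes)
}

#' Propagate a methylome one generation
#'
#' Each still-retained gain region survives independently with probability
#' `r`; lost regions revert their CG sites to the baseline probability.
#' Baseline (pre-existing) methylation always persists, and no new gain
#' region is ever created here.
#'
#' @param methylome A `true_methylome` with a gain registry.
#' @param r Per-generation retention probability in \[0,1\].
#' @param seed Seed for the retention draw.
#' @param generation Label for the new generation; by default bumps a
#'   trailing integer in the current label (`"G1"` -> `"G2"`).
#' @return The propagated `true_methylome`.
#' @export
propagate_generation <- function(methylome, r, seed,
                                 generation = NULL) {
  stopifnot(inherits(methylome, "true_methylome"))
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 1) {
    abort("`r` must be a single probability in [0, 1]")
  }
  if (is.null(generation)) {
    k <- suppressWarnings(as.integer(sub("^\\D*", "", methylome$generation)))
    generation <- if (is.na(k)) paste0(methylome$generation, "+1") else
      sub("\\d+$", k + 1L, methylome$generation)
  }
  registry <- methylome$registry
  sites <- methylome$sites
  alive <- which(registry$retained)
  if (length(alive) > 0) {
    keep <- with_seed(seed, runif(length(alive)) < r)
    lost <- alive[!keep]
    if (length(lost) > 0) {
      registry$retained[lost] <- FALSE
      registry$lost_generation[lost] <- generation
      ## regions are grid-aligned, so match sites by their region key per width
      revert <- rep(FALSE, nrow(sites))
      widths <- registry$end[lost] - registry$start[lost]
      for (w in unique(widths)) {
        ids <- registry$region_id[lost[widths == w]]
        key <- bin_id(sites$chrom, ((sites$pos - 1L) %/% w) * w)
        revert <- revert | key %in% ids
      }
      revert <- revert & sites$context == "CG"
      sites$prob[revert] <- sites$baseline[revert]
    }
  }
  new_true_methylome(sites, registry, generation, methylome$gbm_genes)
}
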