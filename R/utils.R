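## shared small helpers (internal)

## keys must never hit scientific notation, so force integer rendering
bin_id <- function(chrom, bin_start) paste0(chrom, ":", as.integer(bin_start))

#' @noRd
assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be a single %s value, got %s",
                  name, if (open) "(0,1)" else "[0,1]", format(x)[1]))
  }
  invisible(x)
}

assert_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer", name))
  }
  invisible(as.integer(x))
}

## chromosome lengths as a named integer vector from a DNAStringSet or
## named numeric vector
chrom_lengths_of <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    abort("`genome` must be a named DNAStringSet or a named length vector")
  }
}

## seeded evaluation that leaves the caller's RNG state untouched
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

## sample() without the length-1 surprise
sample_safely <- function(x, size) {
  x[sample.int(length(x), size)]
}
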