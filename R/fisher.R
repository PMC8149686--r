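#' Exact two-sided Fisher test for binned methylation counts
#'
#' Vectorised exact test of the 2x2 table
#' `[[m1, u1], [m2, u2]]` (methylated/unmethylated counts of a bin in two
#' samples). The two-sided p-value is the hypergeometric tail sum over all
#' tables with fixed margins whose probability does not exceed that of the
#' observed table (with the conventional `1 + 1e-7` relative guard against
#' floating-point ties). Inputs recycle to a common length; tables sharing
#' margins are solved once.
#'
#' @param m1,u1 Methylated / unmethylated counts in the test sample.
#' @param m2,u2 Methylated / unmethylated counts in the reference sample.
#' @return Numeric vector of two-sided p-values.
#' @examples
#' bin_fisher_test(8, 2, 2, 8)       # 2 * 2126 / 184756
#' bin_fisher_test(5, 5, 5, 5)       # 1
#' @export
bin_fisher_test <- function(m1, u1, m2, u2) {
  n <- max(length(m1), length(u1), length(m2), length(u2))
  m1 <- rep_len(as.numeric(m1), n); u1 <- rep_len(as.numeric(u1), n)
  m2 <- rep_len(as.numeric(m2), n); u2 <- rep_len(as.numeric(u2), n)
  if (any(c(m1, u1, m2, u2) < 0) || anyNA(c(m1, u1, m2, u2))) {
    abort("counts must be non-negative and non-missing")
  }
  n1 <- m1 + u1
  n2 <- m2 + u2
  if (any(n1 + n2 == 0)) abort("at least one margin must be positive")
  K <- m1 + m2

  p <- numeric(n)
  key <- paste(n1, n2, K)
  for (g in split(seq_len(n), key)) {
    gn1 <- n1[g[1]]; gn2 <- n2[g[1]]; gK <- K[g[1]]
    lo <- max(0, gK - gn2)
    hi <- min(gK, gn1)
    pmf <- dhyper(lo:hi, gn1, gn2, gK)
    ord <- order(pmf)
    cum <- cumsum(pmf[ord])
    obs <- pmf[m1[g] - lo + 1L]
    idx <- findInterval(obs * (1 + 1e-7), pmf[ord])
    p[g] <- pmin(1, cum[pmax(idx, 1L)])
  }
  p
}

## Normal-approximation score test on the difference of two proportions,
## offered as a sensitivity-analysis alternative to the exact test.
bin_score_test <- function(m1, u1, m2, u2) {
  n1 <- m1 + u1
  n2 <- m2 + u2
  p_pool <- (m1 + m2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- (m1 / n1 - m2 / n2) / se
  p <- 2 * pnorm(-abs(z))
  p[!is.finite(z)] <- 1
  p
}
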