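#' Weir-Cockerham FST between two populations
#'
#' Per-locus theta-hat from the Weir & Cockerham (1984) variance components
#' a (among populations), b (among individuals within populations) and c
#' (within individuals), for two populations and biallelic loci, using the
#' observed heterozygote proportions (the full 1984 estimator, not a
#' Hardy-Weinberg shortcut). The multilocus estimate is the ratio of sums
#' `sum(a) / sum(a + b + c)` over loci where the denominator is defined.
#'
#' Loci monomorphic in both populations (or without data in either) have no
#' defined theta; they get `NA` and are listed in the `undefined` attribute.
#' Negative per-locus estimates are expected sampling noise and are retained.
#'
#' @param counts_a,counts_b `allele_counts` tables (with heterozygote counts)
#'   over the same locus list.
#' @return A `data.frame` with columns `locus_id`, `a`, `b`, `c`, `theta`;
#'   attributes `multilocus` (ratio-of-sums estimate) and `undefined`
#'   (locus ids with `a + b + c = 0` or missing data).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fst <- function(counts_a, counts_b) {
  if (!identical(counts_a$locus_id, counts_b$locus_id)) {
    stop("allele-count tables must share an identical locus list")
  }
  r <- 2                                   # number of populations
  n1 <- counts_a$n_ind
  n2 <- counts_b$n_ind
  p1 <- counts_a$n_alt / counts_a$n_total
  p2 <- counts_b$n_alt / counts_b$n_total
  h1 <- counts_a$n_het / counts_a$n_ind    # observed het proportions
  h2 <- counts_b$n_het / counts_b$n_ind

  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2

  denom <- a + b + cc
  theta <- a / denom
  bad <- !is.finite(denom) | denom == 0
  theta[bad] <- NA_real_

  out <- data.frame(locus_id = counts_a$locus_id, a = a, b = b, c = cc,
                    theta = theta, stringsAsFactors = FALSE)
  ok <- !bad
  attr(out, "multilocus") <- sum(a[ok]) / sum(denom[ok])
  attr(out, "undefined") <- counts_a$locus_id[bad]
  out
}

#' Multilocus FST (ratio of sums)
#'
#' @param fst A result of [wc_fst()].
#' @return The multilocus Weir-Cockerham estimate.
#' @export
multilocus_fst <- function(fst) attr(fst, "multilocus")
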