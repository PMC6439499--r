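#' Genotypic linkage disequilibrium r-squared
#'
#' Composite genotypic LD between two loci: the squared Pearson correlation of
#' the 0/1/2 alt-allele dosage vectors over individuals non-missing at both
#' loci. Genotypes are unphased, so this phase-free measure (equivalent in
#' purpose to the Burrows composite measure) is used for marker-independence
#' pruning.
#'
#' Undefined cases - fewer than two shared individuals, or either locus
#' monomorphic on the shared set - return `NA_real_`. Panel selection treats
#' `NA` as "fails the LD filter" so that degenerate loci can never pass on a
#' technicality.
#'
#' @param gm A [genotype_matrix()].
#' @param locus_x,locus_y Locus ids (or column indices).
#' @return r-squared in `[0, 1]`, or `NA_real_` when undefined.
#' @export
ld_r2 <- function(gm, locus_x, locus_y) {
  stopifnot(inherits(gm, "genotype_matrix"))
  jx <- if (is.character(locus_x)) match(locus_x, gm$loci$locus_id) else locus_x
  jy <- if (is.character(locus_y)) match(locus_y, gm$loci$locus_id) else locus_y
  if (is.na(jx) || is.na(jy)) stop("unknown locus id")
  x <- gm$dosage[, jx]
  y <- gm$dosage[, jy]
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 2L) return(NA_real_)
  x <- x[keep]
  y <- y[keep]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}
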