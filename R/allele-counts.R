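#' Per-locus allele counts from genotypes
#'
#' Summarises a genotype matrix into per-locus alt-allele counts, total
#' non-missing allele copies, and the observed heterozygote counts needed by
#' the Weir-Cockerham FST estimator. Counts always derive from complete
#' diploid genotypes, so `n_total` is even.
#'
#' @param gm A [genotype_matrix()].
#' @param subset Character vector of individual ids to count over, or `NULL`
#'   for all individuals.
#' @return An object of class `allele_counts`: a `data.frame` with columns
#'   `locus_id`, `n_alt` (alt allele copies), `n_total` (non-missing allele
#'   copies), `n_het` (observed heterozygotes), `n_ind` (non-missing
#'   individuals). Loci genotyped in no individual have `n_total = 0` and are
#'   flagged in the `all_missing` attribute.
#' @export
allele_counts <- function(gm, subset = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  if (!is.null(subset)) {
    if (length(subset) == 0L) stop("empty individual subset")
    miss <- setdiff(subset, rownames(d))
    if (length(miss)) stop("unknown individuals: ", paste(miss, collapse = ", "))
    d <- d[subset, , drop = FALSE]
  }
  obs <- !is.na(d)
  out <- data.frame(
    locus_id = gm$loci$locus_id,
    n_alt = as.integer(colSums(d, na.rm = TRUE)),
    n_total = 2L * as.integer(colSums(obs)),
    n_het = as.integer(colSums(d == 1L, na.rm = TRUE)),
    n_ind = as.integer(colSums(obs)),
    stringsAsFactors = FALSE
  )
  attr(out, "all_missing") <- out$locus_id[out$n_total == 0L]
  class(out) <- c("allele_counts", "data.frame")
  out
}

#' Alt-allele sample frequencies
#'
#' @param counts An `allele_counts` table.
#' @return Numeric vector `n_alt / n_total`, named by locus; `NaN` where a
#'   locus has no data.
#' @export
allele_freq <- function(counts) {
  stats::setNames(counts$n_alt / counts$n_total, counts$locus_id)
}

#' Bundle reference-population allele counts into a baseline set
#'
#' A baseline set holds one allele-count table per named reference population
#' over a shared locus list; assignment likelihoods condition on it.
#'
#' @param ... Named `allele_counts` tables (at least two), e.g.
#'   `baseline_set(east = ce, west = cw)`.
#' @param provenance Optional free-text description (e.g. pooled sampling
#'   years).
#' @return An object of class `baseline_set`: list with `labels`, `counts`
#'   (named list of tables) and `provenance`.
#' @export
baseline_set <- function(..., provenance = "") {
  counts <- list(...)
  if (length(counts) == 1L && is.list(counts[[1]]) &&
      !inherits(counts[[1]], "data.frame")) {
    counts <- counts[[1]]
  }
  if (length(counts) < 2L) stop("a baseline set needs at least 2 populations")
  labels <- names(counts)
  if (is.null(labels) || any(labels == "")) stop("populations must be named")
  ids <- counts[[1]]$locus_id
  for (k in seq_along(counts)) {
    if (!identical(counts[[k]]$locus_id, ids)) {
      stop("all populations must share an identical locus list")
    }
  }
  structure(list(labels = labels, counts = counts, provenance = provenance),
            class = "baseline_set")
}

#' Pool allele counts across samples of the same population
#'
#' Used to pool baseline samples from different years into a single
#' assignment baseline by summing allele and heterozygote counts locus-wise.
#'
#' @param ... `allele_counts` tables over the same locus list.
#' @return A pooled `allele_counts` table.
#' @export
pool_counts <- function(...) {
  tabs <- list(...)
  ids <- tabs[[1]]$locus_id
  out <- tabs[[1]]
  for (k in seq_along(tabs)[-1]) {
    if (!identical(tabs[[k]]$locus_id, ids)) stop("locus lists differ")
    for (col in c("n_alt", "n_total", "n_het", "n_ind")) {
      out[[col]] <- out[[col]] + tabs[[k]][[col]]
    }
  }
  attr(out, "all_missing") <- out$locus_id[out$n_total == 0L]
  out
}

#' Restrict an allele-count table to a locus subset
#'
#' @param counts An `allele_counts` table.
#' @param loci Character vector of locus ids, in the desired order.
#' @return The subset table.
#' @export
subset_counts <- function(counts, loci) {
  idx <- match(loci, counts$locus_id)
  if (anyNA(idx)) {
    stop("unknown loci: ", paste(loci[is.na(idx)], collapse = ", "))
  }
  out <- counts[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_missing") <- out$locus_id[out$n_total == 0L]
  class(out) <- c("allele_counts", "data.frame")
  out
}
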