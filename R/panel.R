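#' Rank loci by FST
#'
#' Dense 1-based ranking of loci by descending per-locus Weir-Cockerham theta.
#' Loci with undefined theta (monomorphic in both populations) are dropped.
#' Ties are broken deterministically by lexicographic locus id.
#'
#' @param fst A result of [wc_fst()].
#' @return A `data.frame` with columns `locus_id`, `fst`, `rank`, ordered by
#'   rank.
#' @export
rank_loci_by_fst <- function(fst) {
  keep <- !is.na(fst$theta)
  out <- data.frame(locus_id = fst$locus_id[keep], fst = fst$theta[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fst, out$locus_id), , drop = FALSE]
  # dense rank: equal fst shares a rank
  out$rank <- match(out$fst, unique(out$fst))
  rownames(out) <- NULL
  out
}

#' Genome-spread locus selection on a linkage map
#'
#' Selects markers spread across the genome by a greedy scan: within each
#' linkage group, loci are visited in ascending map position (ties by locus
#' id) and a locus is kept iff its distance from the last kept locus is at
#' least `min_cm`; the first locus of every group is always kept. This is the
#' procedure that yields the map-spread panel used for the hybridization test.
#'
#' @param loci A locus table (see [locus_table()]); every locus must have a
#'   linkage group and a finite map position.
#' @param min_cm Minimum spacing in centimorgans (default 1).
#' @return Character vector of selected locus ids, in map order.
#' @export
spread_select <- function(loci, min_cm = 1.0) {
  if (nrow(loci) == 0L) return(character(0))
  bad <- is.na(loci$linkage_group) | is.na(loci$map_pos)
  if (any(bad)) {
    stop("loci without map position or linkage group: ",
         paste(loci$locus_id[bad], collapse = ", "))
  }
  ord <- order(loci$linkage_group, loci$map_pos, loci$locus_id)
  loci <- loci[ord, , drop = FALSE]
  selected <- character(0)
  for (lg in unique(loci$linkage_group)) {
    sub <- loci[loci$linkage_group == lg, , drop = FALSE]
    last <- -Inf
    for (k in seq_len(nrow(sub))) {
      if (sub$map_pos[k] - last >= min_cm) {
        selected <- c(selected, sub$locus_id[k])
        last <- sub$map_pos[k]
      }
    }
  }
  selected
}

#' High-grade a maximum-power assignment panel
#'
#' Greedy panel selection in descending-FST rank order: a candidate locus is
#' accepted iff, against every already accepted locus, its genotypic LD
#' satisfies `r2 < r2_within_lg` when both loci are on the same linkage group
#' and `r2 < r2_between_lg_max` when on different groups (strict
#' inequalities). Selection stops when `panel_size` loci are accepted or the
#' candidates run out. Undefined r-squared (monomorphic pair member, no shared
#' individuals) conservatively fails the filter.
#'
#' Pooling two divergent populations manufactures mixture LD between any two
#' differentiated loci, which would veto every high-FST pair; LD is therefore
#' measured within population samples. Pass a single genotype matrix, or a
#' list of matrices (one per baseline) in which case the constraint is
#' applied to the maximum r-squared across them (conservative).
#'
#' @param ranked Ranking from [rank_loci_by_fst()] (columns `locus_id`,
#'   `fst`, `rank`).
#' @param gm Genotype matrix used to measure LD, or a list of genotype
#'   matrices sharing the locus list (LD screened within each).
#' @param panel_size Target number of loci (default 39).
#' @param r2_within_lg Within-linkage-group threshold (default 0.01).
#' @param r2_between_lg_max Between-group threshold (default 0.25).
#' @return An object of class `panel_selection`: list with `selected`
#'   (locus ids in acceptance order), `audit` (`data.frame` of every
#'   considered candidate: `locus_id`, `fst`, `rank`, `status` in
#'   `none | within_lg_r2 | between_lg_r2 | monomorphic | undefined_r2`),
#'   and `complete` (`FALSE`, with a warning, when fewer than `panel_size`
#'   eligible loci exist).
#' @export
high_grade_panel <- function(ranked, gm, panel_size = 39,
                             r2_within_lg = 0.01, r2_between_lg_max = 0.25) {
  gms <- if (inherits(gm, "genotype_matrix")) list(gm) else gm
  stopifnot(all(vapply(gms, inherits, logical(1), "genotype_matrix")),
            panel_size >= 1)
  idx <- match(ranked$locus_id, gms[[1]]$loci$locus_id)
  if (anyNA(idx)) {
    stop("ranked loci absent from genotype matrix: ",
         paste(ranked$locus_id[is.na(idx)], collapse = ", "))
  }
  lg <- gms[[1]]$loci$linkage_group[idx]
  ds <- lapply(gms, function(g) g$dosage[, idx, drop = FALSE])
  # max r2 across the samples where it is defined; undefined everywhere
  # stays NA and conservatively fails the filter
  pair_r2 <- function(k, s) {
    r2 <- vapply(ds, function(d) ld_r2_cols(d[, k], d[, s]), numeric(1))
    if (all(is.na(r2))) NA_real_ else max(r2, na.rm = TRUE)
  }
  selected <- integer(0)
  status <- character(0)
  considered <- integer(0)
  for (k in seq_len(nrow(ranked))) {
    if (length(selected) >= panel_size) break
    considered <- c(considered, k)
    poly <- vapply(ds, function(d) {
      x <- d[, k]
      length(unique(x[!is.na(x)])) >= 2L
    }, logical(1))
    if (!any(poly)) {
      status <- c(status, "monomorphic")
      next
    }
    verdict <- "none"
    for (s in selected) {
      r2 <- pair_r2(k, s)
      if (is.na(r2)) { verdict <- "undefined_r2"; break }
      same_lg <- !is.na(lg[k]) && !is.na(lg[s]) && lg[k] == lg[s]
      if (same_lg && r2 >= r2_within_lg) { verdict <- "within_lg_r2"; break }
      if (!same_lg && r2 >= r2_between_lg_max) { verdict <- "between_lg_r2"; break }
    }
    status <- c(status, verdict)
    if (verdict == "none") selected <- c(selected, k)
  }
  complete <- length(selected) >= panel_size
  if (!complete) {
    warning("only ", length(selected), " eligible loci for a panel of ",
            panel_size)
  }
  audit <- data.frame(locus_id = ranked$locus_id[considered],
                      fst = ranked$fst[considered],
                      rank = ranked$rank[considered],
                      status = status, stringsAsFactors = FALSE)
  structure(list(selected = ranked$locus_id[selected], audit = audit,
                 complete = complete),
            class = "panel_selection")
}

# internal: r2 of two dosage columns, pairwise-complete (same semantics as
# ld_r2 but without re-subsetting the matrix)
ld_r2_cols <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 2L) return(NA_real_)
  x <- x[keep]; y <- y[keep]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("<panel_selection> ", length(x$selected), " loci selected (",
      nrow(x$audit), " candidates considered",
      if (!x$complete) "; INCOMPLETE" else "", ")\n", sep = "")
  invisible(x)
}
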