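#' Rannala-Mountain per-locus genotype probabilities
#'
#' Posterior-predictive genotype probabilities for a diploid biallelic locus
#' given observed baseline allele counts, under a Dirichlet prior with
#' per-allele parameter 1/k (k = 2 alleles, i.e. Beta(1/2, 1/2)). For a
#' baseline with `n_alt` alt copies out of `n_total`:
#' \deqn{P(hom.alt) = (n_{alt}+\tfrac12)(n_{alt}+\tfrac32) / ((n+1)(n+2))}
#' \deqn{P(het) = 2 (n_{alt}+\tfrac12)(n-n_{alt}+\tfrac12) / ((n+1)(n+2))}
#' and `P(hom.ref)` symmetrically. The prior mass floor guarantees a strictly
#' positive likelihood even for alleles unseen in the baseline.
#'
#' @param n_alt,n_total Integer vectors of alt and total allele copies.
#' @return Numeric matrix with one row per locus and columns `p0`, `p1`, `p2`
#'   (probability of dosage 0, 1, 2). Each row sums to 1.
#' @references Rannala, B. & Mountain, J.L. (1997) Detecting immigration by
#'   using multilocus genotypes. PNAS 94:9197-9201.
#' @export
rm_genotype_probs <- function(n_alt, n_total) {
  if (any(n_alt < 0) || any(n_total < 0) || any(n_alt > n_total)) {
    stop("invalid allele counts")
  }
  na <- n_alt + 0.5
  nr <- n_total - n_alt + 0.5
  den <- (n_total + 1) * (n_total + 2)
  cbind(p0 = nr * (nr + 1) / den,
        p1 = 2 * na * nr / den,
        p2 = na * (na + 1) / den)
}

#' Rannala-Mountain log-likelihood of one multilocus genotype
#'
#' Natural-log likelihood of a single individual's genotype under one
#' baseline: the sum over non-missing loci of the log posterior-predictive
#' genotype probabilities of [rm_genotype_probs()]. Missing loci contribute
#' nothing.
#'
#' @param dosages Integer vector of alt dosages (0/1/2/`NA`), aligned with the
#'   rows of `counts`.
#' @param counts An `allele_counts` table for one baseline population.
#' @return The log-likelihood (scalar).
#' @export
rm_log_likelihood <- function(dosages, counts) {
  if (length(dosages) != nrow(counts)) {
    stop("dosage vector and count table must be aligned")
  }
  use <- !is.na(dosages)
  if (!any(use)) stop("no usable (non-missing) loci")
  p <- rm_genotype_probs(counts$n_alt[use], counts$n_total[use])
  sum(log(p[cbind(seq_len(nrow(p)), dosages[use] + 1L)]))
}

#' Convert per-baseline log-likelihoods to 0-100 assignment scores
#'
#' The assignment score of a baseline is 100 times the ratio of its genotype
#' likelihood to the sum of the likelihoods over all baselines, computed in
#' log space so that likelihood differences of thousands of log units neither
#' underflow nor overflow.
#'
#' @param logliks Numeric vector (one individual) or matrix (individuals in
#'   rows) of per-baseline natural-log likelihoods. At least 2 baselines.
#' @return Scores on the 0-100 scale, same shape as the input; each
#'   individual's scores sum to 100.
#' @export
assignment_scores <- function(logliks) {
  vec <- is.null(dim(logliks))
  ll <- if (vec) matrix(logliks, nrow = 1) else as.matrix(logliks)
  if (ncol(ll) < 2L) stop("need at least 2 baselines")
  if (any(!is.finite(apply(ll, 1, max)))) {
    stop("all log-likelihoods are -Inf for some individual")
  }
  m <- apply(ll, 1, max)
  e <- exp(ll - m)
  sc <- 100 * e / rowSums(e)
  if (vec) drop(sc) else sc
}

# internal: n x B matrix of RM log-likelihoods for all individuals of gm
# against each baseline count table in `counts_list`; missing dosages
# contribute 0. Vectorised via one matrix product per dosage class.
rm_loglik_matrix <- function(gm, counts_list) {
  d <- gm$dosage
  out <- matrix(0, nrow(d), length(counts_list),
                dimnames = list(rownames(d), names(counts_list)))
  ind <- list(`0` = !is.na(d) & d == 0L,
              `1` = !is.na(d) & d == 1L,
              `2` = !is.na(d) & d == 2L)
  for (b in seq_along(counts_list)) {
    cb <- counts_list[[b]]
    logp <- log(rm_genotype_probs(cb$n_alt, cb$n_total))
    acc <- numeric(nrow(d))
    for (g in 0:2) acc <- acc + ind[[g + 1L]] %*% logp[, g + 1L]
    out[, b] <- acc
  }
  out
}

#' Assign mixture individuals to baselines
#'
#' Computes, for every individual, the Rannala-Mountain log-likelihood under
#' each baseline, the 0-100 assignment scores, and the assigned baseline
#' (highest score). Exact score ties are labelled `"ambiguous"`; individuals
#' with zero usable loci are labelled `"unusable"` and must be excluded from
#' downstream mixing proportions.
#'
#' @param gm Mixture [genotype_matrix()]; its loci must all be present in the
#'   baseline set.
#' @param baselines A [baseline_set()].
#' @return An object of classes `assignment_result` and `data.frame`, one row
#'   per individual: `individual_id`, `loglik_<label>` and `score_<label>`
#'   per baseline, `assigned`, `n_loci_used`.
#' @export
assign_individuals <- function(gm, baselines) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(baselines, "baseline_set"))
  counts <- lapply(baselines$counts, subset_counts, loci = gm$loci$locus_id)
  ll <- rm_loglik_matrix(gm, counts)
  n_used <- rowSums(!is.na(gm$dosage))
  usable <- n_used > 0L
  sc <- matrix(NA_real_, nrow(ll), ncol(ll))
  if (any(usable)) {
    sc[usable, ] <- assignment_scores(ll[usable, , drop = FALSE])
  }
  best <- max.col(replace(ll, !is.finite(ll), -Inf), ties.method = "first")
  assigned <- baselines$labels[best]
  ties <- apply(ll, 1, function(z) sum(z == max(z)) > 1L)
  assigned[ties] <- "ambiguous"
  assigned[!usable] <- "unusable"
  ll[!usable, ] <- NA_real_
  out <- data.frame(individual_id = rownames(gm$dosage),
                    stringsAsFactors = FALSE)
  for (b in seq_along(baselines$labels)) {
    out[[paste0("loglik_", baselines$labels[b])]] <- ll[, b]
    out[[paste0("score_", baselines$labels[b])]] <- sc[, b]
  }
  out$assigned <- assigned
  out$n_loci_used <- as.integer(n_used)
  class(out) <- c("assignment_result", "data.frame")
  out
}

#' Leave-one-out self-assignment power
#'
#' Estimates assignment power on baseline samples: each baseline individual is
#' assigned with its own two allele copies removed from its own population's
#' allele counts at every locus where it was genotyped (the other population's
#' counts are untouched), then scored as in [assign_individuals()].
#' Misassignment means the highest-scoring baseline is not the individual's
#' true population. The log10 likelihood ratio
#' `lr_log10 = (loglik_own - loglik_other) / ln 10` summarises how decisively
#' each fish assigns home. Run this on hold-out samples (not the samples used
#' to select the panel) to avoid high-grading bias.
#'
#' @param baseline_gms Named list of two [genotype_matrix()] objects over the
#'   same loci, one per baseline population; names are the population labels.
#' @return An object of class `power_report`: list with `per_population`
#'   (`data.frame`: `population`, `n`, `n_misassigned`, `misassignment_rate`)
#'   and `individuals` (`data.frame`: `individual_id`, `population`,
#'   `assigned`, `loglik_own`, `loglik_other`, `lr_log10`, `score_own`).
#' @export
loo_self_assignment <- function(baseline_gms) {
  if (length(baseline_gms) != 2L || is.null(names(baseline_gms))) {
    stop("need a named list of exactly two baseline genotype matrices")
  }
  labs <- names(baseline_gms)
  if (!identical(baseline_gms[[1]]$loci$locus_id,
                 baseline_gms[[2]]$loci$locus_id)) {
    stop("baseline genotype matrices must share a locus list")
  }
  counts <- lapply(baseline_gms, allele_counts)
  rows <- list()
  for (b in 1:2) {
    gm <- baseline_gms[[b]]
    own <- counts[[b]]
    other <- counts[[3L - b]]
    if (nrow(gm$dosage) == 1L) {
      warning("population '", labs[b], "' has a single individual; ",
              "leave-one-out leaves prior-only counts")
    }
    d <- gm$dosage
    # other-population likelihood: plain RM
    ll_other <- drop(rm_loglik_matrix(gm, stats::setNames(list(other), "o")))
    # own-population LOO likelihood: per locus, the counts seen by an
    # individual with dosage g are (n_alt - g, n_total - 2)
    ll_own <- numeric(nrow(d))
    logp_loo <- lapply(0:2, function(g) {
      nt <- pmax(own$n_total - 2L, 0L)
      # clamp keeps loci where this dosage class cannot occur (the individual
      # is missing there) numerically valid; such loci are masked out below
      na <- pmin(pmax(own$n_alt - g, 0L), nt)
      log(rm_genotype_probs(na, nt)[, g + 1L])
    })
    for (g in 0:2) {
      m <- !is.na(d) & d == g
      ll_own <- ll_own + m %*% logp_loo[[g + 1L]]
    }
    ll_own <- drop(ll_own)
    usable <- rowSums(!is.na(d)) > 0L
    assigned <- ifelse(ll_own > ll_other, labs[b],
                       ifelse(ll_own < ll_other, labs[3L - b], "ambiguous"))
    assigned[!usable] <- "unusable"
    sc <- assignment_scores(cbind(ll_own, ll_other))
    rows[[b]] <- data.frame(individual_id = rownames(d),
                            population = labs[b],
                            assigned = assigned,
                            loglik_own = ifelse(usable, ll_own, NA_real_),
                            loglik_other = ifelse(usable, ll_other, NA_real_),
                            lr_log10 = ifelse(usable,
                                              (ll_own - ll_other) / log(10),
                                              NA_real_),
                            score_own = ifelse(usable, sc[, 1], NA_real_),
                            stringsAsFactors = FALSE)
  }
  ind <- do.call(rbind, rows)
  per_pop <- do.call(rbind, lapply(labs, function(lb) {
    sub <- ind[ind$population == lb & ind$assigned != "unusable", ]
    n_mis <- sum(sub$assigned != lb)
    data.frame(population = lb, n = nrow(sub), n_misassigned = n_mis,
               misassignment_rate = n_mis / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_population = per_pop, individuals = ind),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat("<power_report>\n")
  print(x$per_population, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio summary of a power report
#'
#' Per population, the geometric mean of the individual own-vs-other
#' likelihood ratios (`10^mean(lr_log10)`) - the "average fish" ratio - plus
#' the full `lr_log10` distribution for plotting the separation of the two
#' baselines.
#'
#' @param report A [loo_self_assignment()] result.
#' @return List with `per_population` (`data.frame`: `population`,
#'   `mean_lr_log10`, `geometric_mean_lr`) and `distribution` (`data.frame`:
#'   `individual_id`, `population`, `lr_log10`).
#' @export
lr_summary <- function(report) {
  stopifnot(inherits(report, "power_report"))
  ind <- report$individuals[!is.na(report$individuals$lr_log10), ]
  if (nrow(ind) == 0L) stop("empty power report")
  per_pop <- do.call(rbind, lapply(unique(ind$population), function(lb) {
    m <- mean(ind$lr_log10[ind$population == lb])
    data.frame(population = lb, mean_lr_log10 = m,
               geometric_mean_lr = 10^m, stringsAsFactors = FALSE)
  }))
  list(per_population = per_pop,
       distribution = ind[, c("individual_id", "population", "lr_log10")])
}
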