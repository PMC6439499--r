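#' Simulate pure parental genotypes from baseline allele frequencies
#'
#' Each individual's dosage at each locus is the sum of two independent allele
#' draws with `P(alt) = p`, i.e. Hardy-Weinberg genotypes at the supplied
#' (sample) frequencies. This is the parental-simulation half of the
#' mechanical-mixing vs hybridization test.
#'
#' @param freqs Named numeric vector of alt-allele frequencies in `[0, 1]`
#'   (names become locus ids).
#' @param n Number of individuals.
#' @param seed Optional integer seed (local to this call).
#' @param prefix Individual-id prefix.
#' @return A [genotype_matrix()].
#' @export
simulate_parental <- function(freqs, n, seed = NULL, prefix = "sim") {
  stopifnot(n >= 1, all(freqs >= 0 & freqs <= 1))
  ids <- names(freqs)
  if (is.null(ids)) ids <- paste0("locus", seq_along(freqs))
  with_seed(seed, {
    d <- matrix(stats::rbinom(n * length(freqs), 2L, rep(freqs, each = n)),
                nrow = n)
    genotype_matrix(d, locus_table(ids), paste0(prefix, seq_len(n)))
  })
}

#' Simulate F1 hybrid genotypes
#'
#' Every F1 individual draws, at every locus, exactly one allele from the
#' eastern frequencies and one from the western frequencies.
#'
#' @param freqs_east,freqs_west Alt-allele frequency vectors over the same
#'   loci.
#' @inheritParams simulate_parental
#' @return A [genotype_matrix()].
#' @export
simulate_f1 <- function(freqs_east, freqs_west, n, seed = NULL,
                        prefix = "f1_") {
  if (length(freqs_east) != length(freqs_west)) stop("mismatched locus lists")
  ids <- names(freqs_east)
  if (!is.null(ids) && !is.null(names(freqs_west)) &&
      !identical(ids, names(freqs_west))) {
    stop("mismatched locus lists")
  }
  if (is.null(ids)) ids <- paste0("locus", seq_along(freqs_east))
  L <- length(ids)
  with_seed(seed, {
    d <- matrix(stats::rbinom(n * L, 1L, rep(freqs_east, each = n)) +
                  stats::rbinom(n * L, 1L, rep(freqs_west, each = n)),
                nrow = n)
    genotype_matrix(d, locus_table(ids), paste0(prefix, seq_len(n)))
  })
}

# internal: grid posterior of the two-population admixture coefficient for a
# dosage matrix (individuals x loci). Returns list(grid, log_lik [G x n]).
admixture_grid_loglik <- function(d, freqs_east, freqs_west, grid_size) {
  q <- seq(0, 1, length.out = grid_size)
  pmix_alt <- outer(q, freqs_east) + outer(1 - q, freqs_west)   # G x L
  pmix_ref <- 1 - pmix_alt
  eps <- 1e-300                               # guard log(0) at the boundary
  alt_copies <- d
  alt_copies[is.na(alt_copies)] <- 0L
  ref_copies <- 2L - d
  ref_copies[is.na(ref_copies)] <- 0L
  ll <- log(pmax(pmix_alt, eps)) %*% t(alt_copies) +
    log(pmax(pmix_ref, eps)) %*% t(ref_copies)
  list(grid = q, log_lik = ll)
}

#' Estimate individual admixture coefficients
#'
#' Two-population admixture model with known (fixed) parental allele
#' frequencies: each of an individual's allele copies is eastern with
#' probability `q` and western with probability `1 - q`, so the likelihood is
#' \deqn{L(q) = \prod_{copies} [\, q\, p_E(a) + (1-q)\, p_W(a)\,]}
#' (a heterozygote contributes one ref and one alt copy). With a Uniform(0,1)
#' prior the posterior is evaluated on a uniform grid with trapezoid
#' normalization; `q_hat` is the posterior mode and the interval is the
#' equal-tailed 95% credible interval, widened if necessary to contain the
#' mode (relevant only when the mode sits on a boundary). `q = 1` means pure
#' eastern ancestry.
#'
#' Individuals whose likelihood is flat (all informative loci missing, or
#' `p_E = p_W` everywhere) are flagged `uninformative` and reported with the
#' full `[0, 1]` interval.
#'
#' @param gm A [genotype_matrix()] (or a bare dosage matrix/vector).
#' @param freqs_east,freqs_west Parental alt-allele frequencies aligned with
#'   the loci of `gm`.
#' @param grid_size Number of grid points on `[0, 1]` (default 1001).
#' @return An object of classes `admixture_estimate` and `data.frame`:
#'   `individual_id`, `q_hat`, `ci_low`, `ci_high`, `n_loci_used`,
#'   `uninformative`.
#' @export
estimate_admixture <- function(gm, freqs_east, freqs_west, grid_size = 1001) {
  if (inherits(gm, "genotype_matrix")) {
    d <- gm$dosage
  } else if (is.null(dim(gm))) {
    d <- matrix(as.integer(gm), nrow = 1,
                dimnames = list("ind1", names(gm)))
  } else {
    d <- as.matrix(gm)
  }
  if (ncol(d) != length(freqs_east) || ncol(d) != length(freqs_west)) {
    stop("frequency vectors must be aligned with loci")
  }
  if (is.null(rownames(d))) rownames(d) <- paste0("ind", seq_len(nrow(d)))
  n_used <- rowSums(!is.na(d))
  if (all(n_used == 0L)) stop("no usable loci for any individual")
  gl <- admixture_grid_loglik(d, freqs_east, freqs_west, grid_size)
  q <- gl$grid
  ll <- gl$log_lik
  n <- ncol(ll)
  h <- q[2] - q[1]
  w <- rep(h, length(q)); w[c(1, length(q))] <- h / 2   # trapezoid weights
  q_hat <- ci_low <- ci_high <- numeric(n)
  uninf <- logical(n)
  for (i in seq_len(n)) {
    lli <- ll[, i]
    if (n_used[i] == 0L || max(lli) - min(lli) < 1e-12) {
      q_hat[i] <- 0.5; ci_low[i] <- 0; ci_high[i] <- 1; uninf[i] <- TRUE
      next
    }
    post <- exp(lli - max(lli))
    post <- post / sum(post * w)
    q_hat[i] <- q[which.max(post)]
    # cumulative trapezoid CDF, then equal-tailed interval by interpolation
    cdf <- cumsum(c(0, (post[-1] + post[-length(post)]) / 2 * h))
    cdf <- cdf / cdf[length(cdf)]
    # break exact plateaus (regions of ~zero density) so inversion is defined
    cdf <- cummax(cdf + seq_along(cdf) * 1e-15)
    ci_low[i] <- stats::approx(cdf, q, xout = 0.025, ties = "ordered")$y
    ci_high[i] <- stats::approx(cdf, q, xout = 0.975, ties = "ordered")$y
  }
  out <- data.frame(individual_id = rownames(d), q_hat = q_hat,
                    ci_low = pmin(ci_low, q_hat), ci_high = pmax(ci_high, q_hat),
                    n_loci_used = as.integer(n_used),
                    uninformative = uninf, stringsAsFactors = FALSE)
  class(out) <- c("admixture_estimate", "data.frame")
  out
}

#' Classify ancestry from an admixture credible interval
#'
#' Pure/admixed calls follow the credible-interval logic of the
#' parental-vs-F1 simulation figure: an individual is pure-western when its
#' interval overlaps 0 but not 1, pure-eastern when it overlaps 1 but not 0,
#' admixed when it excludes both boundaries, and ambiguous when it overlaps
#' both (or was flagged uninformative). "Overlaps a boundary" means the
#' interval endpoint is within `eps` of it.
#'
#' The default `eps = 0.025` (the interval's own tail mass, alpha/2) reflects
#' that an equal-tailed interval from a continuous posterior never touches
#' the boundary exactly: even when the posterior mode of a pure fish sits at
#' the boundary, the 97.5% quantile falls short of it by an amount of order
#' `0.025 * posterior width`, so a strictly-at-boundary rule would call every
#' pure fish admixed. See the methods vignette.
#'
#' @param est An [estimate_admixture()] result.
#' @param eps Boundary-overlap tolerance (default 0.025).
#' @return An object of classes `ancestry_call` and `data.frame`:
#'   `individual_id`, `call` in
#'   `pure_west | pure_east | admixed | ambiguous`.
#' @export
classify_ancestry <- function(est, eps = 0.025) {
  stopifnot(inherits(est, "admixture_estimate"))
  at0 <- est$ci_low <= eps
  at1 <- est$ci_high >= 1 - eps
  call <- ifelse(at0 & at1, "ambiguous",
                 ifelse(at0, "pure_west",
                        ifelse(at1, "pure_east", "admixed")))
  call[est$uninformative] <- "ambiguous"
  out <- data.frame(individual_id = est$individual_id, call = call,
                    stringsAsFactors = FALSE)
  class(out) <- c("ancestry_call", "data.frame")
  out
}

#' Mechanical mixing vs hybridization test
#'
#' Runs the admixture estimator and ancestry classifier on an observed mixed
#' sample and, alongside it, on simulated pure parental individuals (a 50/50
#' east/west panel) and simulated F1 hybrids built from the baseline sample
#' frequencies. If the observed fish behave like the simulated parentals
#' (credible intervals overlapping 0 or 1, never both) mixing is mechanical;
#' an excess of intermediate coefficients with intervals excluding both
#' boundaries indicates hybridization.
#'
#' @param observed [genotype_matrix()] of the mixed sample; loci must be a
#'   subset of the baseline loci.
#' @param baselines A [baseline_set()] with populations named `east` and
#'   `west` (or whose first two labels are taken as east, west).
#' @param n_sim Number of simulated individuals per panel (default 1000);
#'   the parental panel is split half east / half west.
#' @param seed Integer seed for the simulations.
#' @param grid_size Grid size for [estimate_admixture()].
#' @param eps Boundary tolerance for [classify_ancestry()].
#' @return An object of class `hybrid_test`: list with `observed`,
#'   `parental`, `f1` (each a `data.frame` of q-hat/CI/call, the parental
#'   table with a `truth` column) and `call_counts` (table of calls per
#'   panel).
#' @export
hybrid_test <- function(observed, baselines, n_sim = 1000, seed = NULL,
                        grid_size = 1001, eps = 0.025) {
  stopifnot(inherits(observed, "genotype_matrix"),
            inherits(baselines, "baseline_set"))
  labs <- baselines$labels
  east_lab <- if ("east" %in% labs) "east" else labs[1]
  west_lab <- if ("west" %in% labs) "west" else labs[2]
  loci <- observed$loci$locus_id
  fe <- allele_freq(subset_counts(baselines$counts[[east_lab]], loci))
  fw <- allele_freq(subset_counts(baselines$counts[[west_lab]], loci))
  run <- function(gm) {
    est <- estimate_admixture(gm, fe, fw, grid_size)
    est$call <- classify_ancestry(est, eps)$call
    est
  }
  n_e <- ceiling(n_sim / 2)
  n_w <- n_sim - n_e
  sim_e <- simulate_parental(fe, n_e, seed = if (is.null(seed)) NULL else
    substream_seed(seed, "parental_east"), prefix = "simE")
  sim_w <- simulate_parental(fw, n_w, seed = if (is.null(seed)) NULL else
    substream_seed(seed, "parental_west"), prefix = "simW")
  sim_f1 <- simulate_f1(fe, fw, n_sim, seed = if (is.null(seed)) NULL else
    substream_seed(seed, "f1"))
  obs <- run(observed)
  par_est <- run(rbind_genotypes(sim_e, sim_w))
  par_est$truth <- rep(c(east_lab, west_lab), c(n_e, n_w))
  f1 <- run(sim_f1)
  lv <- c("pure_west", "pure_east", "admixed", "ambiguous")
  counts <- sapply(list(observed = obs, parental = par_est, f1 = f1),
                   function(z) table(factor(z$call, levels = lv)))
  structure(list(observed = obs, parental = par_est, f1 = f1,
                 call_counts = counts),
            class = "hybrid_test")
}

#' @export
print.hybrid_test <- function(x, ...) {
  cat("<hybrid_test> call counts:\n")
  print(x$call_counts)
  invisible(x)
}

#' Plot a hybrid test (parental-vs-F1 figure analogue)
#'
#' Draws q-hat with 95% intervals for the observed sample, the simulated
#' parental panel and the simulated F1 panel in three stacked panels.
#'
#' @param x A [hybrid_test()] result.
#' @param ... Unused.
#' @export
plot.hybrid_test <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(df, main) {
    ord <- order(df$q_hat)
    df <- df[ord, ]
    n <- nrow(df)
    graphics::plot(seq_len(n), df$q_hat, ylim = c(0, 1), pch = 16, cex = 0.4,
                   xlab = "", ylab = "admixture q", main = main)
    graphics::segments(seq_len(n), df$ci_low, seq_len(n), df$ci_high,
                       col = "grey60")
    graphics::points(seq_len(n), df$q_hat, pch = 16, cex = 0.4)
    graphics::abline(h = c(0, 0.5, 1), lty = 3)
  }
  panel(x$observed, "observed")
  panel(x$parental, "simulated parental (50/50)")
  panel(x$f1, "simulated F1")
  invisible(x)
}
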