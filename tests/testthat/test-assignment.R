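# beta_integral_prob lives in helper-oracles.R

test_that("rm_genotype_probs matches the Beta-integral oracle and closed forms", {
  # spec closed forms
  expect_equal(rm_genotype_probs(9, 10)[, "p2"], (9.5 / 11) * (10.5 / 12),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rm_log_likelihood(2L, make_counts(9, 10, 0, 5)),
               log(0.7556818181818), tolerance = 1e-10)
  # allele unseen in the baseline still has positive probability
  expect_gt(rm_genotype_probs(0, 40)[, "p2"], 0)
  expect_equal(rm_genotype_probs(0, 40)[, "p2"],
               (0.5 * 1.5) / (41 * 42), ignore_attr = TRUE)
  # fixed baseline, heterozygote
  n <- 12
  expect_equal(rm_genotype_probs(n, n)[, "p1"],
               2 * (n + 0.5) * 0.5 / ((n + 1) * (n + 2)), ignore_attr = TRUE)
  # rows are distributions
  set.seed(2)
  na <- sample(0:50, 20, replace = TRUE)
  nt <- na + sample(0:50, 20, replace = TRUE)
  expect_equal(rowSums(rm_genotype_probs(na, nt)), rep(1, 20),
               tolerance = 1e-12)
  # quadrature oracle on random cases
  for (k in 1:30) {
    p <- rm_genotype_probs(na[k %% 20 + 1], nt[k %% 20 + 1])
    for (g in 0:2) {
      expect_equal(p[, g + 1], beta_integral_prob(g, na[k %% 20 + 1],
                                                  nt[k %% 20 + 1]),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
  expect_error(rm_genotype_probs(-1, 10), "invalid")
})

test_that("rm_log_likelihood sums non-missing loci and refuses empty genotypes", {
  cts <- make_counts(c(3, 7, 5), c(20, 20, 20), c(1, 3, 3), c(10, 10, 10))
  d <- c(0L, NA, 2L)
  p <- rm_genotype_probs(cts$n_alt, cts$n_total)
  expect_equal(rm_log_likelihood(d, cts),
               unname(log(p[1, 1]) + log(p[3, 3])))
  expect_error(rm_log_likelihood(c(NA_integer_, NA, NA), cts), "usable")
  expect_error(rm_log_likelihood(c(0L, 1L), cts), "aligned")
})

test_that("assignment_scores are exact ratios computed without under/overflow", {
  expect_equal(assignment_scores(c(0, 0)), c(50, 50))
  expect_equal(assignment_scores(c(log(9), 0)), c(90, 10), tolerance = 1e-12)
  big <- assignment_scores(c(50, 0))
  expect_equal(big[1], 100, tolerance = 1e-9)
  huge <- assignment_scores(c(-12345, -16345))   # |delta| = 4000 log units
  expect_equal(sum(huge), 100, tolerance = 1e-9)
  expect_false(any(!is.finite(huge)))
  # invariance to adding a constant
  ll <- matrix(rnorm(12), 4)
  expect_equal(assignment_scores(ll), assignment_scores(ll + 1000),
               tolerance = 1e-9)
  expect_equal(rowSums(assignment_scores(ll)), rep(100, 4), tolerance = 1e-9)
  expect_error(assignment_scores(matrix(1, 1, 1)), "2 baselines")
  expect_error(assignment_scores(c(-Inf, -Inf)), "-Inf")
})

test_that("assign_individuals assigns, flags ties and unusable individuals", {
  # strongly divergent baselines
  bl <- baseline_set(east = make_counts(rep(95, 20), rep(100, 20),
                                        rep(5, 20), rep(50, 20)),
                     west = make_counts(rep(5, 20), rep(100, 20),
                                        rep(5, 20), rep(50, 20)))
  east_fish <- rep(2L, 20)
  mirror_fish <- rep(1L, 20)       # heterozygous everywhere: mirrored freqs
  none_fish <- rep(NA_integer_, 20)
  gm <- make_gm(rbind(east_fish, mirror_fish, none_fish))
  res <- assign_individuals(gm, bl)
  expect_equal(res$assigned, c("east", "ambiguous", "unusable"))
  expect_gt(res$score_east[1], 99)
  expect_equal(res$score_east[2], 50, tolerance = 1e-9)
  expect_equal(res$n_loci_used, c(20L, 20L, 0L))
  expect_equal(res$score_east + res$score_west,
               c(100, 100, NA), tolerance = 1e-9)
})

test_that("simulated eastern fish assign east with near-certain scores", {
  cfg <- generator_config(n_candidate_loci = 39, inflated_frac = 1,
                          ld_block_spec = NULL, seed = 31)
  bl <- gen_baselines(cfg, n = 150)
  fish <- simulate_parental(bl$truth$freq_east, 200, seed = 1)
  blset <- baseline_set(east = allele_counts(bl$east),
                        west = allele_counts(bl$west))
  res <- assign_individuals(fish, blset)
  expect_gt(mean(res$assigned == "east"), 0.95)
  expect_gt(median(res$score_east), 99)
})

test_that("leave-one-out bookkeeping removes exactly the focal individual's alleles", {
  set.seed(9)
  east <- make_gm(matrix(rbinom(8 * 6, 2, 0.8), 4), ids = paste0("e", 1:4))
  west <- make_gm(matrix(rbinom(8 * 6, 2, 0.2), 4), ids = paste0("w", 1:4))
  pw <- loo_self_assignment(list(east = east, west = west))
  # manual recomputation for individual e2
  cts <- allele_counts(east)
  d <- east$dosage["e2", ]
  loo_cts <- make_counts(cts$n_alt - d, cts$n_total - 2L,
                         cts$n_het - (d == 1L), cts$n_ind - 1L)
  expect_equal(pw$individuals$loglik_own[pw$individuals$individual_id == "e2"],
               rm_log_likelihood(d, loo_cts), tolerance = 1e-12)
  expect_equal(pw$individuals$loglik_other[pw$individuals$individual_id == "e2"],
               rm_log_likelihood(d, allele_counts(west)), tolerance = 1e-12)
  expect_equal(pw$individuals$lr_log10,
               (pw$individuals$loglik_own - pw$individuals$loglik_other) /
                 log(10))
})

test_that("loo_self_assignment separates fixed baselines and catches planted migrants", {
  # two populations fixed for opposite alleles -> no misassignment
  east <- make_gm(matrix(2L, 10, 8), ids = paste0("e", 1:10))
  west <- make_gm(matrix(0L, 10, 8), ids = paste0("w", 1:10))
  pw <- loo_self_assignment(list(east = east, west = west))
  expect_equal(pw$per_population$n_misassigned, c(0L, 0L))
  # constructed 4-individual baselines: one 'west' fish is an eastern genotype
  set.seed(21)
  L <- 30
  de <- matrix(rbinom(2 * L, 2, 0.9), 2)
  dw <- rbind(rbinom(L, 2, 0.1), rbinom(L, 2, 0.9))   # w2 drawn from east
  pw2 <- loo_self_assignment(list(
    east = make_gm(de, ids = c("e1", "e2")),
    west = make_gm(dw, ids = c("w1", "w2"))))
  expect_equal(
    pw2$per_population$misassignment_rate[pw2$per_population$population == "west"],
    0.5)
  mis <- pw2$individuals[pw2$individuals$individual_id == "w2", ]
  expect_equal(mis$assigned, "east")
  # population of size 1 is permitted with a warning
  expect_warning(
    loo_self_assignment(list(east = make_gm(matrix(2L, 1, 4), ids = "e1"),
                             west = make_gm(matrix(0L, 3, 4),
                                            ids = paste0("w", 1:3)))),
    "single individual")
})

test_that("lr_summary computes geometric means and exports the distribution", {
  rep <- structure(list(
    per_population = data.frame(population = "east", n = 3, n_misassigned = 0,
                                misassignment_rate = 0),
    individuals = data.frame(individual_id = c("a", "b", "c"),
                             population = "east", assigned = "east",
                             loglik_own = 0, loglik_other = 0,
                             lr_log10 = c(3, 1, 3), score_own = 99)),
    class = "power_report")
  s <- lr_summary(rep)
  expect_equal(s$per_population$geometric_mean_lr, 10^(7 / 3))
  sub <- s$distribution[s$distribution$individual_id %in% c("b", "a"), ]
  expect_equal(10^mean(sub$lr_log10), 100)   # {1,3} -> geometric mean 100
  expect_equal(nrow(s$distribution), 3)
})

test_that("misassignment decreases as panel divergence or size grows", {
  rate_at <- function(fst, L, seed) {
    cfg <- generator_config(n_candidate_loci = L, inflated_frac = 0,
                            fst_target = fst, ld_block_spec = NULL,
                            seed = seed)
    bl <- gen_baselines(cfg, n = 60)
    pw <- loo_self_assignment(list(east = bl$east, west = bl$west))
    sum(pw$per_population$n_misassigned) / sum(pw$per_population$n)
  }
  weak <- mean(vapply(1:3, function(s) rate_at(0.01, 10, s), numeric(1)))
  strong <- mean(vapply(1:3, function(s) rate_at(0.10, 10, s), numeric(1)))
  more_loci <- mean(vapply(1:3, function(s) rate_at(0.01, 60, s), numeric(1)))
  expect_gt(weak, strong)
  expect_gt(weak, more_loci)
})
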