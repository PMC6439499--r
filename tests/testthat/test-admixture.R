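test_that("parental and F1 simulators honour boundary frequencies and moments", {
  z <- simulate_parental(setNames(rep(0, 5), paste0("l", 1:5)), 4, seed = 1)
  expect_true(all(z$dosage == 0L))
  o <- simulate_parental(setNames(rep(1, 5), paste0("l", 1:5)), 4, seed = 1)
  expect_true(all(o$dosage == 2L))
  # binomial moments: p = 0.3 -> mean dosage 0.6 within a 3-sigma band
  n <- 10000
  m <- mean(simulate_parental(setNames(0.3, "l"), n, seed = 5)$dosage)
  expect_lt(abs(m - 0.6), 3 * sqrt(2 * 0.3 * 0.7 / n))
  # diagnostic loci: F1 heterozygous everywhere
  f1 <- simulate_f1(setNames(rep(1, 6), paste0("l", 1:6)), rep(0, 6), 7,
                    seed = 2)
  expect_true(all(f1$dosage == 1L))
  # mean dosage = pE + pW within MC error
  f2 <- simulate_f1(setNames(0.2, "l"), 0.7, n, seed = 3)
  expect_lt(abs(mean(f2$dosage) - 0.9), 3 * sqrt(0.41 / n))
  expect_error(simulate_f1(c(a = 0.5), c(0.5, 0.5), 3), "mismatched")
  # reproducibility under a fixed seed
  fr <- setNames(c(0.2, 0.5, 0.8, 0.4), letters[1:4])
  expect_identical(simulate_parental(fr, 5, seed = 9)$dosage,
                   simulate_parental(fr, 5, seed = 9)$dosage)
})

test_that("estimate_admixture handles diagnostic loci and boundary modes", {
  L <- 25
  fe <- setNames(rep(1, L), paste0("l", 1:L))
  fw <- setNames(rep(0, L), paste0("l", 1:L))
  pure <- estimate_admixture(rep(2L, L), fe, fw)
  expect_equal(pure$q_hat, 1)
  expect_equal(pure$ci_high, 1)
  expect_gt(pure$ci_low, 0)
  het <- estimate_admixture(rep(1L, L), fe, fw)
  expect_equal(het$q_hat, 0.5, tolerance = 1e-3)
  expect_gt(het$ci_low, 0.01)
  expect_lt(het$ci_high, 0.99)
  # flat likelihood -> uninformative, full interval
  same <- estimate_admixture(rep(1L, 4), setNames(rep(0.5, 4), letters[1:4]),
                             rep(0.5, 4))
  expect_true(same$uninformative)
  expect_equal(c(same$ci_low, same$ci_high), c(0, 1))
})

test_that("grid posterior agrees with a fine-grid brute-force oracle", {
  set.seed(13)
  L <- 10
  fe <- runif(L, 0.1, 0.9); fw <- runif(L, 0.1, 0.9)
  d <- rbinom(L, 2, 0.5 * fe + 0.5 * fw)
  est <- estimate_admixture(matrix(d, 1), fe, fw, grid_size = 1001)
  # independent brute force: direct likelihood product on 1e5 points,
  # rectangle normalisation
  q <- seq(0, 1, length.out = 100001)
  lik <- rep(1, length(q))
  for (j in 1:L) {
    pa <- q * fe[j] + (1 - q) * fw[j]
    lik <- lik * pa^d[j] * (1 - pa)^(2 - d[j])
  }
  w <- rep(1, length(q)); w[c(1, length(q))] <- 0.5
  cdf <- cumsum(lik * w) / sum(lik * w)
  expect_equal(est$q_hat, q[which.max(lik)], tolerance = 1e-3)
  expect_equal(est$ci_low, q[which.min(abs(cdf - 0.025))], tolerance = 1e-3)
  expect_equal(est$ci_high, q[which.min(abs(cdf - 0.975))], tolerance = 1e-3)
  # grid refinement changes the estimate by less than one coarse step
  est2 <- estimate_admixture(matrix(d, 1), fe, fw, grid_size = 2001)
  expect_lt(abs(est$q_hat - est2$q_hat), 1 / 1000)
  expect_lt(abs(est$ci_low - est2$ci_low), 1 / 1000)
  expect_lt(abs(est$ci_high - est2$ci_high), 1 / 1000)
})

test_that("estimate_admixture is equivariant under swapping the parental labels", {
  set.seed(4)
  L <- 40
  fe <- runif(L); fw <- runif(L)
  d <- matrix(rbinom(5 * L, 2, 0.5), 5)
  a <- estimate_admixture(d, fe, fw)
  b <- estimate_admixture(d, fw, fe)
  expect_equal(a$q_hat, 1 - b$q_hat, tolerance = 2e-3)
  expect_equal(a$ci_low, 1 - b$ci_high, tolerance = 2e-3)
  expect_equal(a$ci_high, 1 - b$ci_low, tolerance = 2e-3)
})

test_that("classify_ancestry follows the CI-overlap rules", {
  est <- structure(data.frame(
    individual_id = c("a", "b", "c", "d"),
    q_hat = c(0.97, 0.5, 0.5, 0.03),
    ci_low = c(0.92, 0.31, 0.0, 0.0),
    ci_high = c(1.0, 0.68, 1.0, 0.2),
    n_loci_used = 10L, uninformative = FALSE),
    class = c("admixture_estimate", "data.frame"))
  expect_equal(classify_ancestry(est)$call,
               c("pure_east", "admixed", "ambiguous", "pure_west"))
  # boundary tolerance is configurable
  est$ci_high[2] <- 0.996
  expect_equal(classify_ancestry(est, eps = 1e-9)$call[2], "admixed")
  expect_equal(classify_ancestry(est, eps = 0.05)$call[2], "pure_east")
})

test_that("hybrid_test separates planted F1s from parental mixtures", {
  cfg <- generator_config(n_candidate_loci = 483, inflated_frac = 0,
                          fst_target = 0.05, ld_block_spec = NULL, seed = 37)
  bl <- gen_baselines(cfg, n = 100)
  bs <- baseline_set(east = allele_counts(bl$east),
                     west = allele_counts(bl$west))
  fe <- allele_freq(bs$counts$east)
  fw <- allele_freq(bs$counts$west)
  observed <- rbind_genotypes(
    rbind_genotypes(simulate_parental(fe, 15, seed = 1, prefix = "obsE"),
                    simulate_parental(fw, 15, seed = 2, prefix = "obsW")),
    simulate_f1(fe, fw, 10, seed = 3, prefix = "obsF"))
  ht <- hybrid_test(observed, bs, n_sim = 150, seed = 77)
  # planted F1s are called admixed, parental observed fish are not
  obs_calls <- ht$observed$call
  f1_rows <- grepl("^obsF", ht$observed$individual_id)
  expect_gte(mean(obs_calls[f1_rows] == "admixed"), 0.9)
  expect_lte(mean(obs_calls[!f1_rows] == "admixed"), 0.1)
  # simulated panels behave like their figure panels
  expect_gte(mean(ht$f1$call == "admixed"), 0.9)
  expect_lte(mean(ht$parental$call == "admixed"), 0.1)
  expect_equal(sum(ht$call_counts[, "observed"]), 40)
  # determinism under a fixed seed
  ht2 <- hybrid_test(observed, bs, n_sim = 150, seed = 77)
  expect_identical(ht$parental$q_hat, ht2$parental$q_hat)
})
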