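# small helper: haul table generated directly from a known truth
sim_hauls <- function(n_hauls = 60, fish = 30, seed = 1,
                      adult_tr = 13.0, juv_tr = 13.5, steep = 8,
                      beta_env = c(0, 0, 0), stages = c("adult", "juvenile")) {
  set.seed(seed)
  lon <- sort(runif(n_hauls, 12, 14.5))
  sal <- 10 - 1.5 * (lon - 12) + rnorm(n_hauls, 0, 0.5)
  oxy <- 6 - 0.8 * (lon - 12) + rnorm(n_hauls, 0, 0.4)
  tem <- 5 + 0.5 * (lon - 12) + rnorm(n_hauls, 0, 0.6)
  std <- function(x) (x - mean(x)) / sd(x)
  rows <- list()
  for (st in stages) {
    tr <- if (st == "juvenile") juv_tr else adult_tr
    eta <- steep * (lon - tr) + beta_env[1] * std(sal) +
      beta_env[2] * std(oxy) + beta_env[3] * std(tem)
    pi <- plogis(eta)
    rows[[st]] <- data.frame(
      haul_id = sprintf("h%03d", seq_len(n_hauls)),
      period_id = rep(c("2013-Q1", "2014-Q2", "2015-Q3"),
                      length.out = n_hauls),
      utm_x = lon, life_stage = st,
      east_count = rbinom(n_hauls, fish, pi), n_fish = fish,
      salinity = sal, oxygen = oxy, temperature = tem,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "true_pi") <- NULL
  rownames(out) <- NULL
  out
}

test_that("standardize centres, scales, stores moments, and rejects constants", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$values, c(-1, 0, 1))
  expect_equal(s$original_mean, 2)
  expect_equal(s$original_sd, 1)
  set.seed(3)
  x <- rnorm(50)
  z <- standardize(x)$values
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z)$values, z, tolerance = 1e-12)  # idempotent
  expect_error(standardize(rep(4, 10)), "constant")
  expect_error(standardize(c(1, NA, 2)), "finite")
  expect_error(standardize(1), "at least 2")
})

test_that("aggregate_hauls counts assigned fish per haul and stage", {
  asn <- structure(data.frame(
    individual_id = paste0("f", 1:7),
    loglik_east = 0, score_east = 50,
    assigned = c("east", "east", "east", "west", "west", "ambiguous",
                 "unusable"),
    n_loci_used = c(rep(10L, 6), 0L), stringsAsFactors = FALSE),
    class = c("assignment_result", "data.frame"))
  meta <- data.frame(individual_id = paste0("f", 1:7),
                     haul_id = c(rep("A", 6), "B"),
                     period_id = "2014-Q1", utm_x = c(rep(13.4, 6), 12.1),
                     length_cm = c(30, 40, 35, 25, 50, 30, 18),
                     maturity = c(rep("adult", 6), "unknown"),
                     salinity = 8, oxygen = 5, temperature = 6,
                     stringsAsFactors = FALSE)
  agg <- aggregate_hauls(asn, meta)
  # haul A adults: {E,E,E,W,W}; the ambiguous fish is excluded
  expect_equal(nrow(agg), 1)
  expect_equal(agg$east_count, 3)
  expect_equal(agg$n_fish, 5)
  expect_equal(agg$area, "east_of_13E")
  # haul B had only the unusable fish -> dropped and logged
  expect_equal(attr(agg, "dropped_hauls"), "B")
  # the 18 cm fish with unknown maturity is a juvenile by the length rule
  expect_equal(infer_life_stage(18, "unknown"), "juvenile")
  expect_equal(infer_life_stage(18, "spawning"), "adult")
  expect_equal(infer_life_stage(c(25, NA), NULL), c("adult", "adult"))
})

test_that("WAIC matches an independent implementation and its zero-variance limit", {
  hauls <- sim_hauls(20, 20, seed = 5, stages = "adult")
  fit <- fit_mixing_model(hauls, "M0", list(seed = 2, n_draws = 400))
  # independent recomputation from the stored draws, observation by
  # observation with two-pass variance and direct averaging
  eta <- fit$draws %*% t(fit$A)
  waic_oracle <- 0
  for (i in seq_along(fit$y)) {
    lp <- dbinom(fit$y[i], fit$N[i], plogis(eta[, i]), log = TRUE)
    lppd_i <- log(mean(exp(lp)))
    v_i <- sum((lp - mean(lp))^2) / (length(lp) - 1)
    waic_oracle <- waic_oracle - 2 * (lppd_i - v_i)
  }
  expect_equal(as.numeric(fit$waic), waic_oracle, tolerance = 1e-8)
  # degenerate single-point posterior: penalty 0, deviance at the point
  fit2 <- fit
  fit2$draws <- fit$draws[rep(1, 10), ]
  w2 <- compute_waic(fit2)
  eta1 <- drop(fit$A %*% fit$draws[1, ])
  expect_equal(as.numeric(w2),
               -2 * sum(dbinom(fit$y, fit$N, plogis(eta1), log = TRUE)),
               tolerance = 1e-8)
  expect_equal(attr(w2, "p_waic"), 0, tolerance = 1e-10)
  fit2$draws <- fit$draws[1, , drop = FALSE]
  expect_error(compute_waic(fit2), "at least 2")
})

test_that("M0 on null data recovers a flat intercept and covariate nulls", {
  hauls <- sim_hauls(100, 30, seed = 11, steep = 0, adult_tr = 13.25,
                     juv_tr = 13.25, stages = "adult")
  fit <- fit_mixing_model(hauls, "M0", list(seed = 4))
  s <- summary(fit)
  expect_lt(abs(s$mean[s$term == "intercept"]), 0.15)
  for (tm in c("salinity", "oxygen", "temperature")) {
    expect_lt(s$lower[s$term == tm], 0)
    expect_gt(s$upper[s$term == tm], 0)
  }
  # diagnostics exist and behave: Pearson residuals of a well-specified model
  r <- pearson_residuals(fit)
  expect_true(all(is.finite(r)))
  expect_lt(abs(var(r) - 1), 0.5)
})

test_that("recoding east and west mirrors the fit exactly", {
  hauls <- sim_hauls(40, 25, seed = 7, stages = c("adult", "juvenile"))
  flipped <- hauls
  flipped$east_count <- flipped$n_fish - flipped$east_count
  f1 <- fit_mixing_model(hauls, "M2", list(seed = 9, n_draws = 300))
  f2 <- fit_mixing_model(flipped, "M2", list(seed = 9, n_draws = 300))
  expect_equal(unname(f1$beta), unname(-f2$beta), tolerance = 1e-4)
  expect_equal(as.numeric(f1$waic), as.numeric(f2$waic), tolerance = 1e-6)
})

test_that("M3/M4 smoothers recover sharp longitude transitions", {
  hauls <- sim_hauls(80, 30, seed = 13, adult_tr = 13.0, juv_tr = 13.5)
  f4 <- fit_mixing_model(hauls, "M4", list(seed = 3))
  pa <- predict_longitude_profile(f4, "adult")
  pj <- predict_longitude_profile(f4, "juvenile")
  expect_lt(abs(pa$crossing - 13.0), 0.25)
  expect_lt(abs(pj$crossing - 13.5), 0.25)
  expect_true(all(pa$profile$lower <= pa$profile$median + 1e-9))
  # M3 on single-stage data: one shared smoother, no stage argument allowed
  ad <- hauls[hauls$life_stage == "adult", ]
  f3 <- fit_mixing_model(ad, "M3", list(seed = 3))
  p3 <- predict_longitude_profile(f3)
  expect_lt(abs(p3$crossing - 13.0), 0.3)
  expect_error(predict_longitude_profile(f3, "juvenile"), "M3")
  expect_error(predict_longitude_profile(fit_mixing_model(ad, "M0",
                                                          list(seed = 1))),
               "smoother")
})

test_that("model preconditions and comparison table are enforced", {
  ad <- sim_hauls(20, 20, seed = 2, stages = "adult")
  expect_error(fit_mixing_model(ad, "M2", list(seed = 1)), "life stages")
  west_only <- ad[ad$utm_x < 13, ]
  west_only$area <- "west_of_13E"
  expect_error(fit_mixing_model(west_only, "M1", list(seed = 1)), "areas")
  expect_error(fit_mixing_model(ad[, -3], "M0"), "lacks columns")
  bad <- ad; bad$east_count[1] <- 99L
  expect_error(fit_mixing_model(bad, "M0"), "invalid east_count")
  # comparison: identical call -> identical table; delta anchored at 0
  hauls <- sim_hauls(30, 20, seed = 8)
  t1 <- compare_models(hauls, c("M0", "M2"), list(seed = 5, n_draws = 300))
  t2 <- compare_models(hauls, c("M0", "M2"), list(seed = 5, n_draws = 300))
  expect_identical(t1, t2)
  expect_equal(t1$delta_waic[1], 0)
  expect_true(all(diff(t1$waic) >= 0))
})

test_that("before/after comparison uses Wilson intervals and needs both periods", {
  # closed-form Wilson check: 50/200 vs 150/200 are disjoint
  w1 <- wilson_ci(50, 200)
  w2 <- wilson_ci(150, 200)
  z <- qnorm(0.975)
  centre <- (0.25 + z^2 / 400) / (1 + z^2 / 200)
  half <- z * sqrt(0.25 * 0.75 / 200 + z^2 / (4 * 200^2)) / (1 + z^2 / 200)
  expect_equal(unname(w1[, "lower"]), centre - half, tolerance = 1e-12)
  expect_equal(unname(w1[, "upper"]), centre + half, tolerance = 1e-12)
  expect_lt(w1[, "upper"], w2[, "lower"])
  hauls <- sim_hauls(30, 20, seed = 4)
  ba <- before_after_comparison(hauls, "2013-Q4")
  expect_setequal(unique(ba$period), c("before", "after"))
  all_rows <- ba[ba$area == "all", ]
  # identical generating process on both sides -> overlapping intervals
  expect_lt(max(all_rows$ci_low), min(all_rows$ci_high))
  expect_error(before_after_comparison(hauls, "1990-Q1"), "non-empty")
})
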