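test_that("generator output is byte-identical under a fixed seed", {
  cfg <- generator_config(n_candidate_loci = 120, baseline_n = 25,
                          survey = list(n_hauls = 8, fish_per_haul = 10),
                          seed = 5)
  a <- gen_baselines(cfg)
  b <- gen_baselines(cfg)
  expect_identical(a$east$dosage, b$east$dosage)
  expect_identical(a$truth$freq_west, b$truth$freq_west)
  sa <- gen_survey(cfg, a)
  sb <- gen_survey(cfg, b)
  expect_identical(sa$genotypes$dosage, sb$genotypes$dosage)
  expect_identical(sa$metadata, sb$metadata)
  # a different sample id yields an independent draw from the same truth
  ho <- gen_baselines(cfg, truth = a$truth, sample_id = "holdout")
  expect_identical(ho$loci, a$loci)
  expect_false(identical(ho$east$dosage, a$east$dosage))
})

test_that("planted LD blocks reach their target correlation", {
  cfg <- generator_config(n_candidate_loci = 300, baseline_n = 150,
                          ld_block_spec = list(n_blocks = 10, block_size = 3,
                                               r2 = 0.9),
                          seed = 8)
  bl <- gen_baselines(cfg)
  blocks <- bl$truth$blocks
  r2s <- c()
  for (bk in unique(blocks$block)) {
    mem <- blocks$locus_index[blocks$block == bk]
    for (i in seq_along(mem)[-1]) {
      r2s <- c(r2s, ld_r2(bl$east, mem[1], mem[i]))
    }
  }
  expect_gt(mean(r2s, na.rm = TRUE), 0.8)
  expect_lte(max(r2s, na.rm = TRUE), 1)
  # block members share a linkage group and sit within 1 cM of the focal locus
  lg <- bl$loci$linkage_group[blocks$locus_index]
  expect_true(all(tapply(lg, blocks$block, function(z) length(unique(z))) == 1))
})

test_that("config validation rejects impossible worlds", {
  expect_error(generator_config(ld_block_spec = list(n_blocks = 2,
                                                     block_size = 3, r2 = 1.4)),
               "infeasible")
  expect_error(generator_config(survey = list(adult_transition = 20)),
               "transition")
  expect_error(generator_config(fst_target = 0), "fst_target")
  expect_error(generator_config(f1_rate = 2), "f1_rate")
})

test_that("survey truth follows the configured transitions and rates", {
  cfg <- generator_config(
    n_candidate_loci = 60, baseline_n = 60, ld_block_spec = NULL,
    survey = list(n_hauls = 40, fish_per_haul = 25, steepness = 1000),
    seed = 9)
  bl <- gen_baselines(cfg)
  sv <- gen_survey(cfg, bl)
  tr <- merge(sv$truth$haul, sv$hauls[, c("haul_id", "utm_x")])
  # steepness -> infinity behaves as a step at the stage transition
  ad <- tr[tr$life_stage == "adult", ]
  expect_true(all(ad$true_pi[ad$utm_x > 13.02] > 0.999))
  expect_true(all(ad$true_pi[ad$utm_x < 12.98] < 0.001))
  ju <- tr[tr$life_stage == "juvenile", ]
  expect_true(all(ju$true_pi[ju$utm_x > 13.52] > 0.999))
  # no F1 in truth unless requested
  expect_false(any(sv$truth$fish$origin == "F1"))
  cfg2 <- generator_config(
    n_candidate_loci = 60, baseline_n = 60, f1_rate = 0.2,
    ld_block_spec = NULL,
    survey = list(n_hauls = 10, fish_per_haul = 30), seed = 9)
  sv2 <- gen_survey(cfg2, gen_baselines(cfg2))
  expect_gt(mean(sv2$truth$fish$origin == "F1"), 0.1)
  # juvenile length rule is generatively consistent
  expect_true(all(sv$metadata$length_cm[sv$truth$fish$life_stage ==
                                          "juvenile"] < 20))
  expect_true(all(sv$metadata$length_cm[sv$truth$fish$life_stage ==
                                          "adult"] > 20))
})

test_that("realized haul fractions are binomially consistent with the truth", {
  cfg <- generator_config(n_candidate_loci = 40, baseline_n = 40,
                          ld_block_spec = NULL,
                          survey = list(n_hauls = 60, fish_per_haul = 40),
                          seed = 13)
  sv <- gen_survey(cfg, gen_baselines(cfg))
  fish <- merge(sv$truth$fish,
                sv$metadata[, c("individual_id", "haul_id")])
  ok <- 0; tot <- 0
  for (key in split(fish, interaction(fish$haul_id, fish$life_stage,
                                      drop = TRUE))) {
    if (nrow(key) < 5) next
    tot <- tot + 1
    p <- key$true_pi[1]
    x <- sum(key$origin == "east")
    ci <- qbinom(c(0.025, 0.975), nrow(key), p)
    ok <- ok + (x >= ci[1] && x <= ci[2])
  }
  expect_gt(ok / tot, 0.9)
})

test_that("end-to-end: assignment on generator output recovers true origins", {
  cfg <- generator_config(n_candidate_loci = 250, baseline_n = 100,
                          survey = list(n_hauls = 15, fish_per_haul = 20),
                          seed = 21)
  bl <- gen_baselines(cfg)
  ranked <- rank_loci_by_fst(wc_fst(allele_counts(bl$east),
                                    allele_counts(bl$west)))
  ps <- high_grade_panel(ranked, list(bl$east, bl$west), panel_size = 39)
  sv <- gen_survey(cfg, bl)
  bs <- baseline_set(
    east = subset_counts(allele_counts(bl$east), ps$selected),
    west = subset_counts(allele_counts(bl$west), ps$selected))
  asn <- assign_individuals(subset_genotypes(sv$genotypes,
                                             loci = ps$selected), bs)
  truth <- sv$truth$fish$origin[match(asn$individual_id,
                                      sv$truth$fish$individual_id)]
  usable <- asn$assigned %in% c("east", "west")
  acc <- mean(asn$assigned[usable] == truth[usable])
  expect_gt(acc, 0.95)
})
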