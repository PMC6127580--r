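test_that("category probabilities telescope and match numerical integration", {
  expect_equal(category_prob(0, 0, 1), 0.5)       # K = 2, symmetric
  expect_equal(category_prob(0, 0, 2), 0.5)

  t5 <- c(0, 1, 2, 3)
  for (eta in c(-1.3, 0, 0.7, 2.5)) {
    probs <- vapply(1:5, function(j) category_prob(eta, t5, j), 0)
    expect_equal(sum(probs), 1)
    expect_true(all(probs > 0))
  }
  # oracle: integrate the shifted standard-normal density over (t1, t2)
  oracle <- stats::integrate(function(u) stats::dnorm(u - 0.7), 0, 1)$value
  expect_equal(category_prob(0.7, t5, 2), oracle, tolerance = 1e-8)
  expect_equal(category_prob(0.7, t5, 2), pnorm(0.3) - pnorm(-0.7))

  expect_error(category_prob(0, c(1, 0), 1), "increasing")
  expect_error(category_prob(0, t5, 6), "category")
})

test_that("liability draws respect their truncation interval", {
  t5 <- c(0, 0.8, 1.6, 2.4)
  set.seed(1)
  expect_true(all(sample_liability(500, 0, t5, 1) <= 0))
  expect_true(all(sample_liability(500, 0, t5, 5) > 2.4))
  u3 <- sample_liability(500, -2, t5, 3)
  expect_true(all(u3 > 0.8 & u3 <= 1.6))
  # extreme linear predictor must not degenerate
  u_far <- sample_liability(100, -40, t5, 5)
  expect_true(all(is.finite(u_far) & u_far > 2.4))
  expect_error(sample_liability(1, 0, t5, 0), "category")
})

test_that("half-normal mean of truncated draws matches the closed form", {
  set.seed(42)
  u <- sample_liability(1e5, 0, 0, 2)    # N(0,1) truncated to (0, Inf)
  expect_equal(mean(u), sqrt(2 / pi), tolerance = 0.015)
  skip_if_not_installed("truncnorm")
  expect_equal(mean(u), truncnorm::etruncnorm(a = 0, mean = 0, sd = 1),
               tolerance = 0.015)
})

test_that("threshold sampler rejects unusable ordinal data", {
  st <- small_study()
  mm <- build_design(st$records, st$pedigree, trait = "score")
  expect_error(gibbs_threshold(mm, st$Ainv, 7, quick_cfg()),
               "never observed")
  mm_bad <- mm
  mm_bad$y <- rep(2, length(mm$y))
  expect_error(gibbs_threshold(mm_bad, st$Ainv, 5, quick_cfg()),
               "one category|never observed")
  mm_frac <- mm
  mm_frac$y[1] <- 1.5
  expect_error(gibbs_threshold(mm_frac, st$Ainv, 5, quick_cfg()),
               "integers")
})

test_that("threshold chain keeps liabilities ordered and is reproducible", {
  st <- small_study()
  mm <- build_design(st$records, st$pedigree, trait = "score")
  cfg <- quick_cfg(seed = 8, n_cycles = 2000, burn_in = 500, thin = 5)
  ch <- gibbs_threshold(mm, st$Ainv, 5, cfg)
  s <- ch$samples
  expect_equal(nrow(s), 300)
  expect_true(all(s$sigma_a2 > 0 & s$sigma_e2 > 0))
  expect_true(all(s$h2 >= 0 & s$h2 <= 1))
  expect_equal(s$h2, s$sigma_a2 / (s$sigma_a2 + s$sigma_e2))
  # free thresholds stay above the fixed pair t1 = 0, t2 = 1 and ordered
  expect_true(all(s$t3 > 1 & s$t4 > s$t3))
  ch2 <- gibbs_threshold(mm, st$Ainv, 5, cfg)
  expect_identical(s, ch2$samples)
})

test_that("zero genetic signal yields near-zero liability heritability", {
  cfg <- sim_config(n_founders = 170, n_generations = 3,
                    offspring_per_gen = 170, n_recorded = 500,
                    fixed_effect_size = 0,
                    traits = list(trait_ordinal("s", 5, 1e-6)))
  st <- simulate_study(cfg, seed = 13)
  mm <- build_design(st$records, st$pedigree, trait = "s")
  ch <- gibbs_threshold(mm, makeAinv(st$pedigree), 5,
                        gibbs_config(8000, 3000, 5, seed = 13))
  expect_lt(mean(ch$samples$h2), 0.1)
})

test_that("three-category liability heritability is recovered", {
  cfg <- sim_config(n_founders = 250, n_generations = 4,
                    offspring_per_gen = 250, n_recorded = 1000,
                    traits = list(trait_ordinal("s", 3, 0.5,
                                                probs = c(0.35, 0.35, 0.3))))
  st <- simulate_study(cfg, seed = 17)
  mm <- build_design(st$records, st$pedigree, trait = "s")
  ch <- gibbs_threshold(mm, makeAinv(st$pedigree), 3,
                        gibbs_config(15000, 7500, 5, seed = 17))
  expect_lt(abs(mean(ch$samples$h2) - 0.5), 0.15)
})

test_that("binary fits demand a proper variance prior and run to completion", {
  cfg <- sim_config(n_founders = 100, n_generations = 2,
                    offspring_per_gen = 100, n_recorded = 200,
                    traits = list(trait_ordinal("b", 2, 0.3,
                                                probs = c(0.5, 0.5))))
  st <- simulate_study(cfg, seed = 19)
  mm <- build_design(st$records, st$pedigree, trait = "b")
  Ainv <- makeAinv(st$pedigree)
  expect_error(gibbs_threshold(mm, Ainv, 2, quick_cfg(), prior_df = -2,
                               prior_scale = 0),
               "proper")
  ch <- gibbs_threshold(mm, Ainv, 2, quick_cfg(seed = 19, n_cycles = 2000,
                                               burn_in = 500, thin = 5))
  s <- ch$samples
  expect_true(all(is.finite(s$sigma_a2)))
  expect_true(all(s$sigma_e2 == 1))       # binary identification
  expect_true(all(s$h2 > 0 & s$h2 < 1))
})
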