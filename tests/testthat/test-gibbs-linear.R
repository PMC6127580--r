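test_that("heritability matches the worked variance-component examples", {
  expect_equal(round(heritability(0.79, 2.03), 2), 0.28)
  expect_equal(round(heritability(62.23, 52.78), 2), 0.54)
  expect_equal(heritability(0, 5), 0)
  expect_error(heritability(0, 0), "undefined")
  expect_error(heritability(-1, 2), "non-negative")
  # vectorised
  expect_equal(heritability(c(1, 1), c(1, 3)), c(0.5, 0.25))
})

test_that("chain bookkeeping: the production chain retains 4000 samples", {
  cfg <- gibbs_config(2e6, 1e6, 250)
  expect_equal(retained_samples(cfg), 4000)
  expect_error(gibbs_config(1000, 1000, 10), "n_cycles > burn_in")
  expect_error(gibbs_config(1000, 500, 7), "divisible")
  expect_error(gibbs_config(1000, 500, 0), "thin")
})

test_that("linear sampler is bit-reproducible under a fixed seed", {
  st <- small_study()
  mm <- build_design(st$records, st$pedigree, trait = "weight")
  cfg <- quick_cfg(seed = 5, n_cycles = 600, burn_in = 100, thin = 5)
  ch1 <- gibbs_linear(mm, st$Ainv, cfg)
  ch2 <- gibbs_linear(mm, st$Ainv, cfg)
  expect_identical(ch1$samples, ch2$samples)
  ch3 <- gibbs_linear(mm, st$Ainv, quick_cfg(seed = 6, n_cycles = 600,
                                             burn_in = 100, thin = 5))
  expect_false(identical(ch1$samples$sigma_a2, ch3$samples$sigma_a2))
  expect_equal(nrow(ch1$samples), 100)
  expect_true(all(ch1$samples$sigma_a2 > 0 & ch1$samples$sigma_e2 > 0))
})

test_that("posterior mean locations agree with the mixed-model equations", {
  st <- small_study()
  mm <- build_design(st$records, st$pedigree, factors = c("yc", "ac"),
                     trait = "weight")
  ch <- gibbs_linear(mm, st$Ainv, quick_cfg(seed = 2, n_cycles = 12000,
                                            burn_in = 2000, thin = 5))
  # direct MME solve at the posterior-mean variance ratio
  lambda <- mean(ch$samples$sigma_e2) / mean(ch$samples$sigma_a2)
  X <- as.matrix(mm$X)
  n <- length(mm$y); N <- mm$N
  Z <- matrix(0, n, N); Z[cbind(seq_len(n), mm$animal)] <- 1
  LHS <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X),
                     crossprod(Z) + as.matrix(st$Ainv) * lambda))
  sol <- solve(LHS, c(crossprod(X, mm$y), crossprod(Z, mm$y)))
  f <- ncol(X)
  expect_lt(max(abs(ch$beta_mean - sol[seq_len(f)])), 0.5)
  expect_gt(stats::cor(ch$alpha_mean, sol[-seq_len(f)]), 0.98)
})

test_that("pure-noise data give near-zero heritability", {
  cfg <- sim_config(n_founders = 100, n_generations = 5,
                    offspring_per_gen = 100, n_recorded = 500,
                    traits = list(trait_continuous("y", 1e-8, 10)))
  st <- simulate_study(cfg, seed = 31)
  mm <- build_design(st$records, st$pedigree, trait = "y")
  ch <- gibbs_linear(mm, makeAinv(st$pedigree),
                     gibbs_config(8000, 3000, 5, seed = 31))
  expect_lt(mean(ch$samples$h2), 0.1)
})

test_that("posterior mean h2 tracks the REML estimate on half-sib data", {
  skip_if_not_installed("lme4")
  hs <- half_sib_study(n_sires = 50, noff = 20, h2 = 0.4, seed = 9)
  mm <- build_design(hs$records, hs$pedigree, factors = character(0),
                     trait = "y")
  ch <- gibbs_linear(mm, makeAinv(hs$pedigree),
                     gibbs_config(8000, 3000, 5, seed = 9))
  fit <- lme4::lmer(y ~ (1 | sire), data = data.frame(y = hs$records$y,
                                                      sire = hs$sire_of),
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vs <- vc$vcov[1]; ve <- vc$vcov[2]
  h2_reml <- 4 * vs / (vs + ve)
  expect_lt(abs(mean(ch$samples$h2) - h2_reml), 0.1)
})

test_that("chains write and read back with their YAML metadata", {
  st <- small_study()
  mm <- build_design(st$records, st$pedigree, trait = "weight")
  cfg <- quick_cfg(seed = 3, n_cycles = 400, burn_in = 100, thin = 3)
  ch <- gibbs_linear(mm, st$Ainv, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chain(ch, path)
  expect_true(file.exists(paste0(path, ".yml")))
  ch2 <- read_chain(path)
  expect_equal(ch2$samples$h2, ch$samples$h2)
  expect_equal(ch2$model, "linear")
  expect_equal(ch2$cfg$seed, cfg$seed)
})
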