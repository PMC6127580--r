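test_that("default pedigree emulates the study size and is valid", {
  set.seed(1)
  ped <- simulate_pedigree(sim_config())
  expect_equal(nrow(ped), 793)
  expect_silent(validate_pedigree(ped))
  expect_equal(sum(ped$sire == 0 & ped$dam == 0), 145)
  # founders-only configuration
  ped0 <- simulate_pedigree(sim_config(n_founders = 10, n_generations = 0,
                                       n_recorded = 5))
  expect_equal(nrow(ped0), 10)
  expect_true(all(ped0$sire == 0 & ped0$dam == 0))
})

test_that("gene dropping reproduces the configured additive variance", {
  cfg <- sim_config(n_founders = 10000, n_generations = 0, n_recorded = 10)
  set.seed(2)
  ped <- simulate_pedigree(cfg)
  bv <- simulate_breeding_values(ped, matrix(2))
  expect_lt(abs(var(bv[, 1]) - 2), 0.1)

  expect_equal(simulate_breeding_values(ped, matrix(0))[, 1],
               rep(0, nrow(ped)), ignore_attr = TRUE)
})

test_that("breeding-value variance follows diag(A) = 1 + F under inbreeding", {
  # heavily inbred mini-pedigree: repeated full-sib matings
  ped <- pedigree(as.character(1:8), c(0, 0, 1, 1, 3, 3, 5, 5),
                  c(0, 0, 2, 2, 4, 4, 6, 6))
  f <- inbreeding(ped)
  expect_gt(max(f), 0.3)
  set.seed(3)
  reps <- vapply(1:600, function(i) {
    simulate_breeding_values(ped, matrix(1))[, 1]
  }, numeric(8))
  emp_var <- apply(reps, 1, var)
  expect_lt(max(abs(emp_var - (1 + f)) / (1 + f)), 0.35)
  expect_lt(abs(mean(emp_var) - mean(1 + f)), 0.05 * mean(1 + f))
})

test_that("ordinal traits honour their threshold category frequencies", {
  cfg <- sim_config(n_founders = 10100, n_generations = 0,
                    n_recorded = 10000, fixed_effect_size = 0,
                    traits = list(trait_ordinal("s", 5, 0.2)))
  st <- simulate_study(cfg, seed = 4)
  counts <- tabulate(st$records$s, 5)
  probs <- cfg$traits$s$probs
  expect_gt(stats::chisq.test(counts, p = probs)$p.value, 0.001)
})

test_that("a symmetric binary trait splits about 50/50", {
  cfg <- sim_config(n_founders = 2100, n_generations = 0,
                    n_recorded = 2000, fixed_effect_size = 0,
                    traits = list(trait_ordinal("b", 2, 0.1,
                                                probs = c(0.5, 0.5))))
  st <- simulate_study(cfg, seed = 5)
  expect_lt(abs(mean(st$records$b == 1) - 0.5), 0.05)
})

test_that("the default study matches the recorded-animal structure", {
  st <- small_study()
  r <- st$records
  expect_equal(nrow(r), 150)
  expect_true(all(r$score %in% 1:5))
  expect_true(all(tabulate(r$score, 5) > 0))
  expect_true(all(as.character(r$animal) %in% st$pedigree$label))
  expect_true(all(c("farm", "birth_year", "sex", "yc", "ac", "cat")
                  %in% names(r)))
  # deterministic under the seed
  st2 <- simulate_study(small_sim_config(), seed = 20260101)
  expect_identical(st2$records, st$records)
})

test_that("correlated pairs carry the configured genetic covariance", {
  g11 <- 0.5; g22 <- 0.8; rg <- 0.7
  G0 <- matrix(c(g11, rg * sqrt(g11 * g22), rg * sqrt(g11 * g22), g22), 2)
  cfg <- sim_config(n_founders = 5000, n_generations = 0, n_recorded = 100,
                    traits = list(trait_ordinal("s", 3, g11 / (g11 + 1)),
                                  trait_continuous("c", g22, 1)))
  set.seed(6)
  ped <- simulate_pedigree(cfg)
  bv <- simulate_breeding_values(ped, G0)
  expect_lt(abs(cor(bv[, 1], bv[, 2]) - rg), 0.05)
  expect_lt(abs(var(bv[, 1]) - g11), 0.05)
})

test_that("generated files round-trip into the model builder", {
  st <- small_study()
  pedfile <- withr::local_tempfile(fileext = ".csv")
  recfile <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(st$pedigree, pedfile)
  write_records(st$records, recfile)
  ped <- read_pedigree(pedfile, header = TRUE)
  recs <- read_records(recfile)
  mm <- build_design(recs, ped, trait = "score")
  expect_equal(length(mm$y), nrow(st$records))
  expect_equal(sort(unique(mm$y)), 1:5)
})
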