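# shared fixtures, built in code

# short chain for unit tests; long enough to stabilise posterior means on
# the small fixtures
quick_cfg <- function(seed = 1L, n_cycles = 4000, burn_in = 1000, thin = 3) {
  gibbs_config(n_cycles, burn_in, thin, seed = seed)
}

# random valid pedigree: founders plus random matings across generations
random_pedigree <- function(n_animals, seed) {
  set.seed(seed)
  nf <- max(2L, round(n_animals / 3))
  sire <- dam <- integer(n_animals)
  sex <- rep_len(c("M", "F"), n_animals)
  for (i in (nf + 1L):n_animals) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    sire[i] <- if (length(males) == 1L) males else sample(males, 1L)
    dam[i] <- if (length(females) == 1L) females else sample(females, 1L)
  }
  pedigree(seq_len(n_animals), sire, dam)
}

# small study reused across tests: 240-animal pedigree, 150 records,
# one 5-category score (liability h2 = 0.3) and one continuous trait
small_sim_config <- function(...) {
  sim_config(n_founders = 60, n_generations = 3, offspring_per_gen = 60,
             n_recorded = 150,
             traits = list(trait_ordinal("score", 5, 0.3),
                           trait_continuous("weight", 30, 70, mu = 40)),
             ...)
}

.fixture_env <- new.env()

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    st <- simulate_study(small_sim_config(), seed = 20260101)
    st$Ainv <- makeAinv(st$pedigree)
    .fixture_env$study <- st
  }
  .fixture_env$study
}

# balanced half-sib design: n_sires unrelated sires, each mated to unique
# dams, noff offspring per sire; records on offspring only
half_sib_study <- function(n_sires, noff, h2, seed, mu = 10, vp = 10) {
  set.seed(seed)
  n_dams <- n_sires * noff
  n_off <- n_sires * noff
  total <- n_sires + n_dams + n_off
  sire <- c(rep(0L, n_sires + n_dams),
            rep(seq_len(n_sires), each = noff))
  dam <- c(rep(0L, n_sires + n_dams),
           n_sires + seq_len(n_off))
  ped <- pedigree(seq_len(total), sire, dam)
  bv <- simulate_breeding_values(ped, matrix(h2 * vp), NULL)
  off <- (n_sires + n_dams + 1L):total
  y <- mu + bv[off, 1] + rnorm(n_off, 0, sqrt((1 - h2) * vp))
  records <- data.frame(animal = ped$label[off],
                        farm = "f1", birth_year = 2013L,
                        sex = rep_len(c("M", "F"), n_off),
                        yc = 1L, ac = 1L, cat = "dry",
                        y = y)
  list(pedigree = ped, records = records,
       sire_of = factor(sire[off]))
}
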