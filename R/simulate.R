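#' Trait definitions for the synthetic-data generator
#'
#' An ordinal trait is generated by thresholding a liability with residual
#' variance 1 and additive variance `sigma_a2` (so liability heritability
#' `h2 = sigma_a2 / (sigma_a2 + 1)`); `probs` are the target marginal
#' category frequencies from which the fixed thresholds are placed (first
#' threshold at 0, the liability mean shifted accordingly). A continuous
#' trait is `mu + fixed effects + breeding value + N(0, sigma_e2)`.
#'
#' @param name Trait (column) name.
#' @param K Number of ordinal categories.
#' @param h2 Liability heritability (ordinal traits).
#' @param probs Target category frequencies (length `K`, summing to 1).
#' @param sigma_a2,sigma_e2 Additive and residual variances (continuous
#'   traits).
#' @param mu Trait mean (continuous traits).
#' @return A trait definition list.
#' @export
trait_ordinal <- function(name, K, h2, probs = NULL) {
  stopifnot(K >= 2, h2 >= 0, h2 < 1)
  if (is.null(probs)) {
    # unimodal frequencies peaked mid-scale, as body-score data typically are
    w <- stats::dnorm(seq_len(K), (K + 1) / 2, K / 3)
    probs <- w / sum(w)
  }
  stopifnot(length(probs) == K, all(probs > 0))
  list(name = name, type = "ordinal", K = as.integer(K),
       sigma_a2 = h2 / (1 - h2), probs = probs / sum(probs))
}

#' @rdname trait_ordinal
#' @export
trait_continuous <- function(name, sigma_a2, sigma_e2, mu = 0) {
  stopifnot(sigma_a2 >= 0, sigma_e2 > 0)
  list(name = name, type = "continuous", sigma_a2 = sigma_a2,
       sigma_e2 = sigma_e2, mu = mu)
}

#' Configuration of the synthetic goat-study generator
#'
#' Defaults emulate the structure of the data the models are meant for: a
#' pedigree of 793 animals of which 385 carry records, a 5-category body
#' condition score and a 6-category rib-eye marbling score with liability
#' heritabilities 0.11 and 0.03, five continuous anchor traits with the
#' estimated variance components (ribeye area 0.79/2.03, sternal fat
#' 0.55/1.77, hip height 3.91/8.29, leg perimeter 6.75/9.55, body weight
#' 62.23/52.78), and fixed effects: contemporary group (4 farms x 3 birth
#' years x 2 sexes), collection year (3), age class (3) and doe category
#' (3). Fixed-effect levels span +/- `fixed_effect_size` residual SDs.
#'
#' @param n_founders,n_generations,offspring_per_gen Pedigree shape;
#'   defaults give 145 + 4 x 162 = 793 animals.
#' @param n_recorded Number of animals with records (selected among
#'   non-founders).
#' @param n_farms,birth_years Contemporary-group structure.
#' @param yc_levels,ac_levels,cat_levels Level counts of the other fixed
#'   effects.
#' @param fixed_effect_size Half-range of the fixed-effect contrasts, in
#'   residual-SD units.
#' @param traits List of [trait_ordinal()] / [trait_continuous()]
#'   definitions.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_founders = 145, n_generations = 4,
                       offspring_per_gen = 162, n_recorded = 385,
                       n_farms = 4, birth_years = 2012:2014,
                       yc_levels = 3, ac_levels = 3, cat_levels = 3,
                       fixed_effect_size = 0.5,
                       traits = list(
                         trait_ordinal("bcs", 5, 0.11),
                         trait_ordinal("mre", 6, 0.03),
                         trait_continuous("rea", 0.79, 2.03, mu = 8),
                         trait_continuous("fts", 0.55, 1.77, mu = 4),
                         trait_continuous("hh", 3.91, 8.29, mu = 70),
                         trait_continuous("lp", 6.75, 9.55, mu = 30),
                         trait_continuous("bw", 62.23, 52.78, mu = 40))) {
  stopifnot(n_founders >= 2, n_generations >= 0, n_recorded >= 1)
  total <- n_founders + n_generations * offspring_per_gen
  if (n_recorded > total) stop("n_recorded exceeds the pedigree size")
  names(traits) <- vapply(traits, `[[`, "", "name")
  structure(list(n_founders = n_founders, n_generations = n_generations,
                 offspring_per_gen = offspring_per_gen,
                 n_recorded = n_recorded, n_farms = n_farms,
                 birth_years = birth_years, yc_levels = yc_levels,
                 ac_levels = ac_levels, cat_levels = cat_levels,
                 fixed_effect_size = fixed_effect_size, traits = traits),
            class = "SimConfig")
}

#' Simulate a multi-generation random-mating pedigree
#'
#' Founders are unrelated and non-inbred; each later generation draws its
#' sire among all earlier males and its dam among all earlier females
#' (selfing impossible, full-sib and parent-offspring matings allowed, so
#' inbreeding accumulates). Output is topologically ordered and carries
#' `sex` and `generation` attributes used by [simulate_records()].
#'
#' @param cfg A `SimConfig`.
#' @return A `Pedigree` of `n_founders + n_generations * offspring_per_gen`
#'   animals.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  nf <- cfg$n_founders
  total <- nf + cfg$n_generations * cfg$offspring_per_gen
  sex <- character(total)
  sex[seq_len(nf)] <- rep_len(c("M", "F"), nf)
  gen <- integer(total)
  sire <- dam <- integer(total)            # 0 = unknown (founders)
  cur <- nf
  for (g in seq_len(cfg$n_generations)) {
    males <- which(sex[seq_len(cur)] == "M")
    females <- which(sex[seq_len(cur)] == "F")
    if (!length(males) || !length(females)) {
      stop("cannot form matings: a sex died out in generation ", g)
    }
    for (k in seq_len(cfg$offspring_per_gen)) {
      cur <- cur + 1L
      sire[cur] <- if (length(males) == 1L) males else sample(males, 1L)
      dam[cur] <- if (length(females) == 1L) females else sample(females, 1L)
      sex[cur] <- sample(c("M", "F"), 1L)
      gen[cur] <- g
    }
  }
  ped <- pedigree(seq_len(total), sire, dam)
  # pedigree() keeps founders-first topological order; map attributes
  ord <- match(ped$label, as.character(seq_len(total)))
  attr(ped, "sex") <- sex[ord]
  attr(ped, "generation") <- gen[ord]
  ped
}

#' Simulate true breeding values by gene dropping
#'
#' Founder breeding values are drawn from `N(0, G0)`; every non-founder
#' gets the parent average plus a Mendelian-sampling deviate with
#' covariance `(0.5 - 0.25 (F_s + F_d)) G0` (variance `0.75 - 0.25 F_p`
#' with one known parent, `G0` with none), so the realised covariance of
#' the breeding values follows `G0 kron A` including inbreeding.
#'
#' @param ped A `Pedigree`.
#' @param G0 k x k additive covariance matrix (a scalar is taken as 1 x 1).
#' @param seed Optional seed.
#' @return N x k matrix of true breeding values.
#' @export
simulate_breeding_values <- function(ped, G0, seed = NULL) {
  validate_pedigree(ped)
  if (!is.null(seed)) set.seed(seed)
  G0 <- as.matrix(G0)
  k <- nrow(G0)
  n <- nrow(ped)
  bv <- matrix(0, n, k, dimnames = list(ped$label, colnames(G0)))
  if (n == 0L || all(G0 == 0)) return(bv)
  L <- t(chol(G0 + diag(1e-12, k)))
  f <- inbreeding(ped)
  s <- ped$sire; d <- ped$dam
  for (i in seq_len(n)) {
    pa <- numeric(k); vmend <- 1
    if (s[i] > 0L && d[i] > 0L) {
      pa <- 0.5 * (bv[s[i], ] + bv[d[i], ])
      vmend <- 0.5 - 0.25 * (f[s[i]] + f[d[i]])
    } else if (s[i] > 0L || d[i] > 0L) {
      p <- max(s[i], d[i])
      pa <- 0.5 * bv[p, ]
      vmend <- 0.75 - 0.25 * f[p]
    }
    bv[i, ] <- pa + sqrt(vmend) * as.numeric(L %*% stats::rnorm(k))
  }
  bv
}

# deterministic level scores spanning [-1, 1]
level_scores <- function(n_levels) {
  if (n_levels == 1L) return(0)
  (seq_len(n_levels) - 1) / (n_levels - 1) * 2 - 1
}

#' Simulate a record set for a pedigree with known breeding values
#'
#' Selects `n_recorded` animals (non-founders preferred), assigns
#' fixed-effect levels, and generates each configured trait: continuous
#' traits as `mu + fixed + bv + N(0, sigma_e2)`, ordinal traits by
#' thresholding a liability (`fixed + bv + N(0, 1)`) at fixed thresholds
#' placed from the target category frequencies with the first threshold at
#' 0. If a category comes out empty the trait is resampled (up to 10
#' attempts, then an error).
#'
#' @param ped A `Pedigree` from [simulate_pedigree()].
#' @param bv Breeding-value matrix with one named column per trait in
#'   `cfg$traits` (from [simulate_breeding_values()]).
#' @param cfg A `SimConfig`.
#' @return A record data.frame passing [build_design()] validation, with
#'   the per-record true breeding values in `attr(, "true_bv")`.
#' @export
simulate_records <- function(ped, bv, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  validate_pedigree(ped)
  n <- nrow(ped)
  gen <- attr(ped, "generation")
  if (is.null(gen)) gen <- ifelse(ped$sire == 0L & ped$dam == 0L, 0L, 1L)
  sex <- attr(ped, "sex")
  if (is.null(sex)) sex <- rep_len(c("M", "F"), n)
  candidates <- which(gen > 0L)
  if (length(candidates) < cfg$n_recorded) candidates <- seq_len(n)
  rec <- sort(sample(candidates, cfg$n_recorded))

  nr <- cfg$n_recorded
  records <- data.frame(
    animal = ped$label[rec],
    farm = paste0("farm", sample.int(cfg$n_farms, nr, replace = TRUE)),
    birth_year = cfg$birth_years[(gen[rec] %% length(cfg$birth_years)) + 1L],
    sex = sex[rec],
    yc = sample.int(cfg$yc_levels, nr, replace = TRUE),
    ac = sample.int(cfg$ac_levels, nr, replace = TRUE),
    cat = c("pregnant", "kidding", "dry")[
      sample.int(cfg$cat_levels, nr, replace = TRUE)],
    stringsAsFactors = FALSE)

  # additive fixed-effect contribution in residual-SD units; the six factor
  # scores sum to at most +/-1 and are scaled to +/- fixed_effect_size
  fixed_units <- function() {
    eff <- function(v) {
      f <- factor(v)
      level_scores(nlevels(f))[as.integer(f)]
    }
    cfg$fixed_effect_size / 6 *
      (eff(records$farm) + eff(records$birth_year) + eff(records$sex) +
         eff(records$yc) + eff(records$ac) + eff(records$cat))
  }

  for (tr in cfg$traits) {
    b <- bv[rec, tr$name]
    if (tr$type == "continuous") {
      sd_e <- sqrt(tr$sigma_e2)
      records[[tr$name]] <- tr$mu + fixed_units() * sd_e + b +
        stats::rnorm(nr, 0, sd_e)
    } else {
      sd_l <- sqrt(tr$sigma_a2 + 1)
      thr <- stats::qnorm(cumsum(tr$probs)[-tr$K]) * sd_l
      mu_l <- -thr[1L]                      # shift so t_1 = 0
      thr <- thr + mu_l
      for (attempt in seq_len(10L)) {
        liab <- mu_l + fixed_units() + b + stats::rnorm(nr)
        yy <- findInterval(liab, thr) + 1L
        if (all(tabulate(yy, tr$K) > 0L)) break
        if (attempt == 10L) {
          stop("could not populate all ", tr$K, " categories of ", tr$name,
               " in 10 attempts; widen probs or increase n_recorded")
        }
        warning("empty category for ", tr$name, "; resampling")
      }
      records[[tr$name]] <- yy
    }
  }
  attr(records, "true_bv") <- bv[rec, , drop = FALSE]
  records
}

#' One-call synthetic study
#'
#' Simulates a pedigree, breeding values for every configured trait and the
#' record set, under a single seed. By default traits are genetically
#' independent (diagonal `G0`); pass `G0` to impose genetic correlations
#' between traits (order and names must match `cfg$traits`).
#'
#' @param cfg A `SimConfig`.
#' @param seed Integer seed.
#' @param G0 Optional k x k additive covariance across the configured
#'   traits; default `diag(sigma_a2)`.
#' @return List with `pedigree`, `records` and the full breeding-value
#'   matrix `bv`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1L, G0 = NULL) {
  set.seed(seed)
  ped <- simulate_pedigree(cfg)
  sa2 <- vapply(cfg$traits, `[[`, 0, "sigma_a2")
  if (is.null(G0)) {
    G0 <- diag(sa2, length(sa2))
    dimnames(G0) <- list(names(cfg$traits), names(cfg$traits))
  }
  bv <- simulate_breeding_values(ped, G0)
  records <- simulate_records(ped, bv, cfg)
  list(pedigree = ped, records = records, bv = bv)
}
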