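#' Category probability under the probit liability model
#'
#' Probability that an ordinal observation falls in category `j` given the
#' linear predictor `eta` on the liability scale and the threshold vector:
#' `Phi(t_j - eta) - Phi(t_{j-1} - eta)`, with `t_0 = -Inf` and
#' `t_K = +Inf`.
#'
#' @param eta Linear predictor(s) on the liability scale.
#' @param thresholds Interior thresholds `t_1 < ... < t_{K-1}` (length
#'   `K - 1`).
#' @param j Category in `1..K`.
#' @param sd Residual standard deviation of the liability (1 in the
#'   identified single-trait model).
#' @return Probability (vectorised over `eta`).
#' @export
category_prob <- function(eta, thresholds, j, sd = 1) {
  K <- length(thresholds) + 1L
  if (j < 1L || j > K) stop("category j must be in 1..", K)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  lo <- if (j == 1L) -Inf else thresholds[j - 1L]
  hi <- if (j == K) Inf else thresholds[j]
  stats::pnorm((hi - eta) / sd) - stats::pnorm((lo - eta) / sd)
}

#' Draw a liability from its truncated-normal full conditional
#'
#' Samples `U ~ N(eta, sd^2)` truncated to the category interval
#' `(t_{j-1}, t_j]` by inverse CDF, evaluated in the complementary tail when
#' the interval sits far from `eta` so extreme intervals do not degenerate.
#'
#' @inheritParams category_prob
#' @param n Number of draws.
#' @return Numeric vector of `n` draws, all inside the interval.
#' @export
sample_liability <- function(n, eta, thresholds, j, sd = 1) {
  K <- length(thresholds) + 1L
  if (j < 1L || j > K) stop("category j must be in 1..", K)
  lo <- if (j == 1L) -Inf else thresholds[j - 1L]
  hi <- if (j == K) Inf else thresholds[j]
  if (lo >= hi) stop("zero-width liability interval")
  rtnorm_cpp(n, eta, sd, lo, hi)
}

#' Single-trait threshold (liability) animal model by Gibbs sampling
#'
#' Data augmentation for an ordinal trait with `K` categories: unobserved
#' liabilities `U ~ N(X beta + Z alpha, I sigma_e2)` are mapped to the
#' observed categories by thresholds, and free thresholds are redrawn each
#' cycle uniformly between the largest liability of category `j` and the
#' smallest of category `j+1` (Albert-Chib).
#'
#' Identification: for `K >= 3` the first two thresholds are fixed at 0 and
#' 1 and the liability residual variance is estimated (flat prior). Pinning
#' the scale with two thresholds is what makes the flat-prior posterior
#' well behaved: if all interior thresholds were free with `sigma_e2 = 1`,
#' the whole liability configuration could inflate indefinitely while the
#' fit sharpens. For binary traits (`K = 2`, a single threshold at 0)
#' `sigma_e2` is fixed at 1 and a proper scaled-inverse-chi-square prior on
#' `sigma_a2` is required because the bounded binary likelihood leaves a
#' flat prior improper; the default (`prior_df = 4`, `prior_scale = 0.25`)
#' is weakly informative with prior mean 0.5 (liability heritability about
#' 1/3). Heritability on the liability scale is
#' `sigma_a2 / (sigma_a2 + sigma_e2)`, which does not depend on the scale
#' convention.
#'
#' @param mm `ModelMatrices` whose `y` holds ordinal codes `1..K`.
#' @param Ainv Sparse A-inverse from [makeAinv()].
#' @param K Number of categories.
#' @param cfg A `GibbsConfig`.
#' @param prior_df,prior_scale Scaled-inverse-chi-square prior on
#'   `sigma_a2` (df and scale). Defaults: flat (`-2`, `0`) for `K >= 3`;
#'   weakly informative (`4`, `0.25`) for `K = 2`, where `prior_df > 2` and
#'   `prior_scale > 0` are required.
#' @return A `ChainSamples` with columns `sigma_a2`, `sigma_e2`, `h2`,
#'   `mu`, `deviance` (observable-scale, from the probit category
#'   probabilities) and one `t_j` column per free threshold (`t3..`).
#' @export
gibbs_threshold <- function(mm, Ainv, K, cfg = gibbs_config(),
                            prior_df = NULL, prior_scale = NULL) {
  stopifnot(inherits(mm, "ModelMatrices"), inherits(cfg, "GibbsConfig"))
  if (nrow(Ainv) != mm$N) stop("Ainv dimension does not match pedigree size")
  K <- as.integer(K)
  y <- as.integer(mm$y)
  if (any(mm$y != y) || any(y < 1L) || any(y > K)) {
    stop("ordinal trait must be coded with integers 1..K")
  }
  tab <- tabulate(y, K)
  if (any(tab == 0L)) {
    stop("categories never observed: ", paste(which(tab == 0L), collapse = ", "),
         "; merge categories before fitting")
  }
  if (length(unique(y)) == 1L) {
    stop("all records fall in one category; the liability is unidentified")
  }
  if (is.null(prior_df)) prior_df <- if (K == 2L) 4 else -2
  if (is.null(prior_scale)) prior_scale <- if (K == 2L) 0.25 else 0
  if (K == 2L && (prior_df <= 2 || prior_scale <= 0)) {
    stop("binary traits need a proper sigma_a2 prior: prior_df > 2 and ",
         "prior_scale > 0 (the flat prior leaves the posterior improper)")
  }
  # start thresholds at normal quantiles of the cumulative frequencies,
  # mapped to the identified scale: t_1 = 0 and (for K >= 3) t_2 = 1
  cum <- cumsum(tab)[-K] / length(y)
  q <- stats::qnorm(cum)
  t_start <- if (K >= 3L) (q - q[1L]) / (q[2L] - q[1L]) else 0
  t_start[1L] <- 0
  # weakly proper prior on the liability residual variance (3 df, scale set
  # from the phenotypic-scale estimate implied by the threshold spacing):
  # with latent responses a flat prior has a density spike at sigma_e2 = 0
  # (residuals of the augmented data can deflate jointly), which this
  # removes while adding only ~3 pseudo-records
  nu_e <- 3
  s2_e <- if (K >= 3L) (1 / (q[2L] - q[1L]))^2 / 3 else 0
  start_sa2 <- if (is.null(cfg$start_sa2)) 0.5 else cfg$start_sa2
  X <- csc_parts(mm$X); A <- csc_parts(Ainv)
  set.seed(cfg$seed)
  out <- gibbs_threshold_cpp(X$p, X$i, X$x, ncol(mm$X), y, K,
                             mm$animal - 1L, mm$N, A$p, A$i, A$x, t_start,
                             as.integer(cfg$n_cycles),
                             as.integer(cfg$burn_in), as.integer(cfg$thin),
                             start_sa2, prior_df, prior_scale, nu_e, s2_e)
  samples <- as.data.frame(out$samples)
  if (K > 3L) {
    thr <- as.data.frame(out$thresholds)
    names(thr) <- paste0("t", 3:(K - 1L))
    samples <- cbind(samples, thr)
  }
  eta_hat <- as.numeric(mm$X %*% out$beta_mean) + out$alpha_mean[mm$animal]
  sd_hat <- sqrt(out$se2_mean)
  p_hat <- vapply(seq_along(y), function(r) {
    category_prob(eta_hat[r], out$t_mean, y[r], sd = sd_hat)
  }, numeric(1))
  dev_hat <- -2 * sum(log(pmax(p_hat, 1e-300)))
  new_chain_samples(samples, cfg, "threshold",
                    K = K, beta_mean = out$beta_mean,
                    alpha_mean = out$alpha_mean, t_mean = out$t_mean,
                    deviance_at_mean = dev_hat)
}
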