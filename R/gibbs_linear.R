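#' Heritability from variance components
#'
#' `h2 = sigma_a2 / (sigma_a2 + sigma_e2)`, the proportion of phenotypic
#' (or liability) variance that is additive genetic. Vectorised.
#'
#' @param sigma_a2 Additive genetic variance(s), >= 0.
#' @param sigma_e2 Residual variance(s), >= 0.
#' @return Heritability in `[0, 1]`.
#' @examples
#' heritability(0.79, 2.03)   # ribeye area: 0.28
#' heritability(62.23, 52.78) # body weight: 0.54
#' @export
heritability <- function(sigma_a2, sigma_e2) {
  if (any(sigma_a2 < 0) || any(sigma_e2 < 0)) {
    stop("variance components must be non-negative")
  }
  tot <- sigma_a2 + sigma_e2
  if (any(tot == 0)) stop("heritability undefined when both variances are 0")
  sigma_a2 / tot
}

csc_parts <- function(M) {
  M <- methods::as(methods::as(M, "generalMatrix"), "CsparseMatrix")
  list(p = M@p, i = M@i, x = M@x)
}

#' Single-trait linear animal model by Gibbs sampling
#'
#' Samples the joint posterior of `y = X beta + Z alpha + e` with
#' `alpha | A, sigma_a2 ~ N(0, A sigma_a2)` and `e ~ N(0, I sigma_e2)`,
#' flat priors on `beta` and on both variances. Location effects are drawn
#' single-site with residual updating; the variances come from their scaled
#' inverse chi-square full conditionals (`df = N - 2` and `n - 2` under the
#' flat prior, scale the quadratic forms `alpha' Ainv alpha` and `e'e`).
#'
#' @param mm `ModelMatrices` from [build_design()].
#' @param Ainv Sparse A-inverse from [makeAinv()] (dimension = pedigree
#'   size).
#' @param cfg A `GibbsConfig`.
#' @return A `ChainSamples` with columns `sigma_a2`, `sigma_e2`, `h2`,
#'   `mu` (intercept) and `deviance` (Gaussian, observable scale), plus
#'   posterior means of all location effects and the deviance evaluated at
#'   the posterior means (for DIC).
#' @export
gibbs_linear <- function(mm, Ainv, cfg = gibbs_config()) {
  stopifnot(inherits(mm, "ModelMatrices"), inherits(cfg, "GibbsConfig"))
  if (nrow(Ainv) != mm$N) stop("Ainv dimension does not match pedigree size")
  vy <- stats::var(mm$y)
  start_sa2 <- if (is.null(cfg$start_sa2)) 0.5 * vy else cfg$start_sa2
  start_se2 <- if (is.null(cfg$start_se2)) 0.5 * vy else cfg$start_se2
  X <- csc_parts(mm$X); A <- csc_parts(Ainv)
  set.seed(cfg$seed)
  out <- gibbs_linear_cpp(X$p, X$i, X$x, ncol(mm$X), mm$y, mm$animal - 1L,
                          mm$N, A$p, A$i, A$x,
                          as.integer(cfg$n_cycles), as.integer(cfg$burn_in),
                          as.integer(cfg$thin), start_sa2, start_se2,
                          -2, -2)
  samples <- as.data.frame(out$samples)
  # deviance at the posterior means of (beta, alpha, sigma_e2)
  eta_hat <- as.numeric(mm$X %*% out$beta_mean) + out$alpha_mean[mm$animal]
  se2_hat <- mean(samples$sigma_e2)
  dev_hat <- sum(stats::dnorm(mm$y, eta_hat, sqrt(se2_hat), log = TRUE)) * -2
  new_chain_samples(samples, cfg, "linear",
                    beta_mean = out$beta_mean, alpha_mean = out$alpha_mean,
                    deviance_at_mean = dev_hat)
}
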