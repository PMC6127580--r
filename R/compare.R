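#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean of the deviance and
#' `pD = Dbar - D(theta_bar)` the effective number of parameters (posterior
#' mean deviance minus the deviance at the posterior means). Smaller DIC
#' indicates the better fit-complexity tradeoff.
#'
#' @param deviance_draws Per-draw deviances (`-2 log L`) on the observable
#'   scale.
#' @param deviance_at_mean Deviance evaluated at the posterior means of the
#'   parameters (e.g. the `deviance_at_mean` attribute of a
#'   `ChainSamples`).
#' @return List with `dic`, `pd`, `dbar`.
#' @export
dic <- function(deviance_draws, deviance_at_mean) {
  if (length(deviance_draws) < 2L) stop("need at least 2 deviance draws")
  dbar <- mean(deviance_draws)
  pd <- dbar - deviance_at_mean
  list(dic = dbar + pd, pd = pd, dbar = dbar)
}

# log of the harmonic-mean marginal-likelihood estimator, stabilised by
# log-sum-exp: log f(y) = log S - logsumexp(-loglik)
log_marginal_harmonic <- function(loglik_draws) {
  x <- -loglik_draws
  m <- max(x)
  log(length(x)) - (m + log(sum(exp(x - m))))
}

#' Bayes factor from per-draw log-likelihoods
#'
#' Estimates each model's marginal likelihood with the harmonic-mean
#' estimator on the log scale and returns the ratio `BF_ij = f(y|M_i) /
#' f(y|M_j)` with the usual reading: BF > 1 prefers the numerator model,
#' BF < 1 the denominator, BF = 1 means the two fit equally well. The
#' harmonic-mean estimator is simple but high-variance; DIC is the primary
#' comparison and the BF is reported alongside it.
#'
#' @param loglik_i,loglik_j Per-draw log-likelihoods of models i
#'   (numerator) and j (denominator).
#' @return List with `bf`, `log_bf`, `log_ml_i`, `log_ml_j` and a
#'   `verdict` string (`"numerator"`, `"denominator"` or `"tie"`).
#' @export
bayes_factor <- function(loglik_i, loglik_j) {
  if (length(loglik_i) < 100L || length(loglik_j) < 100L) {
    warning("fewer than 100 draws: harmonic-mean estimator is unstable")
  }
  li <- log_marginal_harmonic(loglik_i)
  lj <- log_marginal_harmonic(loglik_j)
  log_bf <- li - lj
  verdict <- if (log_bf > 0) "numerator"
             else if (log_bf < 0) "denominator"
             else "tie"
  list(bf = exp(log_bf), log_bf = log_bf, log_ml_i = li, log_ml_j = lj,
       verdict = verdict)
}

#' Compare fitted models by DIC and Bayes factor
#'
#' Convenience wrapper for chains produced by the samplers in this package:
#' computes each model's DIC from its retained deviance draws and the Bayes
#' factor with the first model as numerator. For a linear-vs-threshold
#' contrast pass the linear chain first, so that BF < 1 favours the
#' threshold model.
#'
#' @param chain_i,chain_j `ChainSamples` with a `deviance` column and a
#'   `deviance_at_mean` attribute.
#' @return Data.frame with one row per model (label, dic, pd, dbar) plus
#'   attributes `bf` (the [bayes_factor()] list) and `preferred` (model
#'   label with the smaller DIC).
#' @export
compare_models <- function(chain_i, chain_j) {
  stopifnot(inherits(chain_i, "ChainSamples"), inherits(chain_j, "ChainSamples"))
  di <- dic(chain_i$samples$deviance, chain_i$deviance_at_mean)
  dj <- dic(chain_j$samples$deviance, chain_j$deviance_at_mean)
  bf <- bayes_factor(-0.5 * chain_i$samples$deviance,
                     -0.5 * chain_j$samples$deviance)
  out <- data.frame(model = c(chain_i$model, chain_j$model),
                    dic = c(di$dic, dj$dic),
                    pd = c(di$pd, dj$pd),
                    dbar = c(di$dbar, dj$dbar))
  attr(out, "bf") <- bf
  attr(out, "preferred") <- out$model[which.min(out$dic)]
  out
}
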