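#' Gibbs chain configuration
#'
#' Bundles chain length, burn-in, thinning interval and seed, and checks
#' their arithmetic: the number of retained draws,
#' `(n_cycles - burn_in) / thin`, must be a whole number. The defaults are
#' the long production chain (2,000,000 cycles, 1,000,000 burn-in, keep
#' every 250th draw, i.e. 4,000 retained samples); validation runs use much
#' shorter chains.
#'
#' @param n_cycles Total Gibbs cycles.
#' @param burn_in Cycles discarded before any draw is retained.
#' @param thin Sampling interval among post-burn-in cycles.
#' @param seed Integer seed; every run with the same seed, config and data
#'   is bit-reproducible.
#' @param start_sa2,start_se2 Starting values for the additive-genetic and
#'   residual variances (`NULL` = data-driven: half / half of the
#'   phenotypic variance).
#' @return A `GibbsConfig` list.
#' @examples
#' cfg <- gibbs_config()          # production defaults
#' retained_samples(cfg)          # 4000
#' @export
gibbs_config <- function(n_cycles = 2e6, burn_in = 1e6, thin = 250,
                         seed = 1L, start_sa2 = NULL, start_se2 = NULL) {
  n_cycles <- as.numeric(n_cycles); burn_in <- as.numeric(burn_in)
  thin <- as.numeric(thin)
  if (burn_in < 0 || n_cycles <= burn_in) {
    stop("need n_cycles > burn_in >= 0")
  }
  if (thin < 1) stop("thin must be >= 1")
  if ((n_cycles - burn_in) %% thin != 0) {
    stop("(n_cycles - burn_in) must be divisible by thin")
  }
  structure(list(n_cycles = n_cycles, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), start_sa2 = start_sa2,
                 start_se2 = start_se2),
            class = "GibbsConfig")
}

#' @param cfg A `GibbsConfig`.
#' @rdname gibbs_config
#' @export
retained_samples <- function(cfg) {
  (cfg$n_cycles - cfg$burn_in) / cfg$thin
}

#' @export
print.GibbsConfig <- function(x, ...) {
  cat(sprintf(
    "GibbsConfig: %s cycles, burn-in %s, thin %s -> %s retained (seed %d)\n",
    format(x$n_cycles, big.mark = ","), format(x$burn_in, big.mark = ","),
    x$thin, format(retained_samples(x), big.mark = ","), x$seed))
  invisible(x)
}
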