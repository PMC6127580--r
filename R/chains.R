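#' Retained Gibbs draws
#'
#' `ChainSamples` holds the thinned, post-burn-in draws of a sampler run as
#' a data.frame of named columns (variance components, heritability,
#' thresholds, deviance, ...), together with the chain configuration, the
#' model label and the posterior means of the location effects.
#'
#' @param samples data.frame of retained draws.
#' @param cfg The `GibbsConfig` used.
#' @param model `"linear"`, `"threshold"` or `"bivariate"`.
#' @param ... Extra metadata stored as attributes (e.g. `deviance_at_mean`,
#'   `beta_mean`, `alpha_mean`, `K`).
#' @return A `ChainSamples` object.
#' @keywords internal
new_chain_samples <- function(samples, cfg, model, ...) {
  stopifnot(nrow(samples) == retained_samples(cfg))
  obj <- structure(list(samples = samples, cfg = cfg, model = model),
                   class = "ChainSamples")
  extra <- list(...)
  obj[names(extra)] <- extra
  obj
}

#' @export
print.ChainSamples <- function(x, ...) {
  cat(sprintf("ChainSamples (%s model): %d retained draws of %d parameters\n",
              x$model, nrow(x$samples), ncol(x$samples)))
  print(x$cfg)
  mono <- intersect(c("sigma_a2", "sigma_e2", "h2", "g11", "g22", "rg",
                      "h2_cat", "h2_cont"), names(x$samples))
  if (length(mono)) {
    cat("posterior means:\n")
    print(round(colMeans(x$samples[mono]), 4))
  }
  invisible(x)
}

#' @export
as.data.frame.ChainSamples <- function(x, ...) x$samples

#' Write a chain to disk
#'
#' Writes the retained draws as a plain CSV with named columns and a YAML
#' sidecar (`<path>.yml`) carrying the run metadata: model, chain
#' configuration and seed.
#'
#' @param chain A `ChainSamples`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  utils::write.csv(chain$samples, path, row.names = FALSE)
  meta <- list(model = chain$model,
               n_cycles = chain$cfg$n_cycles,
               burn_in = chain$cfg$burn_in,
               thin = chain$cfg$thin,
               seed = chain$cfg$seed,
               retained = nrow(chain$samples))
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  samples <- utils::read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  cfg <- gibbs_config(meta$n_cycles, meta$burn_in, meta$thin, meta$seed)
  new_chain_samples(samples, cfg, meta$model)
}
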