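#' Genetic correlation from a 2x2 genetic covariance matrix
#'
#' `r_g = G0[1,2] / sqrt(G0[1,1] * G0[2,2])`.
#'
#' @param G0 Symmetric 2x2 additive genetic covariance matrix.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' genetic_correlation(matrix(c(2, 0.6, 0.6, 0.5), 2)) # 0.6
#' @export
genetic_correlation <- function(G0) {
  G0 <- as.matrix(G0)
  stopifnot(nrow(G0) == 2L, ncol(G0) == 2L)
  if (any(diag(G0) <= 0)) stop("genetic correlation undefined: zero or negative diagonal")
  G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])
}

#' Bivariate threshold-linear animal model by Gibbs sampling
#'
#' Joint analysis of one ordinal trait (threshold-linked, `K >= 3`) and one
#' continuous trait (linear-linked) on the same records:
#' `y | beta, a, G0, R0 ~ N(X beta + Z a, R0 kron I)`,
#' `a | G0, A ~ N(0, G0 kron A)`, flat location priors and minimally proper
#' inverse-Wishart variance priors. The liability scale is identified by
#' fixing the first two thresholds at 0 and 1, so the full 2x2 residual
#' matrix `R0` is estimable. Each cycle samples the liabilities from their
#' conditional normal given the continuous record through `R0`, redraws the
#' free thresholds (Albert-Chib), updates fixed effects single-site and
#' both traits' breeding values jointly per animal, then draws `R0` and
#' `G0` from their inverse-Wishart conditionals.
#'
#' @param mm_cat `ModelMatrices` of the ordinal trait (codes `1..K`).
#' @param mm_cont `ModelMatrices` of the continuous trait; must cover the
#'   same animals in the same order.
#' @param Ainv Sparse A-inverse from [makeAinv()].
#' @param K Number of categories of the ordinal trait (at least 3).
#' @param cfg A `GibbsConfig`.
#' @return A `ChainSamples` with per-draw `g11`, `g12`, `g22`, `r11`,
#'   `r12`, `r22`, genetic correlation `rg`, liability-scale
#'   `h2_cat = g11/(g11+r11)`, `h2_cont`, free thresholds and the
#'   observable-scale `deviance`.
#' @export
gibbs_bivariate <- function(mm_cat, mm_cont, Ainv, K, cfg = gibbs_config()) {
  stopifnot(inherits(mm_cat, "ModelMatrices"),
            inherits(mm_cont, "ModelMatrices"),
            inherits(cfg, "GibbsConfig"))
  if (!identical(mm_cat$animal, mm_cont$animal)) {
    stop("both traits must be observed on the same animals in the same order",
         " (drop animals missing either trait before building the designs)")
  }
  if (nrow(Ainv) != mm_cat$N) stop("Ainv dimension does not match pedigree size")
  K <- as.integer(K)
  if (K < 3L) {
    stop("the bivariate threshold-linear sampler needs K >= 3 (two fixed ",
         "thresholds identify the liability scale)")
  }
  y1 <- as.integer(mm_cat$y)
  if (any(mm_cat$y != y1) || any(y1 < 1L) || any(y1 > K)) {
    stop("ordinal trait must be coded with integers 1..K")
  }
  tab <- tabulate(y1, K)
  if (any(tab == 0L)) {
    stop("categories never observed: ", paste(which(tab == 0L), collapse = ", "))
  }
  cum <- cumsum(tab)[-K] / length(y1)
  q <- stats::qnorm(cum)
  t_start <- (q - q[1L]) / (q[2L] - q[1L])
  t_start[1L] <- 0
  vy2 <- stats::var(mm_cont$y)
  G0_start <- c(0.5, 0, 0.5 * vy2)
  X1 <- csc_parts(mm_cat$X); X2 <- csc_parts(mm_cont$X)
  A <- csc_parts(Ainv)
  # weakly informative inverse-Wishart priors (df p + 3 = 5, diagonal scale
  # centred at the starting values, i.e. 2 effective records): the implied
  # correlation density vanishes at +/-1, which keeps the chain off the
  # singular-G0 boundary where data influence would disappear
  iw_df <- 5
  s0g <- (iw_df - 3) * c(G0_start[1], G0_start[3])
  s0r <- (iw_df - 3) * c(1, 0.5 * vy2)
  set.seed(cfg$seed)
  out <- gibbs_bivariate_cpp(X1$p, X1$i, X1$x, ncol(mm_cat$X), y1, K,
                             X2$p, X2$i, X2$x, ncol(mm_cont$X), mm_cont$y,
                             mm_cat$animal - 1L, mm_cat$N,
                             A$p, A$i, A$x, t_start,
                             as.integer(cfg$n_cycles),
                             as.integer(cfg$burn_in), as.integer(cfg$thin),
                             G0_start, 0.5 * vy2,
                             iw_df, s0g, s0r, 1e-6)
  samples <- as.data.frame(out$samples)
  if (K > 3L) {
    thr <- as.data.frame(out$thresholds)
    names(thr) <- paste0("t", 3:(K - 1L))
    samples <- cbind(samples, thr)
  }
  if (out$n_jitter > 0) {
    message("covariance draws jittered ", out$n_jitter,
            " time(s) to restore positive definiteness")
  }
  new_chain_samples(samples, cfg, "bivariate", K = K,
                    n_jitter = out$n_jitter)
}
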