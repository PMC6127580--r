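#' Monte Carlo error of a chain
#'
#' Square root of the sample variance of the retained draws divided by the
#' number of draws — the standard error of the posterior-mean estimate
#' attributable to finite chain length (independence approximation).
#'
#' @param chain Numeric vector of retained draws (length >= 2).
#' @return Non-negative scalar.
#' @examples
#' mce(c(1, 2, 3, 4))  # sqrt(1.6667/4) = 0.6455
#' @export
mce <- function(chain) {
  n <- length(chain)
  if (n < 2L) stop("need at least 2 draws")
  sqrt(stats::var(chain) / n)
}

# spectral density at frequency zero of the mean estimate, by 20
# non-overlapping batch means: returns var(mean) = var(batch means)/n_batch
batch_var_of_mean <- function(x, n_batches = 20L) {
  n <- length(x)
  b <- n %/% n_batches
  if (b < 1L) stop("window too small for ", n_batches, " batches")
  x <- x[seq_len(b * n_batches)]
  bm <- colMeans(matrix(x, nrow = b))
  v <- stats::var(bm)
  if (v == 0) stop("zero-variance window: Geweke Z undefined")
  v / n_batches
}

#' Geweke convergence diagnostic
#'
#' Z-test of equality of the chain mean between an early window (first
#' `frac_a` of the draws) and a late window (last `frac_b`), with the
#' variance of each window mean estimated by non-overlapping batch means
#' (a spectral-density-at-zero estimate). Under stationarity Z ~ N(0,1).
#'
#' @param chain Numeric vector of retained draws.
#' @param frac_a Fraction of the chain in the early window (default 0.1).
#' @param frac_b Fraction in the late window (default 0.5).
#' @return List with `z` and two-sided `p`.
#' @export
geweke <- function(chain, frac_a = 0.1, frac_b = 0.5) {
  n <- length(chain)
  na <- floor(frac_a * n); nb <- floor(frac_b * n)
  if (na < 20L || nb < 20L) {
    stop("Geweke windows need at least 20 draws each (have ", na, " and ",
         nb, ")")
  }
  a <- chain[seq_len(na)]
  b <- chain[seq.int(n - nb + 1L, n)]
  z <- (mean(a) - mean(b)) / sqrt(batch_var_of_mean(a) + batch_var_of_mean(b))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Posterior summary of one chain
#'
#' Mean, median, equal-tail credible interval, Monte Carlo error and Geweke
#' diagnostic for a single monitored parameter. The `mce_stable` flag
#' records whether adding the Monte Carlo error to the posterior mean leaves
#' the estimate unchanged at the second decimal place (the convergence
#' confirmation used alongside the Geweke test).
#'
#' @param chain Numeric vector of retained draws (>= 2; Geweke columns are
#'   `NA` when the chain is too short or degenerate).
#' @param level Credible level (default 0.95, equal-tail).
#' @return One-row data.frame: `mean`, `median`, `lower`, `upper`, `mce`,
#'   `geweke_z`, `geweke_p`, `mce_stable`, `n`.
#' @export
summarize_chain <- function(chain, level = 0.95) {
  if (length(chain) < 2L) stop("need at least 2 draws")
  qs <- stats::quantile(chain, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  m <- mean(chain)
  err <- mce(chain)
  gw <- tryCatch(geweke(chain), error = function(e) list(z = NA_real_,
                                                         p = NA_real_))
  data.frame(mean = m, median = stats::median(chain),
             lower = qs[1L], upper = qs[2L], mce = err,
             geweke_z = gw$z, geweke_p = gw$p,
             mce_stable = round(m + err, 2) == round(m, 2),
             n = length(chain))
}

#' Posterior report for a sampler run
#'
#' One [summarize_chain()] row per monitored parameter of a
#' `ChainSamples`.
#'
#' @param chain A `ChainSamples`.
#' @param params Character vector of column names to report (default: all
#'   except the deviance).
#' @param level Credible level.
#' @return A `PosteriorReport` data.frame with a `parameter` column.
#' @export
posterior_report <- function(chain, params = NULL, level = 0.95) {
  stopifnot(inherits(chain, "ChainSamples"))
  if (is.null(params)) params <- setdiff(names(chain$samples), "deviance")
  rows <- lapply(params, function(p) {
    cbind(parameter = p, summarize_chain(chain$samples[[p]], level))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("PosteriorReport", "data.frame")
  out
}

#' @export
print.PosteriorReport <- function(x, digits = 4, ...) {
  cat("Posterior report (", x$n[1L], " retained samples)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a posterior report as CSV and text
#'
#' @param report A `PosteriorReport`.
#' @param path CSV output path; a `.txt` rendering is written alongside.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  txt <- paste0(sub("\\.csv$", "", path), ".txt")
  sink(txt); print(report); sink()
  invisible(path)
}
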