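# MCMC convergence diagnostics: split-chain potential scale reduction and
# the Geweke stationarity z-score.

#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain drift also inflates the statistic):
#' `R-hat = sqrt(((n-1)/n W + B/n) / W)` over the split halves. A degenerate
#' zero-variance input returns 1 with attribute `degenerate = TRUE`.
#'
#' @param draws matrix (iterations x chains) or list of equal-length numeric
#'   vectors; >= 2 chains of >= 10 draws.
#' @return R-hat (finite-sample values slightly below 1 are possible).
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2 || nrow(draws) < 10)
    stop("gelman_rubin(): need >= 2 chains of >= 10 draws")
  n2 <- floor(nrow(draws) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(n2), j], draws[nrow(draws) - n2 + seq_len(n2), j])))
  W <- mean(apply(halves, 2, stats::var))
  if (W == 0 || !is.finite(W)) {
    r <- 1
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  B_over_n <- stats::var(colMeans(halves))
  sqrt(((n2 - 1) / n2 * W + B_over_n) / W)
}

# spectral density at frequency zero from an AIC-selected AR fit
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  fit <- try(stats::ar(x, aic = TRUE), silent = TRUE)
  if (inherits(fit, "try-error")) return(v)
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `frac1` of a chain against the mean of the
#' last `frac2`, standardized by spectral-density-at-zero variance
#' estimates: `z = (mean_a - mean_b) / sqrt(s_a/n_a + s_b/n_b)`. |z| < 1.96
#' is the conventional pass. A constant chain returns z = 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param x single-chain numeric vector, length >= 100.
#' @param frac1 leading fraction (default 0.1).
#' @param frac2 trailing fraction (default 0.5).
#' @return z score.
#' @export
geweke <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 100) stop("geweke(): chain too short (need >= 100)")
  if (frac1 + frac2 > 1) stop("geweke(): overlapping windows")
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[(n - max(2, floor(frac2 * n)) + 1):n]
  if (stats::var(x) == 0) {
    z <- 0
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  denom <- sqrt(spectrum0_ar(a) / length(a) + spectrum0_ar(b) / length(b))
  (mean(a) - mean(b)) / denom
}
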