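#' Individual specialization index
#'
#' Normalized Euclidean distance between a diet composition and the
#' ultra-generalist diet `g = (1/K, ..., 1/K)`. The normalizing constant
#' `sqrt((K-1)/K)` is the distance from `g` to any vertex of the simplex, so
#' the index is 0 for a consumer feeding equally on all resources and exactly
#' 1 for a consumer feeding on a single resource.
#'
#' @param p diet proportion vector on the K-simplex, K >= 2.
#' @param tol tolerance for the simplex check.
#' @return specialization index in [0, 1].
#' @examples
#' epsilon(rep(1 / 6, 6))      # ultra-generalist -> 0
#' epsilon(c(1, 0, 0, 0, 0, 0)) # ultra-specialist -> 1
#' @export
epsilon <- function(p, tol = 1e-9) {
  K <- length(p)
  if (K < 2) stop("epsilon() needs a diet vector of length >= 2")
  if (!is_simplex(p, tol)) stop("epsilon(): input is not on the simplex")
  g <- rep(1 / K, K)
  min(1, sqrt(sum((p - g)^2)) / sqrt((K - 1) / K))
}

# vectorized over rows; assumes rows already on the simplex
epsilon_rows <- function(P) {
  K <- ncol(P)
  g <- 1 / K
  pmin(1, sqrt(rowSums((P - g)^2)) / sqrt((K - 1) / K))
}

#' Specialization summaries from a diet posterior
#'
#' Computes the specialization index for every posterior draw of every unit
#' (individual and group) and summarizes it. Because the index is a convex
#' function of the diet, the index of the posterior-mean diet is not the mean
#' of the per-draw indices; both are reported.
#'
#' @param posterior a `diet_posterior` object from [fit_mixing_model()].
#' @return a data frame of class `specialization_result` with columns
#'   `unit_type`, `unit_id`, `eps_mean`, `eps_sd`, `eps_q2.5`, `eps_q97.5`,
#'   `eps_of_mean_diet`, and `K`.
#' @export
epsilon_posterior <- function(posterior) {
  stopifnot(inherits(posterior, "diet_posterior"))
  if (n_draws(posterior) == 0L) stop("epsilon_posterior(): empty posterior")
  summarize_unit <- function(draws, type, ids) {
    # draws: ndraw x nunit x K
    do.call(rbind, lapply(seq_along(ids), function(u) {
      P <- draws[, u, , drop = TRUE]
      if (is.null(dim(P))) P <- matrix(P, nrow = 1)
      e <- epsilon_rows(P)
      data.frame(
        unit_type = type, unit_id = ids[u],
        eps_mean = mean(e), eps_sd = stats::sd(e),
        eps_q2.5 = unname(stats::quantile(e, 0.025)),
        eps_q97.5 = unname(stats::quantile(e, 0.975)),
        eps_of_mean_diet = epsilon(colMeans(P) / sum(colMeans(P))),
        K = ncol(P), stringsAsFactors = FALSE
      )
    }))
  }
  gd <- pooled_draws(posterior, "group")
  id <- pooled_draws(posterior, "individual")
  out <- rbind(
    summarize_unit(gd, "group", posterior$groups),
    summarize_unit(id, "individual", posterior$individuals)
  )
  rownames(out) <- NULL
  class(out) <- c("specialization_result", class(out))
  out
}

#' Classify a feeding strategy from a specialization index
#'
#' Interval classification with configurable thresholds. Defaults follow the
#' commonly used bands for this index: below 0.34 a generalist, between the
#' specialist-generalist band bounds an intermediate strategy, above it a
#' specialist. Boundary values fall in the less specialized class.
#'
#' @param eps specialization index value(s) in [0, 1].
#' @param thresholds numeric vector `c(generalist, specialist)` of strictly
#'   increasing cut points: `eps <= thresholds[1]` is a generalist,
#'   `eps > thresholds[2]` a specialist, anything between a
#'   specialist-generalist.
#' @return character vector of labels.
#' @export
classify_strategy <- function(eps, thresholds = c(0.34, 0.6)) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0)
    stop("classify_strategy(): thresholds must be two increasing values")
  if (any(eps < -1e-9 | eps > 1 + 1e-9, na.rm = TRUE))
    stop("classify_strategy(): index outside [0, 1]")
  ifelse(eps <= thresholds[1], "generalist",
         ifelse(eps <= thresholds[2], "specialist-generalist", "specialist"))
}
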