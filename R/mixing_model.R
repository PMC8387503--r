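# Bayesian two-tracer stable-isotope mixing model.
#
# Consumer tracer values are modelled as draws from the process-error
# mixture distribution
#   x_ij ~ Normal( sum_k p_jk (mu_ik + lambda_i),
#                  sum_k p_jk^2 (sigma_ik^2 + tau_i^2) )
# where mu/sigma are plug-in source moments, lambda/tau the trophic
# discrimination factor mean/SD, and p_j the individual diet composition.
# Diets are parameterized on ILR coordinates: a fixed-effect coordinate
# vector per group plus an individual random deviation with a half-normal
# scale hyperprior. The Dirichlet prior on group diets is induced exactly
# through the ILR log-Jacobian. Sampling is by adaptive random-walk
# Metropolis with independent group / individual blocks.

as_source_params <- function(sources) {
  if (is.data.frame(sources)) {
    stopifnot(all(c("name", "mu_c", "sd_c", "mu_n", "sd_n") %in%
                    names(sources)))
    lst <- lapply(seq_len(nrow(sources)), function(i)
      source_spec(sources$name[i], NA, sources$mu_c[i], sources$sd_c[i],
                  sources$mu_n[i], sources$sd_n[i],
                  n = if ("n" %in% names(sources)) sources$n[i] else 1L))
    sources <- lst
  }
  if (inherits(sources, "source_spec")) sources <- list(sources)
  nm <- vapply(sources, `[[`, "", "name")
  mu <- cbind(vapply(sources, `[[`, 0, "mu_c"),
              vapply(sources, `[[`, 0, "mu_n"))
  sd <- cbind(vapply(sources, `[[`, 0, "sd_c"),
              vapply(sources, `[[`, 0, "sd_n"))
  dimnames(mu) <- dimnames(sd) <- list(nm, c("d13C", "d15N"))
  if (any(sd < 0)) stop("negative source SD")
  list(names = nm, mu = mu, sd = sd, K = length(nm))
}

#' Process-error mixture moments
#'
#' Mean and variance of a consumer tracer value implied by a diet `p`:
#' `mean_i = sum_k p_k (mu_ik + lambda_i)` and
#' `var_i = sum_k p_k^2 (sigma_ik^2 + tau_i^2)` (process-error form: all
#' scatter comes from source and TDF uncertainty, weighted by the squared
#' diet proportions).
#'
#' @param p diet vector on the simplex.
#' @param sources list of [source_spec()] (or data frame with `name`,
#'   `mu_c`, `sd_c`, `mu_n`, `sd_n`).
#' @param tdf a [tdf_spec()].
#' @return list with `mean` and `var`, each named `c(d13C, d15N)`.
#' @export
mixture_moments <- function(p, sources, tdf = tdf_spec()) {
  sp <- as_source_params(sources)
  if (length(p) != sp$K) stop("mixture_moments(): diet length != K sources")
  if (!is_simplex(p)) stop("mixture_moments(): p not on the simplex")
  lambda <- c(tdf$mean_c, tdf$mean_n)
  tau2 <- c(tdf$sd_c, tdf$sd_n)^2
  m <- drop(p %*% sweep(sp$mu, 2, lambda, "+"))
  v <- drop((p^2) %*% sweep(sp$sd^2, 2, tau2, "+"))
  list(mean = m, var = v)
}

#' Process-error log likelihood of consumer tracer values
#'
#' Sum over tracers of the normal log density at the
#' [mixture_moments()] of `p`. A zero mixture variance contributes 0 when
#' the value matches the mixture mean exactly (degenerate point mass) and
#' `-Inf` otherwise.
#'
#' @param values named numeric `c(d13C = ..., d15N = ...)` (or a matrix with
#'   those columns; rows are summed).
#' @param p diet vector.
#' @inheritParams mixture_moments
#' @return log density.
#' @export
log_likelihood <- function(values, p, sources, tdf = tdf_spec()) {
  mom <- mixture_moments(p, sources, tdf)
  if (is.matrix(values) || is.data.frame(values))
    values <- as.matrix(values[, c("d13C", "d15N")])
  else values <- matrix(values[c("d13C", "d15N")], 1,
                        dimnames = list(NULL, c("d13C", "d15N")))
  ll <- 0
  for (i in 1:2) {
    if (mom$var[i] == 0) {
      ll <- ll + sum(ifelse(abs(values[, i] - mom$mean[i]) < 1e-12, 0, -Inf))
    } else {
      ll <- ll + sum(stats::dnorm(values[, i], mom$mean[i],
                                  sqrt(mom$var[i]), log = TRUE))
    }
  }
  ll
}

#' Mixing model run configuration
#'
#' @param prior Dirichlet concentration vector for group diets (recycled to
#'   K at fit time; default flat, all 1).
#' @param chains number of MCMC chains (>= 2 recommended for diagnostics).
#' @param iterations,burn_in,thin run length per chain; `iterations` counts
#'   post-adaptation sweeps including burn-in, and draws are stored every
#'   `thin` sweeps after `burn_in`.
#' @param preset run-length preset overriding the three numbers:
#'   `"short"` (2 x 3000 / 1500 / 2: quick checks), `"test"`
#'   (3 x 20000 / 10000 / 10: desk-scale inference, the default),
#'   `"long"` (3 x 100000 / 50000 / 50), `"extreme"`
#'   (3 x 3e6 / 1.5e6 / 500: publication-length runs).
#' @param re_scale half-normal prior scale for the individual random-effect
#'   SD, in ILR units (default 2).
#' @param seed integer seed.
#' @return object of class `mixing_config`.
#' @export
mixing_config <- function(prior = 1, chains = 3, iterations = 20000,
                          burn_in = 10000, thin = 10, preset = NULL,
                          re_scale = 2, seed = 1L) {
  if (!is.null(preset)) {
    p <- switch(preset,
      short = list(2L, 3000L, 1500L, 2L),
      test = list(3L, 20000L, 10000L, 10L),
      long = list(3L, 100000L, 50000L, 50L),
      extreme = list(3L, 3000000L, 1500000L, 500L),
      stop("mixing_config(): unknown preset '", preset, "'"))
    chains <- p[[1]]; iterations <- p[[2]]; burn_in <- p[[3]]; thin <- p[[4]]
  }
  if (iterations <= burn_in)
    stop("mixing_config(): iterations must exceed burn_in")
  if (any(prior <= 0)) stop("mixing_config(): concentration entries must be > 0")
  structure(list(prior = prior, chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 re_scale = re_scale, seed = as.integer(seed)),
            class = "mixing_config")
}

# vectorized process-error log likelihood for a matrix of ILR coordinates
# (one row per individual); returns the per-individual log likelihood
ll_rows <- function(Phi, V, X, mu_adj, var_src) {
  P <- ilr_inv(Phi, V)
  M <- P %*% mu_adj                       # n x 2 means
  W <- (P * P) %*% var_src                # n x 2 variances
  if (any(W <= 0)) return(rep(-Inf, nrow(Phi)))
  rowSums(-0.5 * (log(2 * pi * W) + (X - M)^2 / W))
}

# Dirichlet(alpha) log prior on group ILR coordinates, Jacobian included:
# log Dir(p(theta); alpha) + sum_k log p_k + const = sum_k alpha_k log p_k + const
grp_logprior <- function(Theta, V, alpha) {
  P <- ilr_inv(Theta, V)
  drop(log(P) %*% alpha)
}

#' Fit the Bayesian mixing model
#'
#' Adaptive random-walk Metropolis over group-level ILR coordinate vectors
#' (fixed effect), individual ILR deviations (random effect, one vector per
#' consumer, shared SD with a half-normal prior) and the random-effect SD.
#' Proposal scales adapt toward a 30 percent acceptance rate during
#' burn-in. With `likelihood = FALSE` the sampler explores the prior alone,
#' which is useful for verifying that the induced prior on group diets is
#' the configured Dirichlet.
#'
#' @param consumers data frame with columns `id`, `group`, `d13C`, `d15N`.
#' @param sources sources as in [mixture_moments()] (K >= 1).
#' @param config a [mixing_config()].
#' @param tdf a [tdf_spec()].
#' @param likelihood set `FALSE` for a prior-only run.
#' @return object of class `diet_posterior`; see [summarize_posterior()],
#'   [convergence_report()], [epsilon_posterior()].
#' @export
fit_mixing_model <- function(consumers, sources, config = mixing_config(),
                             tdf = tdf_spec(), likelihood = TRUE) {
  sp <- as_source_params(sources)
  K <- sp$K
  stopifnot(is.data.frame(consumers),
            all(c("id", "group", "d13C", "d15N") %in% names(consumers)))
  ids <- as.character(consumers$id)
  grp <- as.character(consumers$group)
  glev <- unique(grp)
  gidx <- match(grp, glev)
  n <- nrow(consumers)
  G <- length(glev)
  X <- as.matrix(consumers[, c("d13C", "d15N")])
  alpha <- rep_len(config$prior, K)
  n_save <- (config$iterations - config$burn_in) %/% config$thin

  if (K == 1) {   # 0-simplex: the posterior is the point p = 1
    draw1 <- array(1, c(n_save, n, 1), dimnames = list(NULL, ids, sp$names))
    drawg <- array(1, c(n_save, G, 1), dimnames = list(NULL, glev, sp$names))
    post <- structure(list(
      ind = rep(list(draw1), config$chains),
      grp = rep(list(drawg), config$chains),
      omega = matrix(0, n_save, config$chains),
      lp = matrix(0, n_save, config$chains),
      individuals = ids, groups = glev, sources = sp$names,
      group_of = stats::setNames(grp, ids), config = config, tdf = tdf),
      class = "diet_posterior")
    return(post)
  }

  V <- ilr_basis(K)
  lambda <- c(tdf$mean_c, tdf$mean_n)
  mu_adj <- sweep(sp$mu, 2, lambda, "+")
  var_src <- sweep(sp$sd^2, 2, c(tdf$sd_c, tdf$sd_n)^2, "+")
  identical_src <- any(duplicated(round(cbind(sp$mu, sp$sd), 10)))
  if (identical_src)
    warning("fit_mixing_model(): sources with identical tracer ",
            "distributions; their individual contributions are not ",
            "identifiable (only their sum is)")

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    Theta <- matrix(stats::rnorm(G * (K - 1), 0, 0.5), G)
    Eta <- matrix(stats::rnorm(n * (K - 1), 0, 0.1), n)
    lom <- log(0.5)
    step_g <- rep(0.5, G); step_i <- rep(0.5, n); step_o <- 0.5
    Phi <- Theta[gidx, , drop = FALSE] + Eta
    ll <- if (likelihood) ll_rows(Phi, V, X, mu_adj, var_src) else numeric(n)
    pg <- grp_logprior(Theta, V, alpha)
    eta_lp <- function(E, om) rowSums(stats::dnorm(E, 0, om, log = TRUE))
    ple <- eta_lp(Eta, exp(lom))
    ind_s <- array(NA_real_, c(n_save, n, K),
                   dimnames = list(NULL, ids, sp$names))
    grp_s <- array(NA_real_, c(n_save, G, K),
                   dimnames = list(NULL, glev, sp$names))
    om_s <- numeric(n_save); lp_s <- numeric(n_save)
    si <- 0L
    for (it in seq_len(config$iterations)) {
      adapting <- it <= config$burn_in
      # --- group fixed effects (independent blocks) ---
      Theta_star <- Theta + matrix(stats::rnorm(G * (K - 1)), G) * step_g
      Phi_star <- Theta_star[gidx, , drop = FALSE] + Eta
      ll_star <- if (likelihood) ll_rows(Phi_star, V, X, mu_adj, var_src)
                 else numeric(n)
      pg_star <- grp_logprior(Theta_star, V, alpha)
      dll <- rowsum(ll_star - ll, gidx, reorder = TRUE)[, 1]
      acc <- log(stats::runif(G)) < (pg_star - pg + dll)
      acc[is.na(acc)] <- FALSE
      if (any(acc)) {
        Theta[acc, ] <- Theta_star[acc, ]
        pg[acc] <- pg_star[acc]
        rows <- gidx %in% which(acc)
        Phi[rows, ] <- Phi_star[rows, , drop = FALSE]
        ll[rows] <- ll_star[rows]
      }
      if (adapting)
        step_g <- step_g * exp((as.numeric(acc) - 0.3) / sqrt(it))
      # --- individual random effects (independent blocks) ---
      Eta_star <- Eta + matrix(stats::rnorm(n * (K - 1)), n) * step_i
      Phi_star <- Theta[gidx, , drop = FALSE] + Eta_star
      ll_star <- if (likelihood) ll_rows(Phi_star, V, X, mu_adj, var_src)
                 else numeric(n)
      ple_star <- eta_lp(Eta_star, exp(lom))
      acc <- log(stats::runif(n)) < (ple_star - ple + ll_star - ll)
      acc[is.na(acc)] <- FALSE
      if (any(acc)) {
        Eta[acc, ] <- Eta_star[acc, , drop = FALSE]
        Phi[acc, ] <- Phi_star[acc, , drop = FALSE]
        ll[acc] <- ll_star[acc]
        ple[acc] <- ple_star[acc]
      }
      if (adapting)
        step_i <- step_i * exp((as.numeric(acc) - 0.3) / sqrt(it))
      # --- random-effect scale (log walk; half-normal prior) ---
      lom_star <- lom + stats::rnorm(1) * step_o
      ple_star <- eta_lp(Eta, exp(lom_star))
      d <- sum(ple_star) - sum(ple) +
        stats::dnorm(exp(lom_star), 0, config$re_scale, log = TRUE) -
        stats::dnorm(exp(lom), 0, config$re_scale, log = TRUE) +
        lom_star - lom
      if (is.finite(d) && log(stats::runif(1)) < d) {
        lom <- lom_star; ple <- ple_star
        if (adapting) step_o <- step_o * exp(0.7 / sqrt(it))
      } else if (adapting) step_o <- step_o * exp(-0.3 / sqrt(it))
      # --- store ---
      if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
        si <- si + 1L
        ind_s[si, , ] <- ilr_inv(Phi, V)
        grp_s[si, , ] <- ilr_inv(Theta, V)
        om_s[si] <- exp(lom)
        lp_s[si] <- sum(ll) + sum(pg) + sum(ple)
      }
    }
    list(ind = ind_s, grp = grp_s, omega = om_s, lp = lp_s)
  }

  chains <- lapply(seq_len(config$chains), function(ch)
    run_chain(config$seed + 7919L * ch))
  structure(list(
    ind = lapply(chains, `[[`, "ind"),
    grp = lapply(chains, `[[`, "grp"),
    omega = vapply(chains, `[[`, numeric(n_save), "omega"),
    lp = vapply(chains, `[[`, numeric(n_save), "lp"),
    individuals = ids, groups = glev, sources = sp$names,
    group_of = stats::setNames(grp, ids), config = config, tdf = tdf),
    class = "diet_posterior")
}

#' @export
print.diet_posterior <- function(x, ...) {
  cat(sprintf(
    "diet_posterior: %d sources, %d groups, %d individuals, %d chains x %d draws\n",
    length(x$sources), length(x$groups), length(x$individuals),
    length(x$ind), n_draws(x) / length(x$ind)))
  invisible(x)
}

#' Number of stored posterior draws (all chains)
#' @param posterior a `diet_posterior`.
#' @return integer.
#' @export
n_draws <- function(posterior) {
  sum(vapply(posterior$ind, function(a) dim(a)[1], 0L))
}

#' Pooled posterior draws across chains
#'
#' @param posterior a `diet_posterior`.
#' @param what `"individual"` or `"group"` level draws.
#' @return array `[draw, unit, source]` with chains concatenated.
#' @export
posterior_draws <- function(posterior, what = c("individual", "group")) {
  pooled_draws(posterior, what)
}

# pooled draws across chains: array [draws, units, sources]
pooled_draws <- function(posterior, what = c("individual", "group")) {
  what <- match.arg(what)
  lst <- if (what == "individual") posterior$ind else posterior$grp
  out <- do.call(abind1, lst)
  dimnames(out) <- dimnames(lst[[1]])
  out
}

abind1 <- function(...) {
  lst <- list(...)
  d <- dim(lst[[1]])
  out <- array(NA_real_, c(sum(vapply(lst, function(a) dim(a)[1], 0L)),
                           d[2], d[3]))
  at <- 0L
  for (a in lst) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Summarize a diet posterior
#'
#' Per-unit mean, SD and equal-tailed 95 percent credible interval of each
#' source's diet proportion. Units are groups, individuals, or periods
#' (periods pool the draws of their member individuals via `periods`, a
#' named vector mapping individual id to period label).
#'
#' @param posterior a `diet_posterior`.
#' @param by `"group"`, `"individual"` or `"period"`.
#' @param periods named character vector (id -> period), required for
#'   `by = "period"`.
#' @return data frame: `unit_type`, `unit_id`, `source`, `mean`, `sd`,
#'   `q2.5`, `q97.5`.
#' @export
summarize_posterior <- function(posterior, by = c("group", "individual",
                                                  "period"),
                                periods = NULL) {
  by <- match.arg(by)
  stopifnot(inherits(posterior, "diet_posterior"))
  if (n_draws(posterior) == 0) stop("summarize_posterior(): empty posterior")
  summarize_arr <- function(draws, type, ids) {
    do.call(rbind, lapply(seq_along(ids), function(u) {
      P <- draws[, u, , drop = FALSE]
      dim(P) <- c(dim(P)[1], dim(P)[3])
      data.frame(unit_type = type, unit_id = ids[u],
                 source = posterior$sources,
                 mean = colMeans(P), sd = apply(P, 2, stats::sd),
                 q2.5 = apply(P, 2, stats::quantile, 0.025),
                 q97.5 = apply(P, 2, stats::quantile, 0.975),
                 row.names = NULL)
    }))
  }
  if (by == "group")
    return(summarize_arr(pooled_draws(posterior, "group"), "group",
                         posterior$groups))
  if (by == "individual")
    return(summarize_arr(pooled_draws(posterior, "individual"), "individual",
                         posterior$individuals))
  if (is.null(periods))
    stop("summarize_posterior(): by = 'period' needs a periods mapping")
  ind <- pooled_draws(posterior, "individual")
  per <- periods[posterior$individuals]
  if (anyNA(per)) stop("summarize_posterior(): unmapped individual id")
  do.call(rbind, lapply(unique(per), function(p) {
    sel <- ind[, per == p, , drop = FALSE]
    P <- matrix(aperm(sel, c(1, 2, 3)), ncol = dim(sel)[3])
    data.frame(unit_type = "period", unit_id = p,
               source = posterior$sources,
               mean = colMeans(P), sd = apply(P, 2, stats::sd),
               q2.5 = apply(P, 2, stats::quantile, 0.025),
               q97.5 = apply(P, 2, stats::quantile, 0.975),
               row.names = NULL)
  }))
}

#' Convergence report for a diet posterior
#'
#' Split-chain [gelman_rubin()] R-hat across chains and per-chain
#' [geweke()] z for every group-level proportion and the random-effect SD.
#' The conventional thresholds (R-hat < 1.1, |z| < 1.96) give the pass
#' flags; failure is reported, never raised, so a non-converged run can
#' still be inspected.
#'
#' @param posterior a `diet_posterior`.
#' @param rhat_threshold,z_threshold pass thresholds.
#' @return data frame `parameter`, `rhat`, `geweke_max_abs_z`, `rhat_pass`,
#'   `geweke_pass`; attribute `pass` is the conjunction.
#' @export
convergence_report <- function(posterior, rhat_threshold = 1.1,
                               z_threshold = 1.96) {
  stopifnot(inherits(posterior, "diet_posterior"))
  nch <- length(posterior$grp)
  params <- list()
  for (g in seq_along(posterior$groups))
    for (k in seq_along(posterior$sources))
      params[[paste0("p[", posterior$groups[g], ",",
                     posterior$sources[k], "]")]] <-
        vapply(posterior$grp, function(a) a[, g, k], numeric(dim(posterior$grp[[1]])[1]))
  params[["omega"]] <- posterior$omega
  rows <- lapply(names(params), function(nm) {
    m <- params[[nm]]
    rh <- as.numeric(gelman_rubin(m))
    gz <- if (nrow(m) >= 100)
      max(abs(vapply(seq_len(ncol(m)), function(j) {
        as.numeric(geweke(m[, j]))
      }, 0))) else NA_real_
    data.frame(parameter = nm, rhat = rh, geweke_max_abs_z = gz)
  })
  out <- do.call(rbind, rows)
  out$rhat_pass <- out$rhat < rhat_threshold
  out$geweke_pass <- is.na(out$geweke_max_abs_z) |
    out$geweke_max_abs_z < z_threshold
  attr(out, "pass") <- all(out$rhat_pass) && all(out$geweke_pass)
  out
}

#' Posterior draws in long format
#'
#' @param posterior a `diet_posterior`.
#' @param what `"individual"` or `"group"` draws.
#' @return data frame `chain`, `iter`, `unit_type`, `unit_id`, `source`,
#'   `proportion`.
#' @export
posterior_long <- function(posterior, what = c("individual", "group")) {
  what <- match.arg(what)
  lst <- if (what == "individual") posterior$ind else posterior$grp
  ids <- if (what == "individual") posterior$individuals else posterior$groups
  do.call(rbind, lapply(seq_along(lst), function(ch) {
    a <- lst[[ch]]
    nd <- dim(a)[1]
    data.frame(chain = ch,
               iter = rep(seq_len(nd), times = length(ids) * length(posterior$sources)),
               unit_type = what,
               unit_id = rep(rep(ids, each = nd), times = length(posterior$sources)),
               source = rep(posterior$sources, each = nd * length(ids)),
               proportion = as.vector(a))
  }))
}
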