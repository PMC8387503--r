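# Seeded generators for prey isotope samples, consumer tissue values and
# compositional fatty-acid profiles, so the whole inference pipeline can be
# exercised without any field data.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Define a prey source
#'
#' Per-tracer mean/SD (per mil) of a prey species or functional group, with
#' its sample size and an optional Dirichlet concentration vector driving the
#' simulation of its fatty-acid signature.
#'
#' @param name species or group label.
#' @param region sampling region label (e.g. `"Est"`, `"Gulf"`, or `NA`).
#' @param mu_c,sd_c d13C mean and SD (per mil).
#' @param mu_n,sd_n d15N mean and SD (per mil).
#' @param n integer sample count (>= 1).
#' @param cn_ratio,pct_lipid optional descriptive means carried into
#'   generated tables.
#' @param fa_alpha optional positive Dirichlet concentration vector for FA
#'   profile simulation.
#' @return object of class `source_spec`.
#' @export
source_spec <- function(name, region = NA_character_, mu_c, sd_c, mu_n, sd_n,
                        n, cn_ratio = NA_real_, pct_lipid = NA_real_,
                        fa_alpha = NULL) {
  if (sd_c < 0 || sd_n < 0)
    stop("source_spec('", name, "'): SDs must be >= 0")
  if (n < 1) stop("source_spec('", name, "'): n must be >= 1")
  if (!is.null(fa_alpha) && any(fa_alpha <= 0))
    stop("source_spec('", name, "'): fa_alpha entries must be > 0")
  structure(list(name = name, region = region,
                 mu_c = mu_c, sd_c = sd_c, mu_n = mu_n, sd_n = sd_n,
                 n = as.integer(n), cn_ratio = cn_ratio,
                 pct_lipid = pct_lipid, fa_alpha = fa_alpha),
            class = "source_spec")
}

#' Reference isotope values of potential fin whale prey
#'
#' Mean and SD of d13C and d15N (per mil, lipid-corrected, undiscriminated)
#' for the seven potential prey taxa sampled in the Estuary and Gulf of
#' St. Lawrence, with stable-isotope sample sizes, C:N ratios and percent
#' lipid. These values parameterize the default synthetic scenarios.
#'
#' @return list of [source_spec()] objects.
#' @export
egsl_prey_specs <- function() {
  list(
    source_spec("Sandlance", "Est",  -18.7, 0.5, 10.8, 0.3,  21, 3.16, 2.9),
    source_spec("Sandlance", "Gulf", -18.8, 0.5, 10.9, 0.4,   6, 3.17, 3.7),
    source_spec("Copepods",  "Est",  -18.4, 0.9,  9.3, 0.4,  42, 3.25, 16.5),
    source_spec("Herring",   "Est",  -17.9, 0.9, 12.7, 0.6,  40, 3.12, 7.1),
    source_spec("Herring",   "Gulf", -19.6, 0.3, 12.2, 0.5,  10, 3.22, NA),
    source_spec("Capelin",   "Est",  -18.7, 0.3, 12.4, 0.4, 100, 3.16, 2.8),
    source_spec("Capelin",   "Gulf", -19.5, 0.2, 12.1, 0.4,  10, 3.14, NA),
    source_spec("NorthernKrill", "Est", -19.5, 0.5, 10.7, 0.4, 110, 3.20, 3.2),
    source_spec("Amphipods", "Est",  -19.2, 0.4, 11.9, 0.4,  34, 3.38, 4.2),
    source_spec("ArcticKrill", "Est", -18.7, 0.3,  9.3, 0.6,  28, 3.23, 6.5)
  )
}

#' Pool source specs into functional groups
#'
#' Combines species-level specs into functional-group specs using exact
#' moment pooling: the pooled mean is the sample-size-weighted mean and the
#' pooled variance includes the between-species spread, matching the moments
#' of the concatenated samples.
#'
#' @param specs list of [source_spec()].
#' @param group_map named character vector mapping `"name.region"` (or
#'   `"name"` when region is NA) to a functional-group label; unmapped specs
#'   keep their own name.
#' @return list of pooled [source_spec()] objects, in first-appearance order
#'   of the group labels.
#' @export
pool_source_specs <- function(specs, group_map) {
  key <- vapply(specs, function(s)
    if (is.na(s$region)) s$name else paste(s$name, s$region, sep = "."), "")
  grp <- ifelse(key %in% names(group_map), group_map[key],
                vapply(specs, `[[`, "", "name"))
  out <- list()
  for (g in unique(grp)) {
    ss <- specs[grp == g]
    n <- vapply(ss, `[[`, 1L, "n")
    pool1 <- function(mu_f, sd_f) {
      mu <- vapply(ss, `[[`, 1, mu_f); sd <- vapply(ss, `[[`, 1, sd_f)
      m <- sum(n * mu) / sum(n)
      v <- sum(n * (sd^2 + mu^2)) / sum(n) - m^2
      c(m, sqrt(max(v, 0)))
    }
    cc <- pool1("mu_c", "sd_c"); nn <- pool1("mu_n", "sd_n")
    out[[g]] <- source_spec(g, NA_character_, cc[1], cc[2], nn[1], nn[2],
                            sum(n))
  }
  unname(out)
}

#' Trophic discrimination factor specification
#'
#' Mean per-tracer isotopic offset between consumer tissue and diet, with the
#' SD expressing uncertainty in that offset. Defaults are the cetacean skin
#' values used for balaenopterids: 1.0 +/- 0.5 per mil for carbon and
#' 1.7 +/- 0.5 per mil for nitrogen.
#'
#' @param mean_c,sd_c carbon TDF mean and SD (per mil).
#' @param mean_n,sd_n nitrogen TDF mean and SD (per mil).
#' @return object of class `tdf_spec`.
#' @export
tdf_spec <- function(mean_c = 1.0, sd_c = 0.5, mean_n = 1.7, sd_n = 0.5) {
  if (sd_c < 0 || sd_n < 0) stop("tdf_spec(): SDs must be >= 0")
  structure(list(mean_c = mean_c, sd_c = sd_c, mean_n = mean_n, sd_n = sd_n),
            class = "tdf_spec")
}

#' Define a simulation scenario
#'
#' A full forward-model description: prey sources, consumer groups with true
#' diet vectors, TDFs and noise terms. Consumer tracer values are drawn from
#' the process-error mixing distribution (see [mixture_moments()]) with
#' additional process and analytical noise added in variance.
#'
#' @param sources list of [source_spec()] objects (the mixing sources).
#' @param groups data frame with columns `group`, `period`, `n`, and one
#'   `diet.<source name>` column per source; each diet row must lie on the
#'   simplex.
#' @param tdf a [tdf_spec()].
#' @param process_sd_extra length-2 extra process SD `c(C, N)` in per mil.
#' @param analytical_sd length-2 instrument SD, defaults `c(0.11, 0.12)`.
#' @param period_windows named list mapping each period label to a
#'   `c(start, end)` pair of dates for uniform date assignment.
#' @param seed integer default seed for generation.
#' @return object of class `scenario`.
#' @export
scenario <- function(sources, groups, tdf = tdf_spec(),
                     process_sd_extra = c(0, 0),
                     analytical_sd = c(0.11, 0.12),
                     period_windows = NULL, seed = 1L) {
  src_names <- vapply(sources, `[[`, "", "name")
  diet_cols <- paste0("diet.", src_names)
  if (!all(diet_cols %in% names(groups)))
    stop("scenario(): groups must carry one diet.<source> column per source")
  P <- as.matrix(groups[, diet_cols])
  for (i in seq_len(nrow(P)))
    if (!is_simplex(P[i, ], tol = 1e-12))
      stop("scenario(): diet vector of group '", groups$group[i],
           "' is not on the simplex")
  if (is.null(period_windows)) {
    period_windows <- lapply(unique(groups$period), function(p)
      as.Date(c("2000-06-01", "2000-11-30")))
    names(period_windows) <- unique(groups$period)
  }
  structure(list(sources = sources, groups = groups, diets = P,
                 source_names = src_names, tdf = tdf,
                 process_sd_extra = process_sd_extra,
                 analytical_sd = analytical_sd,
                 period_windows = period_windows,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' Default regime-shift scenario
#'
#' Ships the package's illustrative study design: six prey functional groups
#' parameterized by pooling the reference prey values
#' ([egsl_prey_specs()]), three pre-period consumer groups (one highly
#' selective for Arctic krill/copepods, one for capelin/herring, one
#' intermediate) and two post-period groups (one zooplankton
#' specialist-generalist, one generalist with more pelagic fish). The diets
#' are illustrative, chosen to span specialist to generalist strategies, not
#' ground truth for any real population.
#'
#' @param seed integer seed stored in the scenario.
#' @return a [scenario()].
#' @export
scenario_regime_shift <- function(seed = 1L) {
  gm <- c("ArcticKrill.Est" = "ArcticKrillCopepods",
          "Copepods.Est" = "ArcticKrillCopepods",
          "Capelin.Est" = "CapelinHerringEst",
          "Herring.Est" = "CapelinHerringEst",
          "Capelin.Gulf" = "CapelinHerringGulf",
          "Herring.Gulf" = "CapelinHerringGulf",
          "NorthernKrill.Est" = "NorthernKrill",
          "Amphipods.Est" = "Amphipods",
          "Sandlance.Est" = "Sandlance",
          "Sandlance.Gulf" = "Sandlance")
  srcs <- pool_source_specs(egsl_prey_specs(), gm)
  ord <- match(c("ArcticKrillCopepods", "NorthernKrill", "CapelinHerringEst",
                 "CapelinHerringGulf", "Amphipods", "Sandlance"),
               vapply(srcs, `[[`, "", "name"))
  srcs <- srcs[ord]
  diets <- rbind(
    g1.1 = c(0.89, 0.02, 0.05, 0.01, 0.02, 0.01),
    g1.2 = c(0.45, 0.03, 0.42, 0.04, 0.03, 0.03),
    g1.3 = c(0.10, 0.03, 0.78, 0.04, 0.03, 0.02),
    g2.1 = c(0.55, 0.33, 0.03, 0.02, 0.05, 0.02),
    g2.2 = c(0.25, 0.18, 0.22, 0.15, 0.10, 0.10)
  )
  colnames(diets) <- paste0("diet.", vapply(srcs, `[[`, "", "name"))
  groups <- cbind(
    data.frame(group = rownames(diets),
               period = c("pre", "pre", "pre", "post", "post"),
               n = c(10L, 24L, 6L, 16L, 24L)),
    as.data.frame(diets, row.names = FALSE)
  )
  scenario(srcs, groups,
           tdf = tdf_spec(),
           period_windows = list(
             pre = as.Date(c("1998-06-01", "2001-11-30")),
             post = as.Date(c("2002-06-01", "2006-11-30"))),
           seed = seed)
}

#' Generate prey isotope samples
#'
#' Draws per-spec samples with each tracer independent
#' `Normal(mu, sd)` (no cross-tracer covariance, as only marginal moments
#' are specified).
#'
#' @param specs list of [source_spec()].
#' @param seed integer seed.
#' @param n_override optional single count overriding every spec's `n`.
#' @return data frame with columns `species`, `region`, `year`, `d13C`,
#'   `d15N`, `cn_ratio`, `pct_lipid`.
#' @export
generate_prey_samples <- function(specs, seed = 1L, n_override = NULL) {
  if (length(specs) == 0) stop("generate_prey_samples(): no specs")
  with_seed(seed, {
    do.call(rbind, lapply(specs, function(s) {
      n <- if (is.null(n_override)) s$n else as.integer(n_override)
      data.frame(species = s$name, region = s$region,
                 year = sample(1999:2005, n, replace = TRUE),
                 d13C = stats::rnorm(n, s$mu_c, s$sd_c),
                 d15N = stats::rnorm(n, s$mu_n, s$sd_n),
                 cn_ratio = s$cn_ratio, pct_lipid = s$pct_lipid)
    }))
  })
}

#' Generate consumer tracer values from a scenario
#'
#' Forward model: consumer j in group g with true diet p gets, per tracer i,
#' `Normal(sum_k p_k (mu_ik + lambda_i),
#'         sum_k p_k^2 (sigma_ik^2 + tau_i^2) + extra_i^2 + analytical_i^2)`,
#' the process-error mixture distribution the inference assumes, plus the
#' configured extra process and analytical noise (added in variance).
#' Sampling dates are uniform within the group's period window.
#'
#' @param scn a [scenario()].
#' @param seed integer seed; defaults to the scenario's.
#' @return list with `consumers` (id, date, period, group, d13C, d15N) and
#'   `truth` (long table id, source, proportion).
#' @export
generate_consumers <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "scenario"))
  mom <- lapply(seq_len(nrow(scn$diets)), function(i)
    mixture_moments(scn$diets[i, ], scn$sources, scn$tdf))
  with_seed(seed, {
    cons <- list(); truth <- list()
    for (i in seq_len(nrow(scn$groups))) {
      g <- scn$groups[i, ]
      m <- mom[[i]]
      sd_c <- sqrt(m$var[1] + scn$process_sd_extra[1]^2 + scn$analytical_sd[1]^2)
      sd_n <- sqrt(m$var[2] + scn$process_sd_extra[2]^2 + scn$analytical_sd[2]^2)
      win <- scn$period_windows[[g$period]]
      ids <- sprintf("%s_%02d", g$group, seq_len(g$n))
      cons[[i]] <- data.frame(
        id = ids,
        date = win[1] + floor(stats::runif(g$n) *
                                (as.numeric(win[2] - win[1]) + 1)),
        period = g$period, group = g$group,
        d13C = stats::rnorm(g$n, m$mean[1], sd_c),
        d15N = stats::rnorm(g$n, m$mean[2], sd_n))
      truth[[i]] <- data.frame(
        id = rep(ids, each = length(scn$source_names)),
        source = rep(scn$source_names, g$n),
        proportion = rep(scn$diets[i, ], g$n))
    }
    list(consumers = do.call(rbind, cons), truth = do.call(rbind, truth))
  })
}

#' Generate compositional fatty-acid profiles
#'
#' One Dirichlet draw per sample, scaled to mass percent (rows sum to 100).
#' Species with well-separated `fa_alpha` vectors produce profiles separable
#' by PERMANOVA/SIMPER downstream. With `no_noise = TRUE` each profile is the
#' Dirichlet mean (a point mass), useful for exact checks.
#'
#' @param specs list of [source_spec()] each carrying `fa_alpha`.
#' @param fa_names character vector naming the FA columns; length must match
#'   every `fa_alpha`.
#' @param seed integer seed.
#' @param n_override optional count overriding every spec's `n`.
#' @param no_noise logical; emit the exact Dirichlet mean instead of draws.
#' @return data frame: `id`, `species`, `region`, then one column per FA.
#' @export
generate_fa_profiles <- function(specs, fa_names, seed = 1L,
                                 n_override = NULL, no_noise = FALSE) {
  for (s in specs) {
    if (is.null(s$fa_alpha))
      stop("generate_fa_profiles(): spec '", s$name, "' lacks fa_alpha")
    if (length(s$fa_alpha) != length(fa_names))
      stop("generate_fa_profiles(): fa_alpha length of '", s$name,
           "' does not match fa_names")
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(specs, function(s) {
      n <- if (is.null(n_override)) s$n else as.integer(n_override)
      P <- if (no_noise) {
        matrix(rep(s$fa_alpha / sum(s$fa_alpha), each = n), nrow = n)
      } else {
        G <- matrix(stats::rgamma(n * length(s$fa_alpha),
                                  shape = rep(s$fa_alpha, each = n)),
                    nrow = n)
        G / rowSums(G)
      }
      colnames(P) <- fa_names
      cbind(data.frame(species = s$name, region = s$region),
            as.data.frame(P * 100, check.names = FALSE))
    }))
    out <- cbind(id = sprintf("fa_%03d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}
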