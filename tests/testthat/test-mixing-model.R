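test_that("mixture moments follow the process-error formulas", {
  srcs <- list(source_spec("ArcticKrill", NA, -18.7, 0.3, 9.3, 0.6, 28),
               source_spec("CapelinEst", NA, -18.7, 0.3, 12.4, 0.4, 100))
  # single source: mean 9.3 + 1.7 = 11.0, var 0.36 + 0.25 = 0.61
  m <- mixture_moments(c(1, 0), srcs, tdf_spec())
  expect_equal(unname(m$mean[2]), 11.0)
  expect_equal(unname(m$var[2]), 0.61)
  # even split, zero SDs: (9.3 + 12.4)/2 + 1.7 = 12.55, var 0
  m2 <- mixture_moments(c(0.5, 0.5),
                        data.frame(name = c("a", "b"), mu_c = c(-18.7, -18.7),
                                   sd_c = 0, mu_n = c(9.3, 12.4), sd_n = 0),
                        tdf_spec(1.0, 0, 1.7, 0))
  expect_equal(unname(m2$mean[2]), 12.55)
  expect_equal(unname(m2$var[2]), 0)
  # two identical sources: moments independent of p
  same <- data.frame(name = c("a", "b"), mu_c = -19, sd_c = 0.4,
                     mu_n = 10, sd_n = 0.3)
  mA <- mixture_moments(c(0.2, 0.8), same, tdf_spec())
  mB <- mixture_moments(c(0.9, 0.1), same, tdf_spec())
  expect_equal(mA$mean, mB$mean)
  expect_error(mixture_moments(c(1, 0, 0), srcs, tdf_spec()), "length")
  expect_error(mixture_moments(c(0.6, 0.6), srcs, tdf_spec()), "simplex")
})

test_that("log likelihood is a normal density peaked at the mixture mean", {
  src <- data.frame(name = "only", mu_c = -19, sd_c = 0, mu_n = 10, sd_n = 0)
  tdf <- tdf_spec(1.0, 1, 1.7, 1)          # unit variance per tracer
  mode_val <- c(d13C = -18, d15N = 11.7)
  ll0 <- log_likelihood(mode_val, c(1), src, tdf)
  expect_equal(ll0, 2 * (-0.5 * log(2 * pi)))
  # strictly decreasing away from the mode
  lls <- sapply(c(0, 0.5, 1, 2), function(d)
    log_likelihood(mode_val + c(0, d), c(1), src, tdf))
  expect_true(all(diff(lls) < 0))
  # zero variance off the mean is -Inf
  src0 <- data.frame(name = "pt", mu_c = -19, sd_c = 0, mu_n = 10, sd_n = 0)
  expect_equal(log_likelihood(c(d13C = -18, d15N = 12), c(1), src0,
                              tdf_spec(1, 0, 1.7, 0)), -Inf)
})

test_that("likelihood matches a quadrature oracle on a one-source toy", {
  # with one source, the marginal of x over the TDF uncertainty is
  # integral N(x; mu + l, sigma^2) N(l; lambda, tau^2) dl, which the
  # process-error likelihood treats as N(mu + lambda, sigma^2 + tau^2)
  mu <- 10; sig <- 0.6; lam <- 1.7; tau <- 0.5
  src <- data.frame(name = "s", mu_c = mu, sd_c = sig, mu_n = mu, sd_n = sig)
  for (x in c(10.5, 11.7, 13.2)) {
    num <- stats::integrate(function(l)
      stats::dnorm(x, mu + l, sig) * stats::dnorm(l, lam, tau),
      lam - 8 * tau, lam + 8 * tau, rel.tol = 1e-10)$value
    mine <- stats::dnorm(x, mu + lam, sqrt(sig^2 + tau^2))
    expect_equal(mine, num, tolerance = 1e-6)
    ll <- log_likelihood(c(d13C = x, d15N = x), c(1), src,
                         tdf_spec(lam, tau, lam, tau))
    expect_equal(ll, 2 * log(num), tolerance = 1e-6)
  }
})

test_that("every stored posterior draw lies on the simplex", {
  scn <- k3_scenario(n = 8L, seed = 30)
  cons <- generate_consumers(scn)$consumers
  fit <- fit_mixing_model(cons, k3_sources(),
                          mixing_config(chains = 2, iterations = 400,
                                        burn_in = 200, thin = 2, seed = 30))
  for (a in c(fit$ind, fit$grp)) {
    sums <- apply(a, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(a >= 0))
  }
  expect_equal(n_draws(fit), 2 * 100)
})

test_that("a single source forces the degenerate point posterior", {
  cons <- data.frame(id = c("i1", "i2"), group = "g",
                     d13C = c(-18, -17.9), d15N = c(11.6, 11.8))
  fit <- fit_mixing_model(cons,
                          data.frame(name = "only", mu_c = -19, sd_c = 0.3,
                                     mu_n = 10, sd_n = 0.4),
                          mixing_config(chains = 2, iterations = 200,
                                        burn_in = 100, thin = 1, seed = 1))
  expect_true(all(posterior_draws(fit, "individual") == 1))
  s <- summarize_posterior(fit, "group")
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
})

test_that("a prior-only run induces the configured flat Dirichlet", {
  srcs <- k3_sources()
  cons <- data.frame(id = sprintf("i%02d", 1:10), group = "g1",
                     d13C = -18, d15N = 11)
  fit <- fit_mixing_model(cons, srcs,
                          mixing_config(preset = "short", seed = 7),
                          likelihood = FALSE)
  gd <- posterior_draws(fit, "group")
  means <- apply(gd, 3, mean)
  vars <- apply(gd, 3, stats::var)
  # batch-means Monte-Carlo SE on consecutive blocks
  for (k in 1:3) {
    x <- as.vector(gd[, 1, k])
    nb <- 30
    bm <- tapply(x, ceiling(seq_along(x) / (length(x) / nb)), mean)
    se <- stats::sd(bm) / sqrt(nb)
    expect_lt(abs(means[k] - 1 / 3), 3 * se)
  }
  # Dirichlet(1,1,1) marginal variance = (1/3)(2/3)/4
  expect_equal(unname(vars), rep(1 / 18, 3), tolerance = 0.15)
})

test_that("a noiseless exact mixture concentrates the posterior at truth", {
  srcs <- data.frame(name = c("a", "b", "c"),
                     mu_c = c(-18, -19.5, -17.5), sd_c = 0.02,
                     mu_n = c(9, 11, 13), sd_n = 0.02)
  p_true <- c(0.6, 0.3, 0.1)
  mom <- mixture_moments(p_true, srcs, tdf_spec(1, 0.02, 1.7, 0.02))
  cons <- data.frame(id = "i1", group = "g",
                     d13C = mom$mean[1], d15N = mom$mean[2])
  fit <- fit_mixing_model(cons, srcs,
                          mixing_config(chains = 2, iterations = 6000,
                                        burn_in = 3000, thin = 3, seed = 5),
                          tdf = tdf_spec(1, 0.02, 1.7, 0.02))
  s <- summarize_posterior(fit, "individual")
  expect_equal(s$mean, p_true, tolerance = 0.08)
})

test_that("Monte-Carlo error shrinks like one over sqrt(iterations)", {
  scn <- k3_scenario(n = 6L, seed = 33)
  cons <- generate_consumers(scn)$consumers
  post_mean <- function(iters, seed) {
    fit <- fit_mixing_model(cons, k3_sources(),
                            mixing_config(chains = 2, iterations = iters,
                                          burn_in = iters / 2, thin = 1,
                                          seed = seed))
    mean(posterior_draws(fit, "group")[, 1, 1])
  }
  m1 <- vapply(1:10, function(s) post_mean(600, 50 + s), 0)
  m2 <- vapply(1:10, function(s) post_mean(2400, 70 + s), 0)
  ratio <- stats::sd(m1) / stats::sd(m2)
  expect_gt(ratio, 1.2)      # expected 2, allow wide Monte-Carlo slack
})

test_that("identical sources are reported as non-identifiable", {
  srcs <- data.frame(name = c("a", "b"), mu_c = -19, sd_c = 0.3,
                     mu_n = 10, sd_n = 0.4)
  cons <- data.frame(id = c("i1", "i2"), group = "g",
                     d13C = c(-18, -18.1), d15N = c(11.6, 11.7))
  expect_warning(fit_mixing_model(cons, srcs,
                                  mixing_config(chains = 2, iterations = 60,
                                                burn_in = 30, thin = 1,
                                                seed = 1)),
                 "not\\s+identifiable")
})

test_that("posterior summaries close to one and draws export losslessly", {
  scn <- k3_scenario(n = 6L, seed = 31)
  cons <- generate_consumers(scn)$consumers
  fit <- fit_mixing_model(cons, k3_sources(),
                          mixing_config(chains = 2, iterations = 400,
                                        burn_in = 200, thin = 2, seed = 31))
  for (by in c("group", "individual")) {
    s <- summarize_posterior(fit, by)
    sums <- tapply(s$mean, s$unit_id, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
  per <- summarize_posterior(fit, "period",
                             periods = setNames(rep("pre", 6),
                                                unique(cons$id)))
  expect_equal(sum(per$mean), 1, tolerance = 1e-6)
  expect_error(summarize_posterior(fit, "period"), "periods")
  long <- posterior_long(fit, "group")
  expect_equal(nrow(long), n_draws(fit) * 3)
  expect_equal(mean(long$proportion[long$source == "ArcticKrill"]),
               mean(posterior_draws(fit, "group")[, 1, 1]))
})

test_that("run-length presets and config validation behave", {
  cfg <- mixing_config(preset = "extreme")
  expect_equal(cfg$iterations, 3000000L)
  expect_equal(cfg$thin, 500L)
  expect_error(mixing_config(iterations = 100, burn_in = 200), "exceed")
  expect_error(mixing_config(prior = c(1, 0)), "> 0")
  expect_error(mixing_config(preset = "warp"), "unknown preset")
})
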