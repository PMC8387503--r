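test_that("PERMANOVA reproduces the hand-partitioned worked example", {
  x <- matrix(c(0, 1, 3, 4))
  r <- permanova(x, c("a", "a", "b", "b"))
  expect_equal(r$ss_total, 10)
  expect_equal(r$ss_among, 9)
  expect_equal(r$ss_within, 1)
  expect_equal(r$pseudo_f, 18)
  expect_true(r$exact)                      # 6 relabellings, all enumerated
  expect_equal(r$p_value, 1 / 3)
})

test_that("pseudo-F on 1-D Euclidean data equals the classical ANOVA F", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(6:14, 1)
    g <- sample(rep(c("a", "b", "c"), length.out = n))
    if (min(table(g)) < 2) next
    y <- stats::rnorm(n)
    r <- permanova(matrix(y), g, n_permutations = 9)
    f_aov <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(r$pseudo_f, f_aov, tolerance = 1e-8)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 on multivariate data", {
  skip_if_not_installed("vegan")
  set.seed(11)
  x <- matrix(stats::rnorm(60), 20, 3)
  g <- rep(c("a", "b"), each = 10)
  x[g == "b", 1] <- x[g == "b", 1] + 1
  r <- permanova(x, g, n_permutations = 99, seed = 1)
  va <- vegan::adonis2(stats::dist(x) ~ g, permutations = 99)
  expect_equal(r$pseudo_f, va$F[1], tolerance = 1e-10)
  expect_equal(r$ss_among, va$SumOfSqs[1], tolerance = 1e-10)
  expect_equal(r$ss_total, va$SumOfSqs[3], tolerance = 1e-10)
})

test_that("sums of squares decompose conservatively and errors are raised", {
  set.seed(12)
  x <- matrix(stats::rnorm(45), 15, 3)
  g <- rep(c("a", "b", "c"), each = 5)
  r <- permanova(x, g, n_permutations = 99, seed = 2)
  expect_equal(r$ss_among + r$ss_within, r$ss_total, tolerance = 1e-8)
  expect_gte(r$p_value, 1 / 100)
  expect_lte(r$p_value, 1)
  expect_error(permanova(x[1:6, ], c("a", "a", "a", "a", "a", "b")),
               "singleton")
  expect_error(permanova(matrix(1, 6, 2), rep(c("a", "b"), 3)), "constant")
})

test_that("Monte-Carlo p matches exhaustive enumeration within binomial error", {
  set.seed(13)
  x <- matrix(stats::rnorm(8), 8, 1)
  g <- rep(c("a", "b"), each = 4)
  exact <- permanova(x, g, n_permutations = 999)    # 70 relabellings: exact
  expect_true(exact$exact)
  mc <- permanova(x, g, n_permutations = 59)        # forces Monte-Carlo
  expect_false(mc$exact)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 60)
  expect_lt(abs(mc$p_value - exact$p_value), 4 * se + 2 / 60)
})

test_that("two-factor partial-SS PERMANOVA matches vegan's marginal tests", {
  skip_if_not_installed("vegan")
  set.seed(14)
  n <- 24
  f1 <- rep(c("m", "f"), each = 12)
  f2 <- rep(rep(c("y1", "y2", "y3"), each = 4), 2)
  x <- matrix(stats::rnorm(n * 2), n)
  x[f1 == "m", 1] <- x[f1 == "m", 1] + 0.8
  r <- permanova2(x, f1, f2, n_permutations = 99, seed = 3)
  va <- vegan::adonis2(stats::dist(x) ~ f1 + f2, by = "margin",
                       permutations = 99,
                       data = data.frame(f1 = f1, f2 = f2))
  expect_equal(r$pseudo_f, va$F[1:2], tolerance = 1e-8)
  expect_equal(r$ss, va$SumOfSqs[1:2], tolerance = 1e-8)
})

test_that("BY adjustment matches the brute-force formula and is invariant", {
  # hand arithmetic with c(3) = 11/6: all three adjust to 0.055
  expect_equal(benjamini_yekutieli(c(0.01, 0.02, 0.03)),
               c(0.055, 0.055, 0.055))
  expect_equal(benjamini_yekutieli(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_yekutieli(0.2), 0.2)          # m = 1: identity
  set.seed(15)
  for (i in 1:100) {
    p <- stats::runif(sample(2:12, 1))
    adj <- benjamini_yekutieli(p)
    expect_equal(adj, by_brute(p), tolerance = 1e-12)
    # order invariance and sorted monotonicity
    perm <- sample(length(p))
    expect_equal(benjamini_yekutieli(p[perm]), adj[perm])
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise PERMANOVA adjusts over all pairs", {
  set.seed(16)
  x <- rbind(matrix(stats::rnorm(20), 10), matrix(stats::rnorm(20) + 3, 10))
  g <- rep(c("a", "b"), each = 10)
  pw <- pairwise_permanova(x, g, n_permutations = 99, seed = 1)
  expect_equal(nrow(pw), 1)
  expect_equal(pw$p_adj, pw$p_raw)                     # single pair: identity
  x3 <- rbind(x, matrix(stats::rnorm(20) + 6, 10))
  pw3 <- pairwise_permanova(x3, c(g, rep("c", 10)),
                            n_permutations = 99, seed = 1)
  expect_equal(nrow(pw3), 3)
  expect_equal(pw3$p_adj, benjamini_yekutieli(pw3$p_raw))
})

test_that("isotopically identical species stay non-significant under the null", {
  ok <- vapply(1:20, function(s) {
    sp <- list(source_spec("A", NA, -18.5, 0.4, 9.3, 0.5, 30),
               source_spec("B", NA, -18.5, 0.4, 9.3, 0.5, 30))
    prey <- generate_prey_samples(sp, seed = 1000 + s)
    pw <- pairwise_permanova(prey[, c("d13C", "d15N")], prey$species,
                             n_permutations = 199, seed = s)
    pw$p_adj > 0.05
  }, TRUE)
  expect_gte(sum(ok), 18)
})

test_that("SIMPER decomposes dissimilarity additively and conservatively", {
  set.seed(17)
  x <- rbind(matrix(stats::rnorm(12), 6), matrix(stats::rnorm(12), 6))
  x[7:12, 1] <- x[7:12, 1] + 5
  g <- rep(c("a", "b"), each = 6)
  # single variable contributes 100%
  r1 <- simper(x[, 1, drop = FALSE], g, c("a", "b"))
  expect_equal(r1$table$pct, 100)
  # a null variable contributes 0 when groups differ only in the other
  xn <- cbind(x[, 1], rep(c(0, 1), 6))
  colnames(xn) <- c("A", "B")
  r2 <- simper(xn, g, c("a", "b"))
  expect_gt(r2$table$pct[r2$table$variable == "A"], 95)
  # conservation: contributions sum to mean squared between-group distance
  colnames(x) <- c("v1", "v2")
  r3 <- simper(x, g, c("a", "b"))
  d2 <- as.matrix(stats::dist(x))^2
  expect_equal(r3$overall, mean(d2[1:6, 7:12]), tolerance = 1e-8)
  expect_true(all(r3$table$contribution >= 0))
  expect_error(simper(x, g, c("a", "zzz")), "unknown group")
})

test_that("Bray-Curtis SIMPER conserves the mean Bray-Curtis dissimilarity", {
  set.seed(18)
  x <- matrix(stats::rexp(40), 10)
  g <- rep(c("a", "b"), each = 5)
  r <- simper(x, g, c("a", "b"), method = "bray")
  bc <- function(u, v) sum(abs(u - v)) / sum(u + v)
  m <- mean(sapply(1:5, function(i)
    sapply(6:10, function(j) bc(x[i, ], x[j, ]))))
  expect_equal(r$overall, m, tolerance = 1e-8)
})

test_that("planted informative FAs carry the bulk of the dissimilarity", {
  # 14 informative of 39 FAs: their cumulative contribution exceeds 70%
  fas <- extended_dietary_fas()
  # equal concentration totals so only the first 14 FAs differ in mean
  a1 <- c(rep(c(30, 10), 7), rep(5, 25))
  a2 <- c(rep(c(10, 30), 7), rep(5, 25))
  sp <- list(source_spec("A", NA, -18, 0.3, 9, 0.3, 25, fa_alpha = a1),
             source_spec("B", NA, -18, 0.3, 9, 0.3, 25, fa_alpha = a2))
  prof <- generate_fa_profiles(sp, fas, seed = 19)
  r <- simper(prof[, fas], prof$species, c("A", "B"))
  informative <- fas[1:14]
  cum <- sum(r$table$pct[r$table$variable %in% informative])
  expect_gt(cum, 70)
  expect_true(all(r$top_set %in% r$table$variable))
})

test_that("source merging follows adjusted p, ecology and transitivity", {
  pw <- data.frame(
    group1 = c("ArcticKrill", "ArcticKrill", "Copepods"),
    group2 = c("Copepods", "Capelin", "Capelin"),
    p_adj = c(0.68, 0.001, 0.001))
  map <- merge_sources(pw, alpha = 0.05)
  expect_equal(unname(map["ArcticKrill"]), "ArcticKrill/Copepods")
  expect_equal(map[["ArcticKrill"]], map[["Copepods"]])
  expect_equal(unname(map["Capelin"]), "Capelin")
  # regional split retained when the between-region test is significant
  pw2 <- data.frame(
    group1 = c("Capelin.Est", "Capelin.Est", "Herring.Est"),
    group2 = c("Herring.Est", "Capelin.Gulf", "Capelin.Gulf"),
    p_adj = c(0.92, 0.002, 0.002))
  map2 <- merge_sources(pw2, alpha = 0.05)
  expect_equal(unname(map2["Capelin.Est"]), "Capelin.Est/Herring.Est")
  expect_equal(unname(map2["Capelin.Gulf"]), "Capelin.Gulf")
  # all pairs significant: identity grouping
  pw3 <- data.frame(group1 = c("a", "a", "b"), group2 = c("b", "c", "c"),
                    p_adj = c(0.01, 0.01, 0.01))
  expect_equal(as.character(merge_sources(pw3)), c("a", "b", "c"))
  # ecology veto blocks a statistically mergeable pair
  map4 <- merge_sources(pw, ecology = data.frame(a = "x", b = "y"),
                        alpha = 0.05)
  expect_equal(unname(map4["ArcticKrill"]), "ArcticKrill")
  # transitive closure is logged
  pw5 <- data.frame(group1 = c("a", "a", "b"), group2 = c("b", "c", "c"),
                    p_adj = c(0.9, 0.9, 0.01))
  expect_message(map5 <- merge_sources(pw5), "transitive")
  expect_equal(unname(map5["b"]), "a/b/c")
})
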