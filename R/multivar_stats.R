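# Permutational multivariate tests and prey functional-group aggregation.

as_num_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite values in data matrix")
  m
}

# squared Euclidean distance matrix
sq_dist <- function(x) {
  d <- as.matrix(stats::dist(x, method = "euclidean"))^2
  d
}

ss_within_labels <- function(D2, labels) {
  s <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

# all distinct assignments of n items to groups with the given sizes
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    first <- avail[1L]                    # fix first item to kill symmetry only
    out <- list()                         # within equal-size groups? groups are
    combs <- utils::combn(avail, sizes[1L], simplify = FALSE)  # labelled: keep all
    for (cmb in combs) {
      rest <- setdiff(avail, cmb)
      for (tail in rec(rest, sizes[-1L]))
        out[[length(out) + 1L]] <- c(list(cmb), tail)
    }
    out
  }
  rec(seq_len(n), sizes)
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on Euclidean distances,
#' using the direct distance partitioning: `SS_total = sum_{i<j} d2_ij / N`
#' and `SS_within = sum_g sum_{i<j in g} d2_ij / n_g`. Significance comes
#' from relabelling observations: exhaustive enumeration of all distinct
#' relabellings when there are no more of them than `n_permutations`
#' (p = proportion of relabellings with `F >= F_obs`, the observed one
#' included), otherwise Monte-Carlo with the positively biased estimator
#' `p = (1 + #exceedances) / (1 + n_permutations)`.
#'
#' @param x numeric matrix or data frame (observations in rows), or a `dist`.
#' @param labels group labels, length `nrow(x)`; every group needs >= 2
#'   observations.
#' @param n_permutations number of random permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @return object of class `permanova_result`: `pseudo_f`, `p_value`,
#'   `df_among`, `df_within`, `ss_among`, `ss_within`, `ss_total`,
#'   `n_permutations`, `exact` (logical).
#' @export
permanova <- function(x, labels, n_permutations = 9999, seed = NULL) {
  labels <- as.character(labels)
  D2 <- if (inherits(x, "dist")) as.matrix(x)^2 else sq_dist(as_num_matrix(x))
  N <- nrow(D2)
  if (length(labels) != N) stop("permanova(): labels length mismatch")
  sizes <- table(labels)
  a <- length(sizes)
  if (a < 2) stop("permanova(): need >= 2 groups")
  if (any(sizes < 2)) stop("permanova(): singleton group '",
                           names(sizes)[which.min(sizes)], "'")
  ss_total <- sum(D2) / (2 * N)
  if (ss_total <= 0) stop("permanova(): constant data (zero total SS)")
  df_among <- a - 1L
  df_within <- N - a
  f_of <- function(lab) {
    ssw <- ss_within_labels(D2, lab)
    ((ss_total - ssw) / df_among) / (ssw / df_within)
  }
  ss_within <- ss_within_labels(D2, labels)
  if (ss_within <= 0)
    stop("permanova(): zero within-group SS; groups are internally constant")
  f_obs <- ((ss_total - ss_within) / df_among) / (ss_within / df_within)

  n_distinct <- round(exp(lgamma(N + 1) - sum(lgamma(sizes + 1))))
  exact <- n_distinct <= n_permutations
  if (exact) {
    glab <- names(sizes)
    exceed <- 0L
    for (asg in enumerate_assignments(as.integer(sizes))) {
      lab <- character(N)
      for (k in seq_along(asg)) lab[asg[[k]]] <- glab[k]
      if (f_of(lab) >= f_obs - 1e-12) exceed <- exceed + 1L
    }
    p <- exceed / n_distinct
    n_used <- n_distinct
  } else {
    exceed <- 0L
    with_seed(seed, {
      for (b in seq_len(n_permutations))
        if (f_of(sample(labels)) >= f_obs - 1e-12) exceed <- exceed + 1L
    })
    p <- (1 + exceed) / (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(pseudo_f = f_obs, p_value = p,
                 df_among = df_among, df_within = df_within,
                 ss_among = ss_total - ss_within, ss_within = ss_within,
                 ss_total = ss_total, n_permutations = n_used,
                 exact = exact),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d,%d) = %.4g, p = %.4g (%s, %d perms)\n",
              x$df_among, x$df_within, x$pseudo_f, x$p_value,
              if (x$exact) "exact" else "Monte-Carlo", x$n_permutations))
  invisible(x)
}

#' Two-factor PERMANOVA with partial sums of squares
#'
#' Crossed two-factor design tested with marginal (partial, Type-III-style)
#' sums of squares via the Gower-centered inner-product matrix: each
#' factor's SS is the drop in explained trace when that factor is removed
#' from the two-main-effects model. Significance from free permutation of
#' raw observations.
#'
#' @param x numeric matrix / data frame, or `dist`.
#' @param f1,f2 the two factors.
#' @param n_permutations,seed as in [permanova()].
#' @return data frame with one row per factor: `term`, `df`, `ss`,
#'   `pseudo_f`, `p_value`.
#' @export
permanova2 <- function(x, f1, f2, n_permutations = 9999, seed = NULL) {
  D2 <- if (inherits(x, "dist")) as.matrix(x)^2 else sq_dist(as_num_matrix(x))
  N <- nrow(D2)
  f1 <- factor(f1); f2 <- factor(f2)
  J <- diag(N) - matrix(1 / N, N, N)
  G <- -0.5 * J %*% D2 %*% J
  hat <- function(X) X %*% solve(crossprod(X), t(X))
  mm <- function(...) stats::model.matrix(~ ..., data = data.frame(...))
  X_full <- stats::model.matrix(~ f1 + f2)
  X_no1 <- stats::model.matrix(~ f2)
  X_no2 <- stats::model.matrix(~ f1)
  H_full <- hat(X_full)
  df1 <- nlevels(f1) - 1L; df2 <- nlevels(f2) - 1L
  df_res <- N - ncol(X_full)
  stat <- function(Gm) {
    ss_res <- sum(diag((diag(N) - H_full) %*% Gm))
    ss1 <- sum(diag(H_full %*% Gm)) - sum(diag(hat(X_no1) %*% Gm))
    ss2 <- sum(diag(H_full %*% Gm)) - sum(diag(hat(X_no2) %*% Gm))
    c(f1 = (ss1 / df1) / (ss_res / df_res),
      f2 = (ss2 / df2) / (ss_res / df_res), ss1 = ss1, ss2 = ss2,
      ss_res = ss_res)
  }
  obs <- stat(G)
  exceed <- c(0L, 0L)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      idx <- sample.int(N)
      s <- stat(G[idx, idx])
      exceed <- exceed + (s[1:2] >= obs[1:2] - 1e-12)
    }
  })
  p <- (1 + exceed) / (1 + n_permutations)
  data.frame(term = c("factor1", "factor2"),
             df = c(df1, df2), ss = unname(c(obs["ss1"], obs["ss2"])),
             pseudo_f = unname(c(obs["f1"], obs["f2"])),
             p_value = unname(p))
}

#' Benjamini-Yekutieli p-value adjustment
#'
#' False-discovery-rate control valid under arbitrary dependence among
#' tests: `adj_(i) = min(1, min_{j>=i} m c(m) p_(j) / j)` with
#' `c(m) = sum_{i=1}^m 1/i`. Delegates to `stats::p.adjust(method = "BY")`
#' after validating the inputs.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
benjamini_yekutieli <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("benjamini_yekutieli(): p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Pairwise PERMANOVA with BY adjustment
#'
#' One PERMANOVA per pair of groups; p-values adjusted over all pairs with
#' [benjamini_yekutieli()].
#'
#' @inheritParams permanova
#' @return data frame: `group1`, `group2`, `pseudo_f`, `p_raw`, `p_adj`.
#' @export
pairwise_permanova <- function(x, labels, n_permutations = 9999, seed = NULL) {
  labels <- as.character(labels)
  x <- as_num_matrix(x)
  gs <- sort(unique(labels))
  if (length(gs) < 2) stop("pairwise_permanova(): need >= 2 groups")
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  res <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    keep <- labels %in% pr
    r <- permanova(x[keep, , drop = FALSE], labels[keep],
                   n_permutations = n_permutations,
                   seed = if (is.null(seed)) NULL else seed + i)
    data.frame(group1 = pr[1], group2 = pr[2],
               pseudo_f = r$pseudo_f, p_raw = r$p_value)
  }))
  res$p_adj <- benjamini_yekutieli(res$p_raw)
  res
}

#' SIMPER: per-variable contributions to between-group dissimilarity
#'
#' Decomposes the average between-group dissimilarity of one group pair into
#' additive per-variable contributions. The default dissimilarity is the
#' squared Euclidean distance, whose per-variable term for an observation
#' pair is `(x_iv - x_jv)^2`, consistent with Euclidean-distance PERMANOVA;
#' `method = "bray"` gives the classical Bray-Curtis decomposition with term
#' `|x_iv - x_jv| / sum_v (x_iv + x_jv)`.
#'
#' @param x numeric matrix / data frame (observations x variables).
#' @param labels group labels.
#' @param pair length-2 character vector naming the two groups to contrast.
#' @param method `"euclidean_sq"` (default) or `"bray"`.
#' @param cutoff cumulative-contribution cutoff defining the reported
#'   minimal variable set (default 0.70).
#' @return object of class `simper_result`: `table` (variables in descending
#'   contribution order with `contribution`, `pct`, `cum_pct`), `overall`
#'   (average between-group dissimilarity), `top_set` (minimal descending
#'   set reaching `cutoff`), `method`.
#' @export
simper <- function(x, labels, pair, method = c("euclidean_sq", "bray"),
                   cutoff = 0.70) {
  method <- match.arg(method)
  x <- as_num_matrix(x)
  labels <- as.character(labels)
  if (!all(pair %in% labels)) stop("simper(): unknown group in pair")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  A <- x[labels == pair[1], , drop = FALSE]
  B <- x[labels == pair[2], , drop = FALSE]
  V <- ncol(x)
  if (V < 1) stop("simper(): need >= 1 variable")
  contrib <- numeric(V)
  npair <- nrow(A) * nrow(B)
  for (i in seq_len(nrow(A))) {
    diffs <- abs(sweep(B, 2, A[i, ]))           # nB x V
    if (method == "euclidean_sq") {
      contrib <- contrib + colSums(diffs^2)
    } else {
      denom <- rowSums(sweep(B, 2, A[i, ], "+"))
      contrib <- contrib + colSums(diffs / denom)
    }
  }
  contrib <- contrib / npair
  overall <- sum(contrib)
  ord <- order(contrib, decreasing = TRUE)
  tab <- data.frame(variable = colnames(x)[ord],
                    contribution = contrib[ord],
                    pct = contrib[ord] / overall * 100)
  tab$cum_pct <- cumsum(tab$pct)
  top <- tab$variable[seq_len(which(tab$cum_pct >= cutoff * 100)[1])]
  structure(list(table = tab, overall = overall, top_set = top,
                 method = method, pair = pair, cutoff = cutoff),
            class = "simper_result")
}

#' Merge prey species into functional groups
#'
#' Two species are mergeable when their BY-adjusted pairwise PERMANOVA
#' p-value exceeds `alpha` (isotopically indistinguishable) and their
#' ecology is declared compatible. Functional groups are the single-linkage
#' connected components of the mergeable relation; when transitivity forces
#' together a pair that was itself distinguishable, a note is logged in the
#' result.
#'
#' @param pairwise data frame from [pairwise_permanova()] (needs `group1`,
#'   `group2`, `p_adj`).
#' @param ecology optional two-column data frame of ecologically compatible
#'   pairs; `NULL` means every pair is compatible.
#' @param alpha significance level below which species stay separate
#'   (default 0.05).
#' @return named character vector mapping each species to its functional
#'   group label (member names joined by "/"); attribute `notes` lists
#'   transitivity conflicts.
#' @export
merge_sources <- function(pairwise, ecology = NULL, alpha = 0.05) {
  sp <- sort(unique(c(pairwise$group1, pairwise$group2)))
  eco_ok <- function(a, b) {
    if (is.null(ecology)) return(TRUE)
    any((ecology[[1]] == a & ecology[[2]] == b) |
        (ecology[[1]] == b & ecology[[2]] == a))
  }
  parent <- stats::setNames(sp, sp)
  find <- function(a) { while (parent[[a]] != a) a <- parent[[a]]; a }
  mergeable <- matrix(FALSE, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$group1[i]; b <- pairwise$group2[i]
    m <- pairwise$p_adj[i] > alpha && eco_ok(a, b)
    mergeable[a, b] <- mergeable[b, a] <- m
    if (m) parent[[find(a)]] <- find(b)
  }
  root <- vapply(sp, find, "")
  notes <- character()
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$group1[i]; b <- pairwise$group2[i]
    if (root[a] == root[b] && !mergeable[a, b])
      notes <- c(notes, paste0("transitive merge joined distinguishable pair ",
                               a, " / ", b))
  }
  if (length(notes)) message("merge_sources(): ",
                             paste(notes, collapse = "; "))
  lab <- vapply(sp, function(s)
    paste(sort(sp[root == root[s]]), collapse = "/"), "")
  attr(lab, "notes") <- notes
  lab
}

#' Pearson-correlation screen for variable loadings
#'
#' Reporting helper: correlates each variable with each column of a set of
#' ordination scores and returns the variables whose absolute correlation
#' exceeds the threshold on any axis.
#'
#' @param x data matrix (observations x variables).
#' @param scores matrix of ordination coordinates (observations x axes).
#' @param r threshold on |Pearson r| (default 0.6).
#' @return data frame of variable, axis, correlation for screened variables.
#' @export
correlation_screen <- function(x, scores, r = 0.6) {
  x <- as_num_matrix(x); scores <- as_num_matrix(scores)
  cc <- stats::cor(x, scores)
  idx <- which(abs(cc) > r, arr.ind = TRUE)
  out <- data.frame(variable = colnames(x)[idx[, 1]],
                    axis = colnames(scores)[idx[, 2]],
                    r = cc[idx])
  out[order(-abs(out$r)), , drop = FALSE]
}
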