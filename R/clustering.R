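# Hierarchical clustering of consumer tracer signatures, Dunn-index model
# selection and discriminant validation.

#' Hierarchical clustering of observations
#'
#' Agglomerative clustering on Euclidean distances (stats::hclust). The
#' default linkage is Ward's minimum-variance criterion on squared
#' distances (`"ward.D2"`); features are optionally z-standardized first,
#' the default for tracer spaces where d13C and d15N have different spreads.
#'
#' @param x numeric matrix / data frame, observations in rows (n >= 3).
#' @param linkage linkage passed to `stats::hclust`.
#' @param standardize z-standardize columns first (constant columns are
#'   left at zero).
#' @return an `hclust` tree, with the (possibly standardized) data kept in
#'   attribute `data`.
#' @export
hierarchical_cluster <- function(x, linkage = "ward.D2", standardize = TRUE) {
  x <- as_num_matrix(x)
  if (nrow(x) < 3) stop("hierarchical_cluster(): need >= 3 observations")
  if (standardize) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    x <- scale(x, center = TRUE, scale = s)
  }
  hc <- stats::hclust(stats::dist(x), method = linkage)
  attr(hc, "data") <- x
  hc
}

#' Dunn index of a partition
#'
#' Ratio of the minimum between-cluster point-to-point distance to the
#' maximum within-cluster diameter. Singleton clusters have diameter 0; a
#' partition whose clusters are all singletons has an undefined (infinite)
#' index.
#'
#' @param x data matrix or `dist`.
#' @param labels cluster labels.
#' @return Dunn index (>= 0, possibly `Inf`).
#' @export
dunn_index <- function(x, labels) {
  D <- if (inherits(x, "dist")) as.matrix(x) else
    as.matrix(stats::dist(as_num_matrix(x)))
  labels <- as.character(labels)
  gs <- unique(labels)
  diam <- 0; sep <- Inf
  for (i in seq_along(gs)) {
    ii <- which(labels == gs[i])
    if (length(ii) > 1) diam <- max(diam, max(D[ii, ii]))
    for (j in seq_along(gs)) if (j > i) {
      jj <- which(labels == gs[j])
      sep <- min(sep, min(D[ii, jj]))
    }
  }
  if (diam == 0) return(Inf)
  sep / diam
}

#' Select the number of clusters by the Dunn index
#'
#' Cuts a dendrogram at each candidate `k`, computes the Dunn index of each
#' partition on the clustering feature space, and returns the partition
#' maximizing it (ties broken toward the smallest `k`). All-singleton
#' partitions (infinite index) are excluded. A best index below 1 — maximum
#' cluster diameter exceeding minimum separation — signals weak structure
#' and raises a warning.
#'
#' @param hc tree from [hierarchical_cluster()] (or any `hclust` plus `x`).
#' @param k_range integer candidates within `[2, n - 1]`.
#' @param x data used for distances; defaults to the data stored in `hc`.
#' @return object of class `cluster_solution`: `labels`, `k`, `dunn`,
#'   `linkage`, `dunn_by_k`, `validation_accuracy` (NA until
#'   [lda_validate()] is run).
#' @export
select_k_dunn <- function(hc, k_range = 2:6, x = attr(hc, "data")) {
  n <- length(hc$order)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("select_k_dunn(): empty k_range")
  if (is.null(x)) stop("select_k_dunn(): no data to compute distances from")
  D <- stats::dist(as_num_matrix(x))
  dunn <- vapply(k_range, function(k)
    dunn_index(D, stats::cutree(hc, k)), 0)
  names(dunn) <- k_range
  finite <- is.finite(dunn)
  if (!any(finite)) stop("select_k_dunn(): all candidate partitions degenerate")
  best <- k_range[finite][which.max(dunn[finite])]
  if (max(dunn[finite]) < 1)
    warning("select_k_dunn(): best Dunn index < 1; cluster structure is weak")
  structure(list(labels = stats::cutree(hc, best), k = best,
                 dunn = unname(dunn[as.character(best)]),
                 linkage = hc$method, dunn_by_k = dunn,
                 validation_accuracy = NA_real_),
            class = "cluster_solution")
}

#' Leave-one-out discriminant validation of a partition
#'
#' Linear discriminant analysis with leave-one-out cross-validation
#' (MASS::lda, CV = TRUE); the returned accuracy is the fraction of
#' observations whose held-out prediction matches their cluster. When the
#' within-class covariance is singular the pooled covariance is
#' ridge-regularized and classification done directly, with the epsilon
#' reported in a message.
#'
#' @param x feature matrix.
#' @param labels class labels (each class >= 2 members).
#' @return accuracy in [0, 1].
#' @export
lda_validate <- function(x, labels) {
  x <- as_num_matrix(x)
  labels <- factor(labels)
  if (any(table(labels) < 2)) stop("lda_validate(): class with < 2 members")
  fit <- try(MASS::lda(x, grouping = labels, CV = TRUE), silent = TRUE)
  if (!inherits(fit, "try-error") && !anyNA(fit$class))
    return(mean(fit$class == labels))
  eps <- 1e-6 * mean(diag(stats::cov(x)))
  message("lda_validate(): singular covariance; ridge epsilon = ",
          format(eps))
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]; lt <- droplevels(labels[-i])
    mus <- rowsum(xt, lt) / as.vector(table(lt))
    S <- matrix(0, ncol(x), ncol(x))
    for (g in levels(lt)) {
      xg <- sweep(xt[lt == g, , drop = FALSE], 2, mus[g, ])
      S <- S + crossprod(xg)
    }
    S <- S / (nrow(xt) - nlevels(lt)) + eps * diag(ncol(x))
    Si <- solve(S)
    sc <- vapply(levels(lt), function(g)
      drop(x[i, ] %*% Si %*% mus[g, ] - 0.5 * mus[g, ] %*% Si %*% mus[g, ] +
             log(mean(lt == g))), 0)
    pred[i] <- names(which.max(sc))
  }
  mean(pred == as.character(labels))
}
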