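#' Isometric log-ratio (ILR) basis
#'
#' Orthonormal contrast matrix mapping the interior of the K-simplex to
#' (K-1)-dimensional real space. A fixed sequential (Helmert-type) basis is
#' used throughout the package; the basis only reparameterizes the sampler,
#' every reported quantity lives on the simplex.
#'
#' @param K number of composition parts (>= 2).
#' @return K x (K-1) matrix `V` with `t(V) %*% V = I` and columns orthogonal
#'   to the unit vector.
#' @export
ilr_basis <- function(K) {
  if (K < 2) stop("ilr_basis() needs K >= 2")
  H <- stats::contr.helmert(K)      # K x (K-1), columns orthogonal to 1
  V <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  dimnames(V) <- NULL
  V
}

#' ILR transform of a composition
#'
#' @param p positive composition vector (or matrix with compositions in rows);
#'   rescaled internally to sum to one.
#' @param V basis from [ilr_basis()]; computed from the length of `p` when
#'   omitted.
#' @return numeric vector (or matrix) of K-1 ILR coordinates.
#' @export
ilr <- function(p, V = NULL) {
  if (is.matrix(p)) {
    if (is.null(V)) V <- ilr_basis(ncol(p))
    if (any(p <= 0)) stop("ilr() requires strictly positive parts")
    lp <- log(p / rowSums(p))
    return(lp %*% V)
  }
  if (is.null(V)) V <- ilr_basis(length(p))
  if (any(p <= 0)) stop("ilr() requires strictly positive parts")
  drop(crossprod(V, log(p / sum(p))))
}

#' Inverse ILR transform
#'
#' @param theta coordinate vector of length K-1, or a matrix with one
#'   coordinate vector per row.
#' @param V basis from [ilr_basis()].
#' @return composition on the simplex (rows sum to 1).
#' @export
ilr_inv <- function(theta, V = NULL) {
  if (is.matrix(theta)) {
    if (is.null(V)) V <- ilr_basis(ncol(theta) + 1L)
    z <- theta %*% t(V)
    z <- z - apply(z, 1, max)       # overflow guard
    e <- exp(z)
    return(e / rowSums(e))
  }
  if (is.null(V)) V <- ilr_basis(length(theta) + 1L)
  z <- drop(V %*% theta)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Check that a vector lies on the probability simplex
#'
#' @param p numeric vector.
#' @param tol absolute tolerance on the sum and on negativity.
#' @return logical scalar.
#' @export
is_simplex <- function(p, tol = 1e-9) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol) &&
    abs(sum(p) - 1) <= tol
}
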