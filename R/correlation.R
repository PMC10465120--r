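#' Pairwise edge-correlation matrix of a forward-propagation chain
#'
#' In a forward-propagation (sequential) chain of `m` graphs, consecutive
#' graphs carry step correlations `rho_steps[k]` and the correlation between
#' graphs `k1 < k2` is the product of the intervening step correlations.
#'
#' @param rho_steps vector of length `m - 1` of step correlations in \[0, 1\].
#' @return An `m x m` matrix of class `correlation_matrix` with unit
#'   diagonal.
#' @examples
#' forward_correlation(c(0.8, 0.8))[1, 3] # 0.64
#' @export
forward_correlation <- function(rho_steps) {
  rho_steps <- as.numeric(rho_steps)
  if (length(rho_steps) < 1) stop("`rho_steps` must be nonempty")
  if (any(rho_steps < 0) || any(rho_steps > 1)) {
    stop("step correlations must lie in [0, 1]")
  }
  m <- length(rho_steps) + 1L
  R <- diag(m)
  for (k1 in seq_len(m - 1)) {
    for (k2 in seq(k1 + 1, m)) {
      R[k1, k2] <- R[k2, k1] <- prod(rho_steps[k1:(k2 - 1)])
    }
  }
  new_correlation_matrix(R)
}

#' Pairwise edge-correlation matrix of a single-generator family
#'
#' In the single-generator model each graph is an independently perturbed
#' copy of one generator graph, with fidelity `nu[k]`; the correlation
#' between two distinct graphs is `nu[k1] * nu[k2]`, so
#' `R = nu nu' + diag(I - nu nu')`.
#'
#' @param nu vector of length `m` of generator fidelities in \[0, 1\].
#' @return An `m x m` matrix of class `correlation_matrix`.
#' @examples
#' generator_correlation(c(0.8, 0.8))[1, 2] # 0.64
#' @export
generator_correlation <- function(nu) {
  nu <- as.numeric(nu)
  if (length(nu) < 1) stop("`nu` must be nonempty")
  if (any(nu < 0) || any(nu > 1)) stop("entries of `nu` must lie in [0, 1]")
  R <- tcrossprod(nu)
  diag(R) <- 1
  new_correlation_matrix(R)
}

new_correlation_matrix <- function(R) {
  R <- as.matrix(R)
  if (!isSymmetric(R, tol = 1e-10)) stop("correlation matrix must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-12)) stop("diagonal entries must equal 1")
  off <- R[upper.tri(R)]
  if (any(off < 0) || any(off > 1)) {
    stop("off-diagonal correlations must lie in [0, 1]")
  }
  structure(R, class = c("correlation_matrix", "matrix", "array"))
}

#' Validate an edge-correlation matrix
#'
#' Checks symmetry, a unit diagonal, nonnegative off-diagonal entries
#' (negative correlation is not supported by the constructive samplers)
#' and positive semidefiniteness.
#'
#' @param R matrix to validate.
#' @return `R` with class `correlation_matrix`, invisibly erroring on any
#'   violated condition.
#' @export
as_correlation_matrix <- function(R) {
  R <- new_correlation_matrix(R)
  ev <- eigen(unclass(R), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("correlation matrix must be positive semidefinite")
  }
  R
}
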