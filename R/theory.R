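#' Second moment matrix of a latent mixture
#'
#' `Delta = E[X1 X1']`, evaluated exactly as the weighted sum of atom outer
#' products. All limit-theory results require `Delta` to have full rank
#' `d`; a rank-deficient mixture is rejected.
#'
#' @param F a [latent_mixture()].
#' @return A `d x d` symmetric positive definite matrix with attribute
#'   `"condition_number"`.
#' @export
second_moment <- function(F) {
  stopifnot(inherits(F, "latent_mixture"))
  Delta <- matrix(0, F$d, F$d)
  for (k in seq_len(F$K)) {
    Delta <- Delta + F$weights[k] * tcrossprod(F$atoms[k, ])
  }
  ev <- eigen(Delta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10) {
    stop("second-moment matrix is rank deficient (rank < d)")
  }
  attr(Delta, "condition_number") <- max(ev) / min(ev)
  Delta
}

#' Limiting per-row covariance kernel of the adjacency spectral embedding
#'
#' The scaled residual of an estimated latent position at latent point `x`
#' is asymptotically Gaussian with covariance
#' `Sigma(x) = Delta^-1 E[(x'X1 - (x'X1)^2) X1 X1'] Delta^-1`,
#' the Bernoulli edge variance `p(1 - p)` propagated through the
#' eigenspace. The expectation over the finite mixture is an exact sum
#' over atoms.
#'
#' @param F a [latent_mixture()].
#' @param x latent point (length-`d` vector); `x' xi_k` must lie in
#'   \[0, 1\] for each atom.
#' @return A symmetric positive semidefinite `d x d` matrix.
#' @export
sigma_x <- function(F, x) {
  stopifnot(inherits(F, "latent_mixture"))
  x <- as.numeric(x)
  if (length(x) != F$d) stop("`x` must have length d = ", F$d)
  p <- drop(F$atoms %*% x)
  if (any(p < -1e-10) || any(p > 1 + 1e-10)) {
    stop("inner products x' xi_k must lie in [0, 1]")
  }
  Delta <- second_moment(F)
  E <- matrix(0, F$d, F$d)
  for (k in seq_len(F$K)) {
    E <- E + F$weights[k] * (p[k] - p[k]^2) * tcrossprod(F$atoms[k, ])
  }
  Dinv <- solve(Delta)
  Dinv %*% E %*% Dinv
}

# Coerce a design specification to its m x m weight profile.
resolve_alpha <- function(alpha) {
  if (inherits(alpha, "omni_coef")) return(unclass(weight_profile(alpha)))
  if (inherits(alpha, "weight_profile")) return(unclass(alpha))
  if (is.matrix(alpha)) return(alpha)
  stop("expected an omni_coef, weight_profile, or m x m matrix")
}

resolve_R <- function(R, m) {
  if (is.null(R)) return(diag(m))
  R <- unclass(as.matrix(R))
  if (!all(dim(R) == m)) stop("`R` must be ", m, " x ", m)
  R
}

#' Limiting covariance of one block of the omnibus embedding
#'
#' Scaled residuals of the `s`-th block's rows are asymptotically Gaussian
#' with covariance `(method + model) * Sigma(x)`, where the method-induced
#' coefficient is `sum_q alpha(s, q)^2 / m^2` and the model-inherent
#' coefficient is `2 sum_{q<l} alpha(s, q) alpha(s, l) rho_{q,l} / m^2`.
#'
#' @param alpha weight design: an `omni_coef`, [weight_profile()] or
#'   `m x m` matrix.
#' @param R `m x m` edge-correlation matrix (identity if `NULL`).
#' @param s block index in `1..m`.
#' @param F a [latent_mixture()].
#' @param x latent point.
#' @return List with `Sigma` (`d x d` matrix), and the scalar
#'   `method_coefficient` and `model_coefficient`.
#' @export
block_covariance <- function(alpha, R = NULL, s, F, x) {
  a <- resolve_alpha(alpha)
  m <- nrow(a)
  R <- resolve_R(R, m)
  if (s < 1 || s > m) stop("`s` out of range")
  as <- a[s, ]
  method <- sum(as^2) / m^2
  cross <- (sum((as %o% as) * R) - sum(as^2)) / 2  # sum_{q<l} a_q a_l rho_ql
  model <- 2 * cross / m^2
  Sig <- sigma_x(F, x)
  list(Sigma = (method + model) * Sig,
       method_coefficient = method, model_coefficient = model)
}

#' Limiting covariance of the difference of two omnibus blocks
#'
#' For blocks `s1`, `s2`, the scaled difference of the two estimates of
#' the same latent position is asymptotically Gaussian with covariance
#' `[sum_q d_q^2 + 2 sum_{q<l} d_q d_l rho_{q,l}] / m^2 * Sigma(x)`, where
#' `d_q = alpha(s1, q) - alpha(s2, q)`. The equivalent product form
#' `2 sum_{q<l} d_q d_l (rho_{q,l} - 1) / m^2` (equivalent exactly when
#' the rows of `alpha` sum to `m`) is returned alongside as
#' `coefficient_product_form`. The scalar coefficient equals
#' `2 (1 - rho(s1, s2))` with `rho(s1, s2)` from
#' [limiting_correlation()].
#'
#' @inheritParams block_covariance
#' @param s1,s2 block indices.
#' @return List with `Sigma`, `method_coefficient`, `model_coefficient`,
#'   the total scalar `coefficient`, and `coefficient_product_form`.
#' @export
difference_covariance <- function(alpha, R = NULL, s1, s2, F, x) {
  a <- resolve_alpha(alpha)
  m <- nrow(a)
  R <- resolve_R(R, m)
  if (s1 < 1 || s1 > m || s2 < 1 || s2 > m) stop("block index out of range")
  dq <- a[s1, ] - a[s2, ]
  method <- sum(dq^2) / m^2
  cross <- (sum((dq %o% dq) * R) - sum(dq^2)) / 2
  model <- 2 * cross / m^2
  # product form 2 sum_{q<l} d_q d_l (rho_{q,l} - 1) / m^2; the diagonal of
  # (R - 1) vanishes, so the full quadratic form halves to the q<l sum.
  # It agrees with the sum form exactly when the rows of alpha sum to m.
  alt <- sum((dq %o% dq) * (R - 1)) / m^2
  list(Sigma = (method + model) * sigma_x(F, x),
       method_coefficient = method, model_coefficient = model,
       coefficient = method + model, coefficient_product_form = alt)
}

#' Limiting correlation between two blocks of the omnibus embedding
#'
#' The correlation, in the limit, between the two estimates of the same
#' latent position carried by blocks `s1` and `s2`:
#' `rho(s1, s2) = 1 - sum_q d_q^2 / (2 m^2)
#'                 - sum_{q<l} d_q d_l rho_{q,l} / m^2`,
#' with `d_q = alpha(s1, q) - alpha(s2, q)`. The first correction is the
#' method-induced part (what the joint embedding itself creates, even for
#' independent graphs) and the second the model-inherent part (what the
#' generating edge correlation contributes).
#'
#' @inheritParams difference_covariance
#' @return List with `correlation`, `method` (the induced part,
#'   `1 - sum d_q^2 / (2 m^2)`) and `model` (the inherent part).
#' @examples
#' a <- weight_profile(classical_coefficients(4))
#' limiting_correlation(a, NULL, 1, 2)$correlation # 3/4
#' @export
limiting_correlation <- function(alpha, R = NULL, s1, s2) {
  a <- resolve_alpha(alpha)
  m <- nrow(a)
  R <- resolve_R(R, m)
  if (s1 < 1 || s1 > m || s2 < 1 || s2 > m) stop("block index out of range")
  dq <- a[s1, ] - a[s2, ]
  method <- 1 - sum(dq^2) / (2 * m^2)
  cross <- (sum((dq %o% dq) * R) - sum(dq^2)) / 2
  model <- -cross / m^2 + 0  # + 0 normalizes a possible negative zero
  list(correlation = method + model, method = method, model = model)
}

#' Closed-form limiting correlations for the named designs
#'
#' Direct transcriptions of the printed closed forms, used as independent
#' oracles for [limiting_correlation()] applied to the coefficient
#' builders:
#' * `"classical"`: `3/4 + rho/4`;
#' * `"total_average"`: `1 - 1/m^2 + rho/m^2`;
#' * `"weighted_equal_pair"` (`w_{s1} = w_{s2} = w`, all other weights 1):
#'   `1 - ((m - 1) w + 1)^2 / (m^2 (1 + w)^2) * (1 - rho)`;
#' * `"pair_preserving"` (pair (1, 2)):
#'   `1 - (1 - rho) (m - 1)^2 / m^2`.
#'
#' @param design one of `"classical"`, `"total_average"`,
#'   `"weighted_equal_pair"`, `"pair_preserving"`.
#' @param m number of graphs.
#' @param rho inherent edge correlation of the pair under consideration.
#' @param w common weight of the pair (weighted equal-pair design only).
#' @return Scalar limiting correlation.
#' @export
closed_form_correlation <- function(design, m, rho = 0, w = 1) {
  stopifnot(m >= 2, rho >= 0, rho <= 1)
  switch(design,
    classical = 3 / 4 + rho / 4,
    total_average = 1 - 1 / m^2 + rho / m^2,
    weighted_equal_pair =
      1 - ((m - 1) * w + 1)^2 / (m^2 * (1 + w)^2) * (1 - rho),
    pair_preserving = 1 - (1 - rho) * (m - 1)^2 / m^2,
    stop("unknown design family: ", design)
  )
}

#' Effective sample size of correlated graphs
#'
#' For `m` graphs with pairwise edge correlation `rho`, averaging their
#' latent-position estimates is as informative as
#' `m / (1 + rho (m - 1))` independent graphs.
#'
#' @param m number of graphs (`>= 1`).
#' @param rho common pairwise edge correlation in \[0, 1\].
#' @return Scalar in \[1, m\], decreasing in `rho`.
#' @export
effective_sample_size <- function(m, rho) {
  if (m < 1 || m != round(m)) stop("`m` must be a positive integer")
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1]")
  m / (1 + rho * (m - 1))
}

#' Limiting covariance of the averaged latent-position estimator
#'
#' Averaging the `m` aligned per-graph estimates (separately embedded and
#' Procrustes-aligned, or the `m` omnibus blocks) of a latent position:
#' each estimate has marginal limiting covariance `Sigma(x)` and
#' cross-graph covariance `rho * Sigma(x)`, so the scaled residual of the
#' average is Gaussian with covariance
#' `((1 - rho)/m + rho) * Sigma(x)` — the classical correlated sample
#' mean, equivalently `Sigma(x)` divided by the effective sample size
#' `m / (1 + rho (m - 1))`. At `rho = 0` the factor is `1/m`; at
#' `rho = 1` the graphs are identical and the average is no better than
#' one graph. `m = 1` is rejected: a single graph needs no averaging and
#' is covered by the plain per-graph law.
#'
#' @param m number of graphs (`>= 2`).
#' @param rho common pairwise edge correlation in \[0, 1\].
#' @param F a [latent_mixture()].
#' @param x latent point.
#' @return List with `Sigma` (`d x d` matrix) and the variance factor
#'   `rho_prime = (1 - rho)/m + rho` (the reciprocal effective sample
#'   size).
#' @export
averaged_estimator_covariance <- function(m, rho, F, x) {
  if (m < 2 || m != round(m)) stop("`m` must be an integer >= 2")
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1]")
  rho_prime <- (1 - rho) / m + rho
  list(Sigma = rho_prime * sigma_x(F, x), rho_prime = rho_prime)
}
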