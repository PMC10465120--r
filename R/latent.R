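#' Finite latent-position mixture for random dot product graphs
#'
#' A random dot product graph (RDPG) places each vertex at an unobserved
#' latent position in `d` dimensions; the probability of an edge between two
#' vertices is the inner product of their positions. A finite mixture of
#' point masses yields a (positive semidefinite) stochastic blockmodel: the
#' atoms are the block representatives and the mixture weights the block
#' membership probabilities.
#'
#' @param atoms numeric matrix, one atom per row (`K` rows, `d` columns).
#' @param weights probability vector of length `K`; defaults to uniform.
#'
#' @return An object of class `latent_mixture` with elements `atoms`,
#'   `weights`, `d` and `K`.
#'
#' @details All pairwise inner products between atoms must lie in \[0, 1\],
#'   so that every realizable edge probability is a probability.
#'
#' @examples
#' F5 <- sbm_mixture(matrix(c(0.7, 0.3, 0.3, 0.5), 2))
#' F5$atoms %*% t(F5$atoms)
#' @export
latent_mixture <- function(atoms, weights = NULL) {
  atoms <- rbind(atoms)
  storage.mode(atoms) <- "double"
  K <- nrow(atoms)
  if (is.null(weights)) weights <- rep(1 / K, K)
  weights <- as.numeric(weights)
  if (length(weights) != K) {
    stop("`weights` must have one entry per atom (row of `atoms`)")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("`weights` must be nonnegative and sum to 1")
  }
  G <- atoms %*% t(atoms)
  if (any(G < -1e-12) || any(G > 1 + 1e-12)) {
    stop("pairwise inner products of atoms must lie in [0, 1]")
  }
  structure(
    list(atoms = atoms, weights = weights, d = ncol(atoms), K = K),
    class = "latent_mixture"
  )
}

#' Latent mixture from a stochastic-blockmodel Gram matrix
#'
#' Factorizes a positive semidefinite block connection-probability matrix
#' `B` as `B = V Lambda V'` and takes the atoms to be the rows of
#' `V Lambda^(1/2)`. Any factorization is equivalent up to an orthogonal
#' rotation, which the RDPG cannot identify anyway.
#'
#' @param B symmetric `K x K` Gram matrix of block connection probabilities,
#'   positive semidefinite with entries in \[0, 1\].
#' @param weights block membership probabilities; defaults to uniform.
#' @return A [latent_mixture()].
#' @export
sbm_mixture <- function(B, weights = NULL) {
  B <- as.matrix(B)
  if (!isSymmetric(B, tol = 1e-10)) stop("`B` must be symmetric")
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (any(e$values < -1e-10)) stop("`B` must be positive semidefinite")
  lam <- pmax(e$values, 0)
  keep <- lam > max(lam) * 1e-12
  atoms <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam[keep]), sum(keep))
  latent_mixture(atoms, weights)
}

#' @export
print.latent_mixture <- function(x, ...) {
  cat("Latent point-mass mixture:", x$K, "atoms in", x$d, "dimensions\n")
  cat("weights:", format(x$weights, digits = 4), "\n")
  print(round(x$atoms %*% t(x$atoms), 6))
  invisible(x)
}

#' Sample i.i.d. latent positions
#'
#' Draws `n` latent positions independently from a finite mixture. With
#' `balanced = TRUE` the component memberships are assigned
#' deterministically instead (the first `ceiling(n * w1)` vertices to atom
#' 1, and so on), which pins a tracked vertex to a known atom in
#' simulation studies.
#'
#' @param F a [latent_mixture()].
#' @param n number of vertices.
#' @param seed optional integer seed for reproducibility.
#' @param balanced logical; deterministic proportional block assignment.
#' @return An object of class `latent_positions`: list with `X` (`n x d`
#'   matrix), `labels` (component index per vertex) and the generating
#'   mixture `F`. The edge-probability matrix is available via
#'   [gram_matrix()].
#' @export
sample_latent <- function(F, n, seed = NULL, balanced = FALSE) {
  stopifnot(inherits(F, "latent_mixture"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (balanced) {
    counts <- diff(round(cumsum(c(0, F$weights)) * n))
    labels <- rep(seq_len(F$K), counts)
    labels <- c(labels, rep(F$K, n - length(labels)))[seq_len(n)]
  } else {
    labels <- sample.int(F$K, n, replace = TRUE, prob = F$weights)
  }
  X <- F$atoms[labels, , drop = FALSE]
  latent_positions(X, labels = labels, F = F)
}

#' Latent position matrix
#'
#' Wraps an `n x d` matrix of latent positions; validates that the implied
#' edge probabilities `X X'` lie in \[0, 1\].
#'
#' @param X numeric `n x d` matrix of latent positions (rows are vertices).
#' @param labels optional component labels (for blockmodel samples).
#' @param F optional generating [latent_mixture()].
#' @return An object of class `latent_positions`.
#' @export
latent_positions <- function(X, labels = NULL, F = NULL) {
  X <- rbind(X)
  storage.mode(X) <- "double"
  P <- X %*% t(X)
  if (any(P < -1e-10) || any(P > 1 + 1e-10)) {
    stop("entries of X X' must lie in [0, 1]")
  }
  structure(
    list(X = X, labels = labels, F = F, n = nrow(X), d = ncol(X)),
    class = "latent_positions"
  )
}

#' Edge-probability (Gram) matrix of latent positions
#' @param X a `latent_positions` object.
#' @return The `n x n` matrix `X X'` with entries clipped to \[0, 1\].
#' @export
gram_matrix <- function(X) {
  stopifnot(inherits(X, "latent_positions"))
  P <- X$X %*% t(X$X)
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' @export
print.latent_positions <- function(x, ...) {
  cat("Latent positions:", x$n, "vertices in", x$d, "dimensions\n")
  invisible(x)
}
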