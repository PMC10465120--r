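#' @importFrom stats rbinom
NULL

# Draw one symmetric hollow binary adjacency with upper-triangle success
# probabilities `p_upper` (vector in column-major upper-triangle order).
draw_adjacency <- function(n, p_upper) {
  if (any(p_upper < 0) || any(p_upper > 1)) {
    stop("edge probabilities must lie in [0, 1]")
  }
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(length(p_upper), 1L, p_upper)
  A + t(A)
}

# Independent per-graph seed streams from one root seed: draw the graph
# seeds up front so the k-th graph's stream does not depend on how many
# edges earlier graphs consumed.
spawn_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max, k))
}

new_graph_collection <- function(graphs, X = NULL, model = "iid", R = NULL,
                                 generator = NULL) {
  n <- nrow(graphs[[1]])
  structure(
    list(
      graphs = graphs, n = n, m = length(graphs), X = X,
      model = model, R = R, generator = generator
    ),
    class = "graph_collection"
  )
}

#' Collect adjacency matrices into a graph collection
#'
#' @param graphs list of symmetric, hollow, binary `n x n` matrices on a
#'   common aligned vertex set.
#' @param X optional `latent_positions` used to generate the graphs.
#' @return A `graph_collection` object with elements `graphs`, `n`, `m`.
#' @export
graph_collection <- function(graphs, X = NULL) {
  stopifnot(is.list(graphs), length(graphs) >= 1)
  graphs <- lapply(graphs, function(A) {
    A <- as.matrix(A)
    if (!isSymmetric(A, tol = 0)) stop("adjacency matrices must be symmetric")
    if (any(diag(A) != 0)) stop("adjacency matrices must be hollow")
    if (!all(A %in% c(0, 1))) stop("adjacency matrices must be binary")
    A
  })
  n <- unique(vapply(graphs, nrow, 1L))
  if (length(n) != 1) stop("all graphs must share one vertex set")
  new_graph_collection(graphs, X = X)
}

#' @export
print.graph_collection <- function(x, ...) {
  cat("Graph collection:", x$m, "graphs on", x$n, "vertices (model:",
      x$model, ")\n")
  invisible(x)
}

#' Sample a single random dot product graph
#'
#' Conditional on the latent positions, each upper-triangle entry of the
#' adjacency matrix is an independent Bernoulli draw with success
#' probability equal to the inner product of the endpoint positions.
#'
#' @param X a [latent_positions()] object.
#' @param seed optional integer seed.
#' @return A `graph_collection` with `m = 1`.
#' @export
sample_rdpg <- function(X, seed = NULL) {
  stopifnot(inherits(X, "latent_positions"))
  if (!is.null(seed)) set.seed(seed)
  P <- gram_matrix(X)
  A <- draw_adjacency(X$n, P[upper.tri(P)])
  new_graph_collection(list(A), X = X, model = "iid")
}

# One conditional re-sampling pass: given parent adjacency entries (0/1 on
# the upper triangle) and edge probabilities, draw the child so that the
# child is marginally Bernoulli(P) and corr(child, parent) = rho.
flip_resample <- function(parent_upper, p_upper, rho) {
  p1 <- p_upper + rho * (1 - p_upper)   # parent edge present
  p0 <- p_upper * (1 - rho)             # parent edge absent
  prob <- ifelse(parent_upper == 1, p1, p0)
  rbinom(length(prob), 1L, prob)
}

#' Sample a forward-propagation (sequential) correlated chain
#'
#' The first graph is an RDPG draw; each subsequent graph is re-sampled
#' edge by edge conditional on its predecessor, with step correlation
#' `rho_steps[k]` between graphs `k` and `k + 1`. Each graph is marginally
#' an RDPG, and the correlation between graphs `k1 < k2` is the product of
#' the intervening step correlations (see [forward_correlation()]).
#'
#' @param X a [latent_positions()] object.
#' @param rho_steps step correlations, length `m - 1`, entries in \[0, 1\].
#' @param seed optional integer root seed; per-graph streams are spawned
#'   from it so the chain is reproducible independent of `m`.
#' @return A `graph_collection` with `m = length(rho_steps) + 1`.
#' @export
sample_forward_chain <- function(X, rho_steps, seed = NULL) {
  stopifnot(inherits(X, "latent_positions"))
  rho_steps <- as.numeric(rho_steps)
  R <- forward_correlation(rho_steps)
  m <- length(rho_steps) + 1L
  seeds <- spawn_seeds(seed, m)
  P <- gram_matrix(X)
  p_upper <- P[upper.tri(P)]

  if (!is.null(seeds[[1]])) set.seed(seeds[[1]])
  upper <- rbinom(length(p_upper), 1L, p_upper)
  uppers <- vector("list", m)
  uppers[[1]] <- upper
  for (k in seq_len(m - 1)) {
    if (!is.null(seeds[[k + 1]])) set.seed(seeds[[k + 1]])
    uppers[[k + 1]] <- flip_resample(uppers[[k]], p_upper, rho_steps[k])
  }
  graphs <- lapply(uppers, function(u) {
    A <- matrix(0, X$n, X$n)
    A[upper.tri(A)] <- u
    A + t(A)
  })
  new_graph_collection(graphs, X = X, model = "forward", R = R)
}

#' Sample a single-generator correlated collection
#'
#' Draws one generator RDPG and then, independently for each of the `m`
#' children, re-samples every edge conditional on the generator with
#' fidelity `nu[k]`. Each child is marginally an RDPG and two children
#' carry edge correlation `nu[k1] * nu[k2]` (see
#' [generator_correlation()]).
#'
#' @param X a [latent_positions()] object.
#' @param nu fidelities, length `m`, entries in \[0, 1\].
#' @param seed optional integer root seed.
#' @return A `graph_collection` of the `m` children; the generator
#'   adjacency is attached as the `generator` element.
#' @export
sample_generator_collection <- function(X, nu, seed = NULL) {
  stopifnot(inherits(X, "latent_positions"))
  nu <- as.numeric(nu)
  R <- generator_correlation(nu)
  m <- length(nu)
  seeds <- spawn_seeds(seed, m + 1L)
  P <- gram_matrix(X)
  p_upper <- P[upper.tri(P)]

  if (!is.null(seeds[[1]])) set.seed(seeds[[1]])
  gen_upper <- rbinom(length(p_upper), 1L, p_upper)
  graphs <- vector("list", m)
  for (k in seq_len(m)) {
    if (!is.null(seeds[[k + 1]])) set.seed(seeds[[k + 1]])
    u <- flip_resample(gen_upper, p_upper, nu[k])
    A <- matrix(0, X$n, X$n)
    A[upper.tri(A)] <- u
    graphs[[k]] <- A + t(A)
  }
  G0 <- matrix(0, X$n, X$n)
  G0[upper.tri(G0)] <- gen_upper
  G0 <- G0 + t(G0)
  new_graph_collection(graphs, X = X, model = "generator", R = R,
                       generator = G0)
}

#' Sample a pair of rho-correlated RDPGs
#'
#' Realized with a single conditional re-sampling step: the second graph is
#' drawn edge by edge conditional on the first, so both are marginally
#' RDPGs with per-edge correlation `rho`.
#'
#' @param X a [latent_positions()] object.
#' @param rho scalar edge correlation in \[0, 1\].
#' @param seed optional integer root seed.
#' @return A `graph_collection` with `m = 2`.
#' @export
sample_correlated_pair <- function(X, rho, seed = NULL) {
  if (length(rho) != 1 || rho < 0 || rho > 1) {
    stop("`rho` must be a scalar in [0, 1]")
  }
  out <- sample_forward_chain(X, rho_steps = rho, seed = seed)
  out$model <- "pair"
  out
}

#' Sample a conditionally independent collection
#'
#' @param X a [latent_positions()] object.
#' @param m number of graphs.
#' @param seed optional integer root seed.
#' @return A `graph_collection` of `m` independent RDPG draws sharing `X`.
#' @export
sample_iid_collection <- function(X, m, seed = NULL) {
  stopifnot(inherits(X, "latent_positions"), m >= 1)
  seeds <- spawn_seeds(seed, m)
  P <- gram_matrix(X)
  p_upper <- P[upper.tri(P)]
  graphs <- lapply(seq_len(m), function(k) {
    if (!is.null(seeds[[k]])) set.seed(seeds[[k]])
    draw_adjacency(X$n, p_upper)
  })
  new_graph_collection(graphs, X = X, model = "iid", R = diag(m))
}
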