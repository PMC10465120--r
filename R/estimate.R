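#' Spectral estimate of an edge-probability matrix
#'
#' Reconstructs `P` from the top-`d` eigenpairs (by magnitude) of the
#' adjacency matrix as `X_hat D_hat X_hat'`, where `D_hat` carries the
#' signs of the retained eigenvalues, then clamps every entry to
#' `[epsilon, 1 - epsilon]` so downstream variance terms `P(1 - P)` stay
#' strictly positive.
#'
#' @param A symmetric adjacency matrix.
#' @param d embedding dimension.
#' @param epsilon trim level in (0, 1/2); default `1e-4`.
#' @return An object of class `edge_prob_estimate`: list with the trimmed
#'   `Phat`, the untrimmed `Ptilde`, `d` and `epsilon`.
#' @export
estimate_edge_probability <- function(A, d, epsilon = 1e-4) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("`epsilon` must lie in (0, 1/2)")
  A <- as.matrix(A)
  e <- eigen(A, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(d)]
  U <- e$vectors[, ord, drop = FALSE]
  Ptilde <- U %*% (e$values[ord] * t(U))
  Phat <- pmin(pmax(Ptilde, epsilon), 1 - epsilon)
  structure(list(Phat = Phat, Ptilde = Ptilde, d = d, epsilon = epsilon),
            class = "edge_prob_estimate")
}

#' @export
print.edge_prob_estimate <- function(x, ...) {
  cat("Edge-probability estimate: n =", nrow(x$Phat), ", d =", x$d,
      ", trim =", x$epsilon, "\n")
  invisible(x)
}

as_phat <- function(P) {
  if (inherits(P, "edge_prob_estimate")) P$Phat else as.matrix(P)
}

#' Plug-in edge-correlation estimator
#'
#' Estimates the common per-edge correlation between two graphs on the
#' same vertex set under the heterogeneous correlated Bernoulli model:
#' `rho_hat = (2 / (n (n - 1))) *
#'   sum_{i<j} (A1_ij - P1_ij)(A2_ij - P2_ij) /
#'             sqrt(P1_ij (1 - P1_ij) P2_ij (1 - P2_ij))`.
#'
#' @param A1,A2 symmetric adjacency matrices.
#' @param P1,P2 edge-probability matrices (true, or
#'   [estimate_edge_probability()] results); entries must lie strictly in
#'   (0, 1).
#' @return Scalar correlation estimate.
#' @export
plugin_edge_correlation <- function(A1, A2, P1, P2 = P1) {
  A1 <- as.matrix(A1); A2 <- as.matrix(A2)
  P1 <- as_phat(P1); P2 <- as_phat(P2)
  n <- nrow(A1)
  if (!all(dim(A2) == n, dim(P1) == n, dim(P2) == n)) stop("shape mismatch")
  ut <- upper.tri(A1)
  p1 <- P1[ut]; p2 <- P2[ut]
  if (any(p1 <= 0) || any(p1 >= 1) || any(p2 <= 0) || any(p2 >= 1)) {
    stop("edge probabilities must lie strictly in (0, 1); trim first")
  }
  z <- (A1[ut] - p1) * (A2[ut] - p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  2 * sum(z) / (n * (n - 1))
}

#' Pearson correlation between two graphs
#'
#' The sample Pearson correlation of the upper-triangle adjacency entries,
#' which estimates the edge correlation under the homogeneous correlated
#' Erdos-Renyi model.
#'
#' @param A1,A2 symmetric adjacency matrices on the same vertex set.
#' @return Scalar in \[-1, 1\]; errors if either graph has constant
#'   off-diagonal entries (undefined correlation).
#' @export
pearson_graph_correlation <- function(A1, A2) {
  A1 <- as.matrix(A1); A2 <- as.matrix(A2)
  if (!all(dim(A1) == dim(A2))) stop("shape mismatch")
  ut <- upper.tri(A1)
  a1 <- A1[ut]; a2 <- A2[ut]
  if (stats::sd(a1) == 0 || stats::sd(a2) == 0) {
    stop("Pearson correlation is undefined for a constant adjacency")
  }
  stats::cor(a1, a2)
}

#' Pairwise correlation matrix of a graph collection
#'
#' Applies [plugin_edge_correlation()] (with spectrally estimated,
#' trimmed edge probabilities, or supplied ones) or
#' [pearson_graph_correlation()] to every pair of graphs.
#'
#' @param G a `graph_collection` or list of adjacency matrices.
#' @param method `"plugin"` or `"pearson"`.
#' @param d embedding dimension for the plug-in probability estimates.
#' @param epsilon trim level for the plug-in estimates.
#' @param P optional list of edge-probability matrices (one per graph, or
#'   a single shared matrix) overriding spectral estimation.
#' @return An `m x m` symmetric matrix of estimated correlations with
#'   unit diagonal.
#' @export
estimate_correlation_matrix <- function(G, method = c("plugin", "pearson"),
                                        d = 2, epsilon = 1e-4, P = NULL) {
  method <- match.arg(method)
  graphs <- if (inherits(G, "graph_collection")) G$graphs else G
  m <- length(graphs)
  if (method == "plugin") {
    if (is.null(P)) {
      P <- lapply(graphs, estimate_edge_probability, d = d,
                  epsilon = epsilon)
    } else if (!is.list(P)) {
      P <- rep(list(P), m)
    }
    P <- lapply(P, as_phat)
  }
  R <- diag(m)
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    R[i, j] <- R[j, i] <- if (method == "plugin") {
      plugin_edge_correlation(graphs[[i]], graphs[[j]], P[[i]], P[[j]])
    } else {
      pearson_graph_correlation(graphs[[i]], graphs[[j]])
    }
  }
  R
}

#' Monte-Carlo correlation of embedded latent-position estimates
#'
#' Measures, by simulation, the correlation that a joint embedding
#' produces between the estimates of the same latent position in two
#' blocks. In each replicate a fresh graph collection is sampled, embedded
#' with the given design, each block is Procrustes-aligned to the true
#' latent positions, and the residual of a tracked vertex is recorded.
#'
#' The correlation "level" is summarized the way the limit theory defines
#' it: the difference of the two estimates of the same latent position
#' has limiting covariance `2 (1 - rho) Sigma(x) / n`, so per coordinate
#' `j` the level is `1 - n * var(diff_j) / (2 * Sigma(x)[j, j])`,
#' averaged over coordinates, with a bootstrap standard error. (The raw
#' Pearson correlation between the block residuals is also returned; it
#' equals the level only when each block's marginal residual covariance
#' is `Sigma(x)/n`, as in separate embedding, and is smaller under a
#' joint embedding whose blocks have deflated marginal variance.)
#'
#' The tracked vertex defaults to vertex 1 with the mixture sampled under
#' `balanced = TRUE`, so its latent position is the first atom in every
#' replicate.
#'
#' @param F a [latent_mixture()].
#' @param coef an `omni_coef` design, or `NULL` to embed each graph
#'   separately (the Procrustes baseline).
#' @param model sampling model: `"iid"`, `"forward"`, `"generator"` or
#'   `"pair"`.
#' @param pair block indices `c(s1, s2)` to correlate.
#' @param n vertices per graph.
#' @param m number of graphs.
#' @param d embedding dimension.
#' @param reps Monte-Carlo replicates.
#' @param rho,rho_steps,nu model parameters for the pair / forward /
#'   generator samplers.
#' @param vertex tracked vertex index.
#' @param seed integer root seed.
#' @param n_boot bootstrap resamples for the standard error.
#' @return List with `correlation`, `se`, per-coordinate `by_coordinate`,
#'   and the matrix of per-replicate residuals `residuals` (replicates in
#'   rows; block s1 coordinates then block s2 coordinates).
#' @export
embedded_correlation_mc <- function(F, coef, model = c("iid", "pair",
                                                       "forward",
                                                       "generator"),
                                    pair = c(1, 2), n = 300, m = 2, d = F$d,
                                    reps = 200, rho = 0, rho_steps = NULL,
                                    nu = NULL, vertex = 1, seed = 1,
                                    n_boot = 200) {
  model <- match.arg(model)
  stopifnot(inherits(F, "latent_mixture"))
  s1 <- pair[1]; s2 <- pair[2]
  set.seed(seed)
  latent_seeds <- sample.int(.Machine$integer.max, reps)
  graph_seeds <- sample.int(.Machine$integer.max, reps)
  res1 <- matrix(NA_real_, reps, d)
  res2 <- matrix(NA_real_, reps, d)
  for (r in seq_len(reps)) {
    X <- sample_latent(F, n, seed = latent_seeds[r], balanced = TRUE)
    G <- switch(model,
      iid = sample_iid_collection(X, m, seed = graph_seeds[r]),
      pair = sample_correlated_pair(X, rho, seed = graph_seeds[r]),
      forward = sample_forward_chain(X, rho_steps, seed = graph_seeds[r]),
      generator = sample_generator_collection(X, nu, seed = graph_seeds[r])
    )
    if (is.null(coef)) {
      b1 <- suppressWarnings(ase(G$graphs[[s1]], d))
      b2 <- suppressWarnings(ase(G$graphs[[s2]], d))
    } else {
      emb <- suppressWarnings(omni_embed(coef, G, d))
      b1 <- emb$blocks[[s1]]
      b2 <- emb$blocks[[s2]]
    }
    a1 <- procrustes_align(b1, X$X)$aligned
    a2 <- procrustes_align(b2, X$X)$aligned
    res1[r, ] <- a1[vertex, ] - X$X[vertex, ]
    res2[r, ] <- a2[vertex, ] - X$X[vertex, ]
  }
  x_tracked <- F$atoms[1, ]  # balanced assignment pins vertex 1 to atom 1
  Sjj <- diag(sigma_x(F, x_tracked))
  diff <- res1 - res2
  level <- function(idx) {
    mean(vapply(seq_len(d), function(j) {
      1 - n * stats::var(diff[idx, j]) / (2 * Sjj[j])
    }, numeric(1)))
  }
  by_coord <- vapply(seq_len(d), function(j) {
    1 - n * stats::var(diff[, j]) / (2 * Sjj[j])
  }, numeric(1))
  pearson <- if (s1 == s2) rep(1, d) else vapply(seq_len(d), function(j) {
    stats::cor(res1[, j], res2[, j])
  }, numeric(1))
  boot <- vapply(seq_len(n_boot), function(b) {
    level(sample.int(reps, reps, replace = TRUE))
  }, numeric(1))
  list(correlation = mean(by_coord), se = stats::sd(boot),
       by_coordinate = by_coord, pearson = pearson,
       residuals = cbind(res1, res2))
}
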