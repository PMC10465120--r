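#' Pairwise Frobenius distances between embedding blocks
#'
#' Because the omnibus embedding places all blocks in one coordinate
#' system, block-to-block distances need no Procrustes alignment:
#' `D[k, l] = ||X_hat^(k) - X_hat^(l)||_F`.
#'
#' @param blocks an `omni_embedding`, or a list of equally sized matrices.
#' @return A symmetric, hollow, nonnegative `m x m` matrix.
#' @export
block_distance_matrix <- function(blocks) {
  if (inherits(blocks, "omni_embedding")) blocks <- blocks$blocks
  m <- length(blocks)
  if (m < 2) stop("need at least two blocks")
  dims <- vapply(blocks, dim, integer(2))
  if (any(dims != dims[, 1])) stop("blocks must share dimensions")
  D <- matrix(0, m, m)
  for (k in seq_len(m - 1)) for (l in seq(k + 1, m)) {
    D[k, l] <- D[l, k] <- norm(blocks[[k]] - blocks[[l]], "F")
  }
  D
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centers `-D^2 / 2` and embeds with the top-`d` eigenpairs,
#' coordinates scaled by root eigenvalues (via [stats::cmdscale()]).
#' Negative eigenvalues (a non-Euclidean `D`) are truncated with a
#' warning.
#'
#' @param D symmetric distance matrix.
#' @param d target dimension, at most `nrow(D) - 1`.
#' @return An `m x d` coordinate matrix with attribute `"eigenvalues"`.
#' @export
cmds_embed <- function(D, d = 2) {
  D <- as.matrix(D)
  m <- nrow(D)
  if (d > m - 1) stop("`d` must be at most nrow(D) - 1")
  fit <- stats::cmdscale(D, k = d, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig)))) {
    warning("distance matrix is non-Euclidean; negative eigenvalues truncated")
  }
  pts <- fit$points
  if (ncol(pts) < d) {  # cmdscale drops zero-eigenvalue axes
    pts <- cbind(pts, matrix(0, m, d - ncol(pts)))
  }
  attr(pts, "eigenvalues") <- fit$eig
  pts
}

#' Gaussian-mixture model-based clustering
#'
#' Clusters points with `mclust`, selecting the number of components (and
#' covariance structure) by BIC over `k_range`, and returns hard labels.
#'
#' @param points numeric matrix (rows = observations).
#' @param k_range candidate component counts.
#' @return List with `labels`, chosen `K`, and the fitted `model`.
#' @export
gmm_cluster <- function(points, k_range = 1:5) {
  points <- as.matrix(points)
  if (nrow(points) < max(k_range)) {
    stop("fewer points than the largest candidate K")
  }
  bic <- mclust::mclustBIC(points, G = k_range, verbose = FALSE)
  fit <- mclust::Mclust(points, x = bic, verbose = FALSE)
  list(labels = fit$classification, K = fit$G, model = fit)
}

#' Minimum misclassification rate over label permutations
#'
#' Clustering labels are only defined up to renaming, so the error rate is
#' the smallest misclassification fraction over all permutations of the
#' predicted label set (exhaustive search; intended for small K).
#'
#' @param labels predicted cluster labels.
#' @param truth reference labels of equal length.
#' @return Error rate in \[0, 1\].
#' @export
clustering_error <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("length mismatch")
  labs <- sort(unique(labels))
  trus <- sort(unique(truth))
  K <- max(length(labs), length(trus))
  if (K > 6) stop("exhaustive permutation search supports at most 6 classes")
  lab_idx <- match(labels, labs)
  tru_idx <- match(truth, trus)
  tab <- matrix(0, K, K)
  for (i in seq_along(lab_idx)) {
    tab[lab_idx[i], tru_idx[i]] <- tab[lab_idx[i], tru_idx[i]] + 1
  }
  perms <- all_permutations(K)
  best <- 0
  for (p in perms) {
    hits <- sum(tab[cbind(seq_len(K), p)])
    if (hits > best) best <- hits
  }
  1 - best / length(labels)
}

all_permutations <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(K - 1)) {
    for (pos in seq_len(K)) {
      out[[length(out) + 1]] <- append(p, K, after = pos - 1)
    }
  }
  out
}

#' Elbow selection of embedding dimension by profile likelihood
#'
#' Splits the sorted eigenvalue magnitudes at every candidate point, fits
#' a common-variance two-Gaussian model to the two segments, and returns
#' the split maximizing the profile log-likelihood.
#'
#' @param eigenvalues magnitudes sorted in decreasing order.
#' @return The selected dimension (position of the elbow).
#' @export
select_dimension <- function(eigenvalues) {
  x <- as.numeric(eigenvalues)
  p <- length(x)
  if (p < 2) stop("need at least two eigenvalues")
  if (is.unsorted(rev(x))) stop("`eigenvalues` must be sorted decreasing")
  ll <- vapply(seq_len(p - 1), function(q) {
    mu1 <- mean(x[1:q])
    mu2 <- mean(x[(q + 1):p])
    ss <- sum((x[1:q] - mu1)^2) + sum((x[(q + 1):p] - mu2)^2)
    sigma2 <- max(ss / p, 1e-12)
    -p / 2 * log(2 * pi * sigma2) - ss / (2 * sigma2)
  }, numeric(1))
  which.max(ll)
}

#' Community-detection experiment on correlated blockmodel pairs
#'
#' For each cell of a grid over vertex count `n`, block-separation `eps`
#' and edge correlation `rho`, samples a correlated pair of two-block SBM
#' graphs whose Gram matrix is `[0.5 0.5; 0.5 0.5 + eps]`, estimates
#' common latent positions by three strategies, clusters each estimate
#' into two groups with a Gaussian mixture, and records the label-recovery
#' error:
#' * `omni` — classical omnibus embedding, blocks averaged;
#' * `abar` — adjacency spectral embedding of the mean graph;
#' * `procrustes` — separate embeddings, Procrustes-aligned, averaged.
#'
#' @param n_grid,eps_grid,rho_grid parameter grids.
#' @param reps Monte-Carlo replicates per cell.
#' @param seed integer root seed.
#' @param d embedding dimension (2 for the two-block model).
#' @return A tibble with one row per (cell, replicate, method):
#'   columns `n`, `eps`, `rho`, `rep`, `seed`, `method`, `error`.
#' @export
run_community_detection_experiment <- function(n_grid = 100,
                                               eps_grid = 0.2,
                                               rho_grid = c(0, 0.75),
                                               reps = 50, seed = 1, d = 2) {
  grid <- expand.grid(n = n_grid, eps = eps_grid, rho = rho_grid)
  set.seed(seed)
  cls <- classical_coefficients(2)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    n <- grid$n[g]; eps <- grid$eps[g]; rho <- grid$rho[g]
    B <- matrix(c(0.5, 0.5, 0.5, 0.5 + eps), 2)
    F <- sbm_mixture(B)
    cell_seeds <- sample.int(.Machine$integer.max, reps)
    for (r in seq_len(reps)) {
      X <- sample_latent(F, n, seed = cell_seeds[r], balanced = TRUE)
      G <- sample_correlated_pair(X, rho, seed = cell_seeds[r] + 1L)
      truth <- X$labels

      emb <- suppressWarnings(omni_embed(cls, G, d))
      x_omni <- (emb$blocks[[1]] + emb$blocks[[2]]) / 2
      abar <- (G$graphs[[1]] + G$graphs[[2]]) / 2
      x_abar <- suppressWarnings(ase(abar, d))
      e1 <- suppressWarnings(ase(G$graphs[[1]], d))
      e2 <- suppressWarnings(ase(G$graphs[[2]], d))
      x_proc <- (e1 + procrustes_align(e2, e1)$aligned) / 2

      for (method in c("omni", "abar", "procrustes")) {
        pts <- switch(method, omni = x_omni, abar = x_abar,
                      procrustes = x_proc)
        cl <- gmm_cluster(pts, k_range = 2)
        rows[[length(rows) + 1]] <- tibble::tibble(
          n = n, eps = eps, rho = rho, rep = r, seed = cell_seeds[r],
          method = method, error = clustering_error(cl$labels, truth)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("community_experiment", class(out))
  out
}

#' Effective-sample-size experiment
#'
#' For each edge correlation in `rho_grid`, samples `reps` collections of
#' `m` pairwise `rho`-correlated graphs (single-generator construction
#' with common fidelity `sqrt(rho)`), estimates the latent positions of
#' each graph, aligns all estimates to the truth, averages them, and
#' records the scaled residual of a tracked vertex. The empirical
#' covariance of these residuals is compared to the correlated
#' sample-mean law `((1 - rho)/m + rho) * Sigma(x)`, i.e. `Sigma(x)`
#' over the effective sample size.
#'
#' @param m graphs per collection.
#' @param rho_grid edge correlations in \[0, 1).
#' @param n vertices per graph.
#' @param reps replicates per grid point.
#' @param F latent mixture (defaults to the two-block Gram
#'   `[0.7 0.3; 0.3 0.5]` mixture).
#' @param method `"separate"` (embed each graph, align, average) or
#'   `"omni"` (average the classical omnibus blocks).
#' @param vertex tracked vertex.
#' @param seed integer root seed.
#' @return A tibble with one row per (rho, replicate): scaled residual
#'   coordinates `r1..rd`, plus per-rho theoretical variance columns
#'   carried in the attribute `"theory"` (tibble of `rho`, `var_theory`
#'   = mean diagonal of the limiting covariance, `ess`).
#' @export
run_ess_experiment <- function(m = 4, rho_grid = c(0, 0.25, 0.5, 0.75),
                               n = 400, reps = 200, F = NULL,
                               method = c("separate", "omni"),
                               vertex = 1, seed = 1) {
  method <- match.arg(method)
  if (is.null(F)) F <- sbm_mixture(matrix(c(0.7, 0.3, 0.3, 0.5), 2))
  d <- F$d
  cls <- classical_coefficients(m)
  rows <- list()
  theory <- list()
  set.seed(seed)
  for (rho in rho_grid) {
    rep_seeds <- sample.int(.Machine$integer.max, reps)
    for (r in seq_len(reps)) {
      X <- sample_latent(F, n, seed = rep_seeds[r], balanced = TRUE)
      G <- sample_generator_collection(X, nu = rep(sqrt(rho), m),
                                       seed = rep_seeds[r] + 1L)
      if (method == "separate") {
        est <- lapply(G$graphs, function(A) {
          procrustes_align(suppressWarnings(ase(A, d)), X$X)$aligned
        })
        avg <- Reduce(`+`, est) / m
      } else {
        emb <- suppressWarnings(omni_embed(cls, G, d))
        avg <- Reduce(`+`, emb$blocks) / m
        avg <- procrustes_align(avg, X$X)$aligned
      }
      resid <- sqrt(n) * (avg[vertex, ] - X$X[vertex, ])
      rows[[length(rows) + 1]] <- tibble::tibble(
        rho = rho, rep = r, seed = rep_seeds[r],
        !!!stats::setNames(as.list(resid), paste0("r", seq_len(d)))
      )
    }
    Sig <- averaged_estimator_covariance(m, rho, F, F$atoms[1, ])$Sigma
    theory[[length(theory) + 1]] <- tibble::tibble(
      rho = rho, var_theory = mean(diag(Sig)),
      ess = effective_sample_size(m, rho)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "theory") <- dplyr::bind_rows(theory)
  class(out) <- c("ess_experiment", class(out))
  out
}

#' Network time-series pipeline: embed, distance, scale, cluster
#'
#' The full change-point / phase-discovery pipeline for an aligned network
#' time series: generalized omnibus embedding of all graphs at once,
#' pairwise Frobenius distances between blocks, classical MDS of the
#' distance matrix, and Gaussian-mixture clustering of the resulting
#' per-graph points.
#'
#' @param G a `graph_collection`.
#' @param coef an `omni_coef` design with matching `m` (e.g.
#'   [dampened_coefficients()] with weights `1:m` for anomaly detection).
#' @param d_embed omnibus embedding dimension.
#' @param d_mds MDS dimension.
#' @param k_range candidate cluster counts.
#' @return List of class `timeseries_pipeline` with `embedding`,
#'   `distances`, `configuration` (MDS coordinates), `labels`, `K`.
#' @export
run_timeseries_pipeline <- function(G, coef, d_embed = 2, d_mds = 2,
                                    k_range = 1:6) {
  emb <- suppressWarnings(omni_embed(coef, G, d_embed))
  D <- block_distance_matrix(emb)
  if (max(D) < 1e-8) {
    # identical blocks: MDS of a zero matrix is a single point cloud
    conf <- matrix(0, emb$m, d_mds)
    return(structure(list(embedding = emb, distances = D,
                          configuration = conf,
                          labels = rep(1L, emb$m), K = 1L),
                     class = "timeseries_pipeline"))
  }
  conf <- suppressWarnings(cmds_embed(D, d_mds))
  cl <- gmm_cluster(conf, k_range = k_range)
  structure(list(embedding = emb, distances = D, configuration = conf,
                 labels = cl$labels, K = cl$K),
            class = "timeseries_pipeline")
}

#' @export
print.timeseries_pipeline <- function(x, ...) {
  cat("Time-series pipeline:", length(x$labels), "graphs,", x$K,
      "clusters\n")
  cat("labels:", x$labels, "\n")
  invisible(x)
}
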