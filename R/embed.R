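#' Adjacency spectral embedding
#'
#' Embeds a symmetric matrix into `d` dimensions via its top-`d`
#' eigenpairs ordered by eigenvalue magnitude:
#' `X_hat = U |S|^(1/2)` where `S` holds the `d` largest-magnitude
#' eigenvalues and `U` the corresponding eigenvectors. For an RDPG
#' adjacency matrix the rows of `X_hat` are consistent estimates of the
#' latent positions, up to one common orthogonal rotation.
#'
#' Negative eigenvalues among the retained `d` are allowed (their
#' magnitude is used for scaling) but flagged with a warning, as is a tie
#' between the `d`-th and `(d+1)`-th magnitudes, where the deterministic
#' index-order tie-break applies. For reproducibility each eigenvector's
#' largest-magnitude entry is made positive. A zero matrix yields a zero
#' embedding with a warning.
#'
#' @param A symmetric numeric matrix.
#' @param d embedding dimension, `1 <= d <= nrow(A)`.
#' @return An `n x d` matrix with attribute `"eigenvalues"` carrying the
#'   `d` retained (signed) eigenvalues.
#' @export
ase <- function(A, d) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (!isSymmetric(A, tol = 1e-8)) stop("`A` must be symmetric")
  if (d < 1 || d > n) stop("`d` must lie in 1..nrow(A)")
  e <- eigen(A, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  lam <- e$values[ord[seq_len(d)]]
  if (d < n &&
      isTRUE(all.equal(abs(e$values[ord[d]]), abs(e$values[ord[d + 1]]),
                       tolerance = 1e-10)) &&
      abs(e$values[ord[d]]) > 0) {
    warning("tie at the d-th eigenvalue magnitude; using index order")
  }
  if (all(abs(lam) < 1e-12)) {
    warning("matrix is (numerically) zero; returning a zero embedding")
    out <- matrix(0, n, d)
    attr(out, "eigenvalues") <- lam
    return(out)
  }
  if (any(lam < 0)) {
    warning("negative eigenvalue(s) among the top-d magnitudes")
  }
  U <- e$vectors[, ord[seq_len(d)], drop = FALSE]
  for (j in seq_len(d)) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) U[, j] <- -U[, j]
  }
  out <- U %*% diag(sqrt(abs(lam)), d)
  attr(out, "eigenvalues") <- lam
  out
}

#' Assemble a generalized omnibus matrix
#'
#' Forms the `mn x mn` block matrix whose `(k, l)` block is
#' `sum_q c[k, l, q] A^(q)`. Substituting the common edge-probability
#' matrix `P` for every graph yields `J_m %x% P` exactly, the rank-`d`
#' expectation that underwrites the embedding theory.
#'
#' @param coef an `omni_coef` design (see [omnibus_designs]).
#' @param G a `graph_collection` (or list of matrices) with `m` graphs
#'   matching the design.
#' @return A symmetric `mn x mn` numeric matrix.
#' @export
assemble_omnibus <- function(coef, G) {
  c_arr <- coef_array(coef)
  graphs <- if (inherits(G, "graph_collection")) G$graphs else G
  m <- dim(c_arr)[1]
  if (length(graphs) != m) stop("design is for ", m, " graphs, got ",
                                length(graphs))
  chk <- validate_coefficients(c_arr)
  if (!chk$valid) stop("invalid omnibus design: ", chk$first_violation)
  n <- nrow(graphs[[1]])
  M <- matrix(0, m * n, m * n)
  for (k in seq_len(m)) for (l in k:m) {
    blk <- matrix(0, n, n)
    for (q in seq_len(m)) {
      cq <- c_arr[k, l, q]
      if (cq != 0) blk <- blk + cq * graphs[[q]]
    }
    ri <- (k - 1) * n + seq_len(n)
    ci <- (l - 1) * n + seq_len(n)
    M[ri, ci] <- blk
    if (l != k) M[ci, ri] <- t(blk)
  }
  M
}

#' Generalized omnibus embedding
#'
#' Assembles the omnibus matrix for a weight design and spectrally embeds
#' it once, returning `m` aligned `n x d` blocks of estimated latent
#' positions — one per graph, in block-row order, with no Procrustes step
#' needed between them.
#'
#' @param coef an `omni_coef` design.
#' @param G a `graph_collection` with matching `m`.
#' @param d embedding dimension.
#' @return An object of class `omni_embedding`: list with `blocks` (list of
#'   `m` `n x d` matrices), the stacked `mn x d` `embedding`, retained
#'   `eigenvalues`, `design`, `m`, `n`, `d`. `tidy()` returns one row per
#'   (graph, vertex).
#' @export
omni_embed <- function(coef, G, d) {
  graphs <- if (inherits(G, "graph_collection")) G$graphs else G
  M <- assemble_omnibus(coef, G)
  Xhat <- ase(M, d)
  n <- nrow(graphs[[1]])
  m <- length(graphs)
  blocks <- lapply(seq_len(m), function(s) {
    Xhat[(s - 1) * n + seq_len(n), , drop = FALSE]
  })
  structure(
    list(blocks = blocks, embedding = `attr<-`(Xhat, "eigenvalues", NULL),
         eigenvalues = attr(Xhat, "eigenvalues"),
         design = if (inherits(coef, "omni_coef")) coef$design else "custom",
         m = m, n = n, d = d),
    class = "omni_embedding"
  )
}

#' @export
print.omni_embedding <- function(x, ...) {
  cat("Omnibus embedding (", x$design, "): ", x$m, " blocks of ",
      x$n, " x ", x$d, "\n", sep = "")
  invisible(x)
}

#' Orthogonal Procrustes alignment
#'
#' Finds the orthogonal `d x d` matrix `W` minimizing
#' `||Xhat %*% W - target||_F`, via the singular value decomposition of
#' `t(Xhat) %*% target`.
#'
#' @param Xhat,target numeric matrices of identical dimension.
#' @return List with `W` (orthogonal rotation), `residual` (the minimized
#'   Frobenius norm) and `aligned` (`Xhat %*% W`).
#' @export
procrustes_align <- function(Xhat, target) {
  Xhat <- as.matrix(Xhat)
  target <- as.matrix(target)
  if (!all(dim(Xhat) == dim(target))) stop("shape mismatch")
  s <- svd(crossprod(Xhat, target))
  W <- s$u %*% t(s$v)
  aligned <- Xhat %*% W
  list(W = W, residual = norm(aligned - target, "F"), aligned = aligned)
}
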