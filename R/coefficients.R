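#' Omnibus weight designs
#'
#' A generalized omnibus matrix of `m` graphs is the `mn x mn` block matrix
#' whose `(k, l)` block is the convex combination
#' `sum_q c[k, l, q] A^(q)`. A design is admissible when every block's
#' weights are a convex combination, the coefficient tensor is symmetric in
#' its first two indices (so the omnibus matrix is symmetric), and in every
#' block-row `k` the cumulative weight `alpha(k, k)` of the row's own graph
#' strictly dominates the cumulative weight `alpha(k, q)` of every other
#' graph.
#'
#' `classical_coefficients()` is the pairwise-average design: diagonal
#' blocks are `A^(k)`, off-diagonal blocks `(A^(k) + A^(l)) / 2`.
#'
#' `total_average_coefficients()` puts the grand mean of all graphs on
#' every off-diagonal block.
#'
#' `weighted_pairwise_coefficients()` takes per-graph weights `w` and sets
#' block `(k, l)` to `(w_k A^(k) + w_l A^(l)) / (w_k + w_l)`, so noisier
#' graphs can be down-weighted.
#'
#' `dampened_coefficients()` requires strictly increasing weights and sets
#' block `(k, l)` for `k > l` to `(w_k A^(k) + A^(l)) / (w_k + 1)`: later
#' graphs dominate their block-rows more strongly, so the induced
#' correlation decays along the sequence (suited to time series with an
#' early anomaly).
#'
#' `forward_coefficients()` sets block `(i, j)` for `i > j` to
#' `((i - 1) A^(j) + A^(i)) / i`, producing correlation that grows along
#' the sequence.
#'
#' `pair_preserving_coefficients()` (even `m`) averages only consecutive
#' odd-even pairs and passes a single graph through every other block, so
#' the embedded correlation of a designated pair tracks its inherent
#' correlation for large `m`.
#'
#' @param m number of graphs (at least 2; even for the pair-preserving
#'   design).
#' @param w positive per-graph weights (strictly increasing for the
#'   dampened design).
#' @return An object of class `omni_coef`: list with the `m x m x m`
#'   coefficient array `c` (`c[k, l, q]` = weight of graph `q` in block
#'   `(k, l)`), the design name and parameters.
#' @seealso [validate_coefficients()], [weight_profile()],
#'   [assemble_omnibus()]
#' @name omnibus_designs
NULL

new_omni_coef <- function(c_arr, design, params = list()) {
  structure(list(c = c_arr, m = dim(c_arr)[1], design = design,
                 params = params),
            class = "omni_coef")
}

#' @export
print.omni_coef <- function(x, ...) {
  cat("Omnibus weight design '", x$design, "' for m = ", x$m, " graphs\n",
      sep = "")
  invisible(x)
}

#' @rdname omnibus_designs
#' @export
classical_coefficients <- function(m) {
  m <- check_m(m)
  c_arr <- array(0, c(m, m, m))
  for (k in seq_len(m)) for (l in seq_len(m)) {
    if (k == l) {
      c_arr[k, l, k] <- 1
    } else {
      c_arr[k, l, k] <- c_arr[k, l, l] <- 1 / 2
    }
  }
  new_omni_coef(c_arr, "classical")
}

#' @rdname omnibus_designs
#' @export
total_average_coefficients <- function(m) {
  m <- check_m(m)
  c_arr <- array(0, c(m, m, m))
  for (k in seq_len(m)) for (l in seq_len(m)) {
    if (k == l) c_arr[k, l, k] <- 1 else c_arr[k, l, ] <- 1 / m
  }
  new_omni_coef(c_arr, "total_average")
}

#' @rdname omnibus_designs
#' @export
weighted_pairwise_coefficients <- function(w) {
  w <- as.numeric(w)
  m <- length(w)
  if (m < 2) stop("need at least two graphs")
  if (any(w <= 0)) stop("weights must be strictly positive")
  c_arr <- array(0, c(m, m, m))
  for (k in seq_len(m)) for (l in seq_len(m)) {
    if (k == l) {
      c_arr[k, l, k] <- 1
    } else {
      c_arr[k, l, k] <- w[k] / (w[k] + w[l])
      c_arr[k, l, l] <- w[l] / (w[k] + w[l])
    }
  }
  new_omni_coef(c_arr, "weighted_pairwise", list(w = w))
}

#' @rdname omnibus_designs
#' @export
dampened_coefficients <- function(w) {
  w <- as.numeric(w)
  m <- length(w)
  if (m < 2) stop("need at least two graphs")
  if (any(w <= 0) || any(diff(w) <= 0)) {
    stop("`w` must be strictly increasing and positive")
  }
  c_arr <- array(0, c(m, m, m))
  for (k in seq_len(m)) for (l in seq_len(m)) {
    if (k == l) {
      c_arr[k, l, k] <- 1
    } else if (k > l) {
      c_arr[k, l, k] <- w[k] / (w[k] + 1)
      c_arr[k, l, l] <- 1 / (w[k] + 1)
    } else {
      c_arr[k, l, k] <- 1 / (w[l] + 1)
      c_arr[k, l, l] <- w[l] / (w[l] + 1)
    }
  }
  new_omni_coef(c_arr, "dampened", list(w = w))
}

#' @rdname omnibus_designs
#' @export
forward_coefficients <- function(m) {
  m <- check_m(m)
  c_arr <- array(0, c(m, m, m))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) {
      c_arr[i, j, i] <- 1
    } else if (i > j) {
      c_arr[i, j, j] <- (i - 1) / i
      c_arr[i, j, i] <- 1 / i
    } else {
      c_arr[i, j, i] <- (j - 1) / j
      c_arr[i, j, j] <- 1 / j
    }
  }
  new_omni_coef(c_arr, "forward")
}

#' @rdname omnibus_designs
#' @export
pair_preserving_coefficients <- function(m) {
  m <- check_m(m)
  if (m %% 2 != 0) stop("the pair-preserving design requires even `m`")
  c_arr <- array(0, c(m, m, m))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i %% 2 == 1) {                 # odd block-row
      if (i == j || i <= j - 2) {
        c_arr[i, j, i] <- 1
      } else if (i == j - 1) {
        c_arr[i, j, i] <- c_arr[i, j, j] <- 1 / 2
      } else {                         # i > j
        c_arr[i, j, j] <- 1
      }
    } else {                           # even block-row
      if (i == j || i <= j - 1) {
        c_arr[i, j, i] <- 1
      } else if (i == j + 1) {
        c_arr[i, j, i] <- c_arr[i, j, j] <- 1 / 2
      } else {                         # i - 1 > j
        c_arr[i, j, j] <- 1
      }
    }
  }
  new_omni_coef(c_arr, "pair_preserving")
}

check_m <- function(m) {
  if (length(m) != 1 || m < 2 || m != round(m)) {
    stop("`m` must be an integer of at least 2")
  }
  as.integer(m)
}

#' Cumulative weight profile of an omnibus design
#'
#' `alpha(k, q)` is the total weight that block-row `k` of the omnibus
#' matrix puts on graph `q`, summed over the row's blocks. Every row sums
#' to `m`, and an admissible design has `alpha(k, k) > alpha(k, q)` for all
#' `q != k`. The profile alone determines the limiting induced correlation
#' of the embedding (see [limiting_correlation()]).
#'
#' @param coef an `omni_coef` object, or a bare `m x m x m` array.
#' @return An `m x m` matrix of class `weight_profile`.
#' @export
weight_profile <- function(coef) {
  c_arr <- coef_array(coef)
  alpha <- apply(c_arr, c(1, 3), sum)  # alpha[k, q] = sum_l c[k, l, q]
  structure(alpha, class = c("weight_profile", "matrix", "array"))
}

coef_array <- function(coef) {
  if (inherits(coef, "omni_coef")) return(coef$c)
  if (is.array(coef) && length(dim(coef)) == 3) return(coef)
  stop("expected an `omni_coef` object or an m x m x m array")
}

#' Check the admissibility of an omnibus weight design
#'
#' Diagnoses the three defining conditions of a generalized omnibus
#' matrix: each block's coefficients form a convex combination
#' (nonnegative, summing to 1), the coefficient tensor is block-symmetric,
#' and the weight profile is strictly diagonally dominant row-wise.
#'
#' @param coef an `omni_coef` object or `m x m x m` array.
#' @return A list with logical fields `convexity`, `symmetry`, `dominance`,
#'   overall `valid`, and `first_violation` (`NA` when valid). Class
#'   `omni_coef_check`; `glance()` returns it as a one-row tibble.
#' @export
validate_coefficients <- function(coef) {
  c_arr <- coef_array(coef)
  m <- dim(c_arr)[1]
  block_sums <- apply(c_arr, c(1, 2), sum)
  convexity <- all(c_arr >= -1e-10) && all(abs(block_sums - 1) < 1e-10)
  symmetry <- TRUE
  for (q in seq_len(m)) {
    if (max(abs(c_arr[, , q] - t(c_arr[, , q]))) > 1e-10) {
      symmetry <- FALSE
      break
    }
  }
  alpha <- apply(c_arr, c(1, 3), sum)
  dominance <- all(vapply(seq_len(m), function(k) {
    all(alpha[k, k] > alpha[k, -k])
  }, logical(1)))
  checks <- c(convexity = convexity, symmetry = symmetry,
              dominance = dominance)
  first <- if (all(checks)) NA_character_ else names(checks)[!checks][1]
  structure(
    list(convexity = convexity, symmetry = symmetry, dominance = dominance,
         valid = all(checks), first_violation = first, m = m),
    class = "omni_coef_check"
  )
}

#' @export
print.omni_coef_check <- function(x, ...) {
  status <- if (x$valid) "valid" else paste("INVALID:", x$first_violation)
  cat("Omnibus design check (m = ", x$m, "): ", status, "\n", sep = "")
  cat(sprintf("  convexity: %s  symmetry: %s  dominance: %s\n",
              x$convexity, x$symmetry, x$dominance))
  invisible(x)
}
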