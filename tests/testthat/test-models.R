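test_that("forward-propagation correlation matrix is the step product", {
  R <- forward_correlation(c(0.8, 0.8))
  expect_equal(R[1, 3], 0.64)
  expect_equal(diag(R), rep(1, 3))
  expect_true(isSymmetric(unclass(R)))

  expect_equal(unclass(forward_correlation(rep(1, 4))),
               matrix(1, 5, 5))

  R2 <- forward_correlation(c(0.5, 0.2))
  expect_equal(R2[1, 2], 0.5)
  expect_equal(R2[2, 3], 0.2)
  expect_equal(R2[1, 3], 0.10)

  expect_error(forward_correlation(numeric(0)), "nonempty")
  expect_error(forward_correlation(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(forward_correlation(-0.1), "\\[0, 1\\]")
})

test_that("single-generator correlation matrix is the outer product", {
  R <- generator_correlation(rep(0.8, 4))
  expect_equal(R[1, 2], 0.64)
  expect_equal(generator_correlation(c(0.8, 0.3))[1, 2], 0.24)
  expect_equal(unclass(generator_correlation(rep(0, 3))), diag(3))
  expect_error(generator_correlation(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("constructed correlation matrices are PSD with unit diagonal", {
  for (i in 1:5) {
    set.seed(i)
    m <- sample(2:8, 1)
    Rf <- forward_correlation(runif(m - 1))
    Rg <- generator_correlation(runif(m))
    for (R in list(Rf, Rg)) {
      expect_equal(diag(unclass(R)), rep(1, m))
      ev <- eigen(unclass(R), symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-10)
      expect_silent(as_correlation_matrix(unclass(R)))
    }
  }
})

test_that("latent mixtures validate weights and inner products", {
  expect_error(latent_mixture(diag(2), c(0.4, 0.4)), "sum to 1")
  expect_error(latent_mixture(matrix(c(2, 0), 1)), "\\[0, 1\\]")
  F <- two_block_mixture()
  expect_equal(F$weights, c(0.5, 0.5))
  expect_equal(F$atoms %*% t(F$atoms),
               matrix(c(0.7, 0.3, 0.3, 0.5), 2), tolerance = 1e-10)
})

test_that("latent sampling hits mixture frequencies and is reproducible", {
  x0 <- matrix(c(0.4, 0.3), 1)
  F0 <- latent_mixture(x0)
  X <- sample_latent(F0, 10, seed = 1)
  expect_true(all(X$X[, 1] == 0.4) && all(X$X[, 2] == 0.3))

  F <- two_block_mixture()
  X1 <- sample_latent(F, 300, seed = 42)
  n1 <- sum(X1$labels == 1)
  # binomial(300, 1/2): 4 SDs around 150
  expect_lt(abs(n1 - 150), 4 * sqrt(300 * 0.25))

  X2 <- sample_latent(F, 300, seed = 42)
  expect_identical(X1$X, X2$X)

  Xb <- sample_latent(F, 11, seed = 1, balanced = TRUE)
  expect_equal(Xb$labels[1], 1)
  expect_equal(sum(Xb$labels == 1), 6)
})

test_that("RDPG sampler produces symmetric hollow binary draws at rate P", {
  n <- 200
  X0 <- constant_p_positions(10, 0)
  expect_equal(sample_rdpg(X0, seed = 1)$graphs[[1]], matrix(0, 10, 10))

  X1 <- constant_p_positions(10, 1)
  A1 <- sample_rdpg(X1, seed = 1)$graphs[[1]]
  expect_equal(A1, matrix(1, 10, 10) - diag(10))

  Xp <- constant_p_positions(n, 0.3)
  A <- sample_rdpg(Xp, seed = 5)$graphs[[1]]
  expect_true(isSymmetric(A))
  expect_equal(diag(A), rep(0, n))
  expect_true(all(A %in% c(0, 1)))
  dens <- mean(A[upper.tri(A)])
  ne <- n * (n - 1) / 2
  expect_lt(abs(dens - 0.3), 3 * sqrt(0.3 * 0.7 / ne))
})

test_that("forward chain reproduces its target correlation structure", {
  X <- constant_p_positions(80, 0.5)
  G1 <- sample_forward_chain(X, rep(1, 2), seed = 3)
  expect_identical(G1$graphs[[1]], G1$graphs[[2]])
  expect_identical(G1$graphs[[1]], G1$graphs[[3]])

  # rho = 0: conditionally independent; correlation near zero
  X2 <- constant_p_positions(150, 0.5)
  G0 <- sample_forward_chain(X2, c(0, 0), seed = 4)
  r0 <- pearson_graph_correlation(G0$graphs[[1]], G0$graphs[[3]])
  expect_lt(abs(r0), 4 / sqrt(150 * 149 / 2))

  # rho = 0.8 chain: corr(1, 3) targets 0.64 via the product rule
  X3 <- constant_p_positions(400, 0.5)
  P <- gram_matrix(X3)
  reps <- 12
  est <- sapply(seq_len(reps), function(r) {
    G <- sample_forward_chain(X3, c(0.8, 0.8), seed = 100 + r)
    plugin_edge_correlation(G$graphs[[1]], G$graphs[[3]], P)
  })
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.64), 3 * se + 1e-12)

  # reproducibility under a fixed root seed
  Ga <- sample_forward_chain(X, c(0.5, 0.5), seed = 11)
  Gb <- sample_forward_chain(X, c(0.5, 0.5), seed = 11)
  expect_identical(Ga$graphs, Gb$graphs)
})

test_that("generator collection reproduces nu_k1 * nu_k2 correlation", {
  X <- constant_p_positions(80, 0.5)
  G1 <- sample_generator_collection(X, c(1, 1), seed = 2)
  expect_identical(G1$graphs[[1]], G1$generator)
  expect_identical(G1$graphs[[2]], G1$generator)

  X2 <- sample_latent(two_block_mixture(), 500, seed = 9, balanced = TRUE)
  P <- gram_matrix(X2)
  reps <- 10
  est <- sapply(seq_len(reps), function(r) {
    G <- sample_generator_collection(X2, c(0.8, 0.8), seed = 200 + r)
    plugin_edge_correlation(G$graphs[[1]], G$graphs[[2]],
                            pmin(pmax(P, 1e-4), 1 - 1e-4))
  })
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.64), 3 * se + 1e-12)

  G0 <- sample_generator_collection(constant_p_positions(150, 0.5),
                                    c(0, 0), seed = 5)
  r0 <- pearson_graph_correlation(G0$graphs[[1]], G0$graphs[[2]])
  expect_lt(abs(r0), 4 / sqrt(150 * 149 / 2))
})

test_that("correlated pair sampler matches the requested rho", {
  X <- constant_p_positions(80, 0.5)
  Gid <- sample_correlated_pair(X, 1, seed = 6)
  expect_identical(Gid$graphs[[1]], Gid$graphs[[2]])

  expect_error(sample_correlated_pair(X, -0.2, seed = 1), "\\[0, 1\\]")
  expect_error(sample_correlated_pair(X, 1.5, seed = 1), "\\[0, 1\\]")

  X2 <- sample_latent(two_block_mixture(), 300, seed = 21, balanced = TRUE)
  P <- pmin(pmax(gram_matrix(X2), 1e-4), 1 - 1e-4)
  reps <- 12
  est <- sapply(seq_len(reps), function(r) {
    G <- sample_correlated_pair(X2, 0.75, seed = 300 + r)
    plugin_edge_correlation(G$graphs[[1]], G$graphs[[2]], P)
  })
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.75), 3 * se + 1e-12)
})

test_that("marginal edge frequencies stay binomial around P", {
  F <- two_block_mixture()
  X <- sample_latent(F, 40, seed = 13, balanced = TRUE)
  P <- gram_matrix(X)
  R <- 200
  acc <- matrix(0, 40, 40)
  for (r in seq_len(R)) {
    acc <- acc + sample_generator_collection(X, c(0.6, 0.6),
                                             seed = r)$graphs[[1]]
  }
  freq <- acc / R
  ut <- upper.tri(P)
  sds <- sqrt(P[ut] * (1 - P[ut]) / R)
  frac_ok <- mean(abs(freq[ut] - P[ut]) <= 4 * sds)
  expect_gte(frac_ok, 0.99)
})

test_that("graph_collection rejects malformed adjacency input", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1  # asymmetric
  expect_error(graph_collection(list(A)), "symmetric")
  B <- diag(3)
  expect_error(graph_collection(list(B)), "hollow")
  C <- matrix(0, 3, 3); C[1, 2] <- C[2, 1] <- 2
  expect_error(graph_collection(list(C)), "binary")
})
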