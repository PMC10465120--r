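test_that("second moment is the exact mixture expectation", {
  F <- two_block_mixture()
  D <- second_moment(F)
  expect_equal(sum(diag(D)), 0.5 * (0.7 + 0.5), tolerance = 1e-12)
  expect_equal(D, 0.5 * (tcrossprod(F$atoms[1, ]) + tcrossprod(F$atoms[2, ])),
               tolerance = 1e-12, ignore_attr = TRUE)

  # a single atom is full rank only in one dimension
  x0 <- latent_mixture(matrix(0.5, 1, 1))
  expect_equal(second_moment(x0)[1, 1], 0.25)
  expect_error(second_moment(latent_mixture(matrix(c(0.5, 0.2), 1))),
               "rank deficient")

  # collapsed blocks: rank-1 second moment in 2 dimensions
  flat <- latent_mixture(rbind(c(0.5, 0.5), c(0.5, 0.5)))
  expect_error(second_moment(flat), "rank deficient")
})

test_that("sigma_x matches scalar closed form and brute-force sums", {
  p <- 0.37
  F1 <- latent_mixture(matrix(sqrt(p), 1))
  expect_equal(sigma_x(F1, sqrt(p))[1, 1], 1 - p, tolerance = 1e-12)

  F <- two_block_mixture()
  x <- F$atoms[1, ]
  # independent brute-force evaluation of the finite-mixture expectation
  Delta <- 0.5 * (tcrossprod(F$atoms[1, ]) + tcrossprod(F$atoms[2, ]))
  E <- matrix(0, 2, 2)
  for (k in 1:2) {
    pk <- sum(x * F$atoms[k, ])
    E <- E + 0.5 * (pk - pk^2) * tcrossprod(F$atoms[k, ])
  }
  oracle <- solve(Delta) %*% E %*% solve(Delta)
  expect_equal(sigma_x(F, x), oracle, tolerance = 1e-12)

  # all inner products in {0, 1}: Bernoulli variance vanishes
  F01 <- latent_mixture(matrix(1, 1))
  expect_equal(sigma_x(F01, 1)[1, 1], 0, tolerance = 1e-12)

  ev <- eigen(sigma_x(F, x), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("block covariance coefficients follow the printed forms", {
  F <- two_block_mixture()
  x <- F$atoms[1, ]
  for (m in c(2, 5, 9)) {
    a <- weight_profile(classical_coefficients(m))
    bc <- block_covariance(a, NULL, 1, F, x)
    expect_equal(bc$method_coefficient, (m + 3) / (4 * m), tolerance = 1e-12)
    expect_equal(bc$model_coefficient, 0)

    ta <- block_covariance(weight_profile(total_average_coefficients(m)),
                           NULL, 1, F, x)
    expect_equal(ta$method_coefficient, (m^2 + m - 1) / m^3,
                 tolerance = 1e-12)

    # perfect correlation collapses the total coefficient to 1
    ones <- matrix(1, m, m)
    bc1 <- block_covariance(a, ones, 1, F, x)
    expect_equal(bc1$method_coefficient + bc1$model_coefficient, 1,
                 tolerance = 1e-12)
  }
  expect_equal(block_covariance(weight_profile(classical_coefficients(2)),
                                NULL, 1, F, x)$method_coefficient, 5 / 8)
  # weighted design with w = (w, 1, ..., 1): printed method coefficient
  for (w in c(0.5, 2, 7)) {
    m <- 6
    a <- weight_profile(weighted_pairwise_coefficients(c(w, rep(1, m - 1))))
    expect_equal(
      block_covariance(a, NULL, 1, F, x)$method_coefficient,
      (m - 1 + (1 + m * w)^2) / (m^2 * (1 + w)^2),
      tolerance = 1e-12
    )
  }
})

test_that("difference covariance links to the limiting correlation", {
  F <- two_block_mixture()
  x <- F$atoms[1, ]
  a <- weight_profile(classical_coefficients(4))
  z <- difference_covariance(a, NULL, 2, 2, F, x)
  expect_equal(z$Sigma, 0 * z$Sigma)

  d5 <- difference_covariance(a, NULL, 1, 2, F, x)
  expect_equal(d5$coefficient, 1 / 2, tolerance = 1e-12)
  expect_equal(d5$Sigma, 0.5 * sigma_x(F, x), tolerance = 1e-12)

  # coefficient = 2 (1 - rho(s1, s2)) across random designs
  set.seed(31)
  for (i in 1:100) {
    m <- sample(2:8, 1)
    a <- random_alpha(m)
    R <- random_R(m)
    s <- sample(m, 2)
    dc <- difference_covariance(a, R, s[1], s[2], F, x)
    lc <- limiting_correlation(a, R, s[1], s[2])
    expect_equal(dc$coefficient, 2 * (1 - lc$correlation),
                 tolerance = 1e-10)
    # both printed algebraic forms agree when rows sum to m
    expect_equal(dc$coefficient, dc$coefficient_product_form,
                 tolerance = 1e-10)
  }
})

test_that("the two covariance forms disagree when row sums differ from m", {
  F <- two_block_mixture()
  a <- unclass(weight_profile(classical_coefficients(3)))
  a[1, 1] <- a[1, 1] + 0.5   # break the row-sum invariant
  dc <- difference_covariance(a, NULL, 1, 2, F, F$atoms[1, ])
  expect_gt(abs(dc$coefficient - dc$coefficient_product_form), 1e-4)
})

test_that("classical limiting correlation is 3/4 plus a quarter of rho", {
  set.seed(32)
  for (i in 1:50) {
    m <- sample(2:10, 1)
    R <- random_R(m)
    s <- sort(sample(m, 2))
    lc <- limiting_correlation(weight_profile(classical_coefficients(m)),
                               R, s[1], s[2])
    expect_equal(lc$correlation, 3 / 4 + R[s[1], s[2]] / 4,
                 tolerance = 1e-12)
    expect_equal(lc$method, 3 / 4, tolerance = 1e-12)
  }
})

test_that("limiting correlation is 1 iff profile rows coincide, monotone in rho", {
  a <- unclass(weight_profile(classical_coefficients(3)))
  a2 <- rbind(a[1, ], a[1, ], a[3, ])
  expect_equal(limiting_correlation(a2, NULL, 1, 2)$correlation, 1)

  vals <- sapply(seq(0, 1, 0.25), function(r) {
    R <- matrix(r, 4, 4); diag(R) <- 1
    limiting_correlation(weight_profile(dampened_coefficients(1:4)),
                         R, 1, 3)$correlation
  })
  expect_true(all(diff(vals) > 0))
})

test_that("closed forms equal the general formula through the builders", {
  set.seed(33)
  for (i in 1:40) {
    m <- sample(2:12, 1)
    rho <- runif(1)
    R <- matrix(rho, m, m); diag(R) <- 1
    s <- sort(sample(m, 2))

    lc <- limiting_correlation(weight_profile(classical_coefficients(m)),
                               R, s[1], s[2])$correlation
    expect_equal(lc, closed_form_correlation("classical", m, rho),
                 tolerance = 1e-10)

    lt <- limiting_correlation(weight_profile(total_average_coefficients(m)),
                               R, s[1], s[2])$correlation
    expect_equal(lt, closed_form_correlation("total_average", m, rho),
                 tolerance = 1e-10)

    w <- runif(1, 0.2, 5)
    ww <- rep(1, m); ww[s] <- w
    lw <- limiting_correlation(weight_profile(weighted_pairwise_coefficients(ww)),
                               R, s[1], s[2])$correlation
    expect_equal(lw, closed_form_correlation("weighted_equal_pair", m, rho,
                                             w = w),
                 tolerance = 1e-10)
  }
  for (m in c(2, 4, 8, 12)) {
    rho <- runif(1)
    R <- matrix(rho, m, m); diag(R) <- 1
    lp <- limiting_correlation(weight_profile(pair_preserving_coefficients(m)),
                               R, 1, 2)$correlation
    expect_equal(lp, closed_form_correlation("pair_preserving", m, rho),
                 tolerance = 1e-10)
  }
  expect_equal(closed_form_correlation("total_average", 3, 0), 8 / 9)
  expect_equal(closed_form_correlation("weighted_equal_pair", 5, 0.3, w = 1),
               3 / 4 + 0.3 / 4)
  expect_equal(closed_form_correlation("pair_preserving", 100, 0.64),
               1 - 0.36 * 99^2 / 100^2)
  expect_error(closed_form_correlation("nope", 3), "unknown")
})

test_that("pair-preserving correlation approaches the inherent one", {
  val <- closed_form_correlation("pair_preserving", 100, 0.64)
  expect_lt(abs(val - (0.64 + (1 - 0.64) * (2 * 100 - 1) / 100^2)), 0.01)
})

test_that("dampened closed-form transcription agrees with the general law", {
  m <- 50
  R <- forward_correlation(rep(0.8, m - 1))
  a <- weight_profile(dampened_coefficients(seq_len(m)))
  for (pair in list(c(1, 2), c(3, 17), c(20, 45), c(49, 50))) {
    expect_equal(
      limiting_correlation(a, R, pair[1], pair[2])$correlation,
      dampened_closed_form(m, pair[1], pair[2], unclass(R)),
      tolerance = 1e-10
    )
  }
})

test_that("effective sample size interpolates between 1 and m", {
  expect_equal(effective_sample_size(7, 0), 7)
  expect_equal(effective_sample_size(7, 1), 1)
  expect_equal(effective_sample_size(2, 0.5), 4 / 3)
  rhos <- seq(0, 1, 0.1)
  vals <- sapply(rhos, effective_sample_size, m = 10)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 1 & vals <= 10))
  expect_error(effective_sample_size(0, 0.5), "positive integer")
  expect_error(effective_sample_size(3, 1.2), "\\[0, 1\\]")
})

test_that("averaged-estimator covariance matches the effective sample size", {
  F <- two_block_mixture()
  x <- F$atoms[1, ]
  S <- sigma_x(F, x)
  a0 <- averaged_estimator_covariance(4, 0, F, x)
  expect_equal(a0$rho_prime, 1 / 4)
  expect_equal(a0$Sigma, S / 4, tolerance = 1e-12)       # independent: 1/m
  a1 <- averaged_estimator_covariance(4, 1, F, x)
  expect_equal(a1$Sigma, S, tolerance = 1e-12)           # identical graphs
  # variance factor is exactly 1 / effective sample size
  for (rho in c(0, 0.3, 0.8)) {
    av <- averaged_estimator_covariance(5, rho, F, x)
    expect_equal(av$rho_prime, 1 / effective_sample_size(5, rho),
                 tolerance = 1e-12)
  }
  expect_error(averaged_estimator_covariance(1, 0.5, F, x), ">= 2")
})
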