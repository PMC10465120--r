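# Shared model fixtures, built in code.

# Two-block SBM mixture with Gram matrix [0.7 0.3; 0.3 0.5], equal weights.
two_block_mixture <- function() {
  sbm_mixture(matrix(c(0.7, 0.3, 0.3, 0.5), 2))
}

# Two-block SBM mixture with Gram [0.5 0.5; 0.5 0.5 + eps], equal weights;
# eps = 0 collapses the blocks (rank 1).
eps_block_mixture <- function(eps) {
  sbm_mixture(matrix(c(0.5, 0.5, 0.5, 0.5 + eps), 2))
}

# Homogeneous latent positions: every edge probability equals p.
constant_p_positions <- function(n, p) {
  latent_positions(matrix(sqrt(p), n, 1))
}

# Random admissible weight profile: draws a random weighted pairwise
# design (always admissible for positive weights).
random_alpha <- function(m) {
  weight_profile(weighted_pairwise_coefficients(stats::runif(m, 0.2, 3)))
}

# Random valid correlation matrix from the single-generator family.
random_R <- function(m) {
  generator_correlation(stats::runif(m))
}

# Independent transcription of the printed dampened-omnibus (w_l = l)
# closed-form correlation: method part rho_me plus inherent part rho_mo.
# Used solely as an oracle for limiting_correlation on the dampened design.
dampened_closed_form <- function(m, s1, s2, R) {
  stopifnot(s1 < s2)
  sum_gt_s1 <- function() {
    ls <- setdiff(seq(s1 + 1, m), s2)
    sum(1 / (ls + 1))
  }
  sum_gt_s2 <- function() {
    if (s2 >= m) 0 else sum(1 / (seq(s2 + 1, m) + 1))
  }
  A1 <- (s1^2 + 1) / (s1 + 1) + sum_gt_s1()      # weight gap at q = s1
  A2 <- (s2^2 - s2 + 1) / (s2 + 1) + sum_gt_s2() # |gap| at q = s2
  mid <- if (s2 - s1 > 1) seq(s1 + 1, s2 - 1) else integer(0)
  rho_me <- 1 - (1 / (2 * m^2)) * (
    (s1 - 1) * (s2 - s1)^2 / ((s1 + 1)^2 * (s2 + 1)^2) +
      A1^2 +
      sum((mid / (mid + 1) - 1 / (s2 + 1))^2) +
      A2^2
  )

  gap_low <- (s2 - s1) / ((s1 + 1) * (s2 + 1))   # gap at q < s1
  acc <- 0
  # pairs q < l < s1
  if (s1 > 2) {
    for (l in 2:(s1 - 1)) for (q in 1:(l - 1)) {
      acc <- acc - gap_low^2 * R[q, l]
    }
  }
  # l = s1, q < s1
  if (s1 > 1) for (q in 1:(s1 - 1)) acc <- acc - gap_low * A1 * R[q, s1]
  # s1 < l < s2
  for (l in mid) {
    gl <- l / (l + 1) - 1 / (s2 + 1)
    if (s1 > 1) for (q in 1:(s1 - 1)) acc <- acc - gap_low * gl * R[q, l]
    acc <- acc - A1 * gl * R[s1, l]
    for (q in mid[mid < l]) {
      acc <- acc - (q / (q + 1) - 1 / (s2 + 1)) * gl * R[q, l]
    }
  }
  # l = s2 (gap is -A2)
  if (s1 > 1) for (q in 1:(s1 - 1)) acc <- acc + gap_low * A2 * R[q, s2]
  acc <- acc + A1 * A2 * R[s1, s2]
  for (q in mid) {
    acc <- acc + (q / (q + 1) - 1 / (s2 + 1)) * A2 * R[q, s2]
  }
  rho_mo <- acc / m^2
  rho_me + rho_mo
}
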