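test_that("intensity_matrix validates generator structure", {
  q <- rbind(c(-0.2, 0.1, 0.1), c(0.3, -0.5, 0.2), c(0.1, 0.4, -0.5))
  m <- intensity_matrix(q)
  expect_s3_class(m, "intensity_matrix")
  expect_equal(rowSums(unclass(m)), c(from.normal = 0, from.mild = 0,
                                      from.severe = 0), ignore_attr = TRUE)

  q_bad <- q; q_bad[1, 2] <- -0.1
  expect_error(intensity_matrix(q_bad), "non-negative")
  q_bad2 <- q; q_bad2[1, 1] <- -0.5
  expect_error(intensity_matrix(q_bad2), "sum to zero")
  expect_error(transition_probability_matrix(m, -1), "non-negative")
})

test_that("P(0) is the identity and P(t) is row-stochastic with CK property", {
  set.seed(42)
  for (rep in 1:20) {
    q <- random_generator()
    p0 <- unclass(transition_probability_matrix(q, 0))
    expect_equal(p0, diag(3), tolerance = 1e-12, ignore_attr = TRUE)

    s <- runif(1, 0.1, 8); t <- runif(1, 0.1, 8)
    ps <- unclass(transition_probability_matrix(q, s))
    pt <- unclass(transition_probability_matrix(q, t))
    pst <- unclass(transition_probability_matrix(q, s + t))
    expect_true(all(ps >= 0))
    expect_equal(rowSums(ps), rep(1, 3), tolerance = 1e-9, ignore_attr = TRUE)
    expect_lt(max(abs(ps %*% pt - pst)), 1e-8)
  }
})

test_that("matrix exponential agrees with the uniformization series oracle", {
  set.seed(7)
  for (rep in 1:25) {
    q <- random_generator()
    t <- runif(1, 0.1, 15)
    p <- unclass(transition_probability_matrix(q, t))
    expect_lt(max(abs(p - expm_oracle(unclass(q), t))), 1e-10)
  }
})

test_that("jump-chain probabilities follow q_ij / -q_ii", {
  c0 <- 0.7
  q <- intensity_matrix(rbind(c(-2 * c0, c0, c0),
                              c(1, -3, 2),
                              c(0.5, 0.5, -1)))
  j <- unclass(jump_chain_probabilities(q))
  expect_equal(j[1, 2:3], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(j[2, c(1, 3)], c(1 / 3, 2 / 3), ignore_attr = TRUE)
  expect_true(all(is.na(diag(j))))
  expect_equal(rowSums(j, na.rm = TRUE), rep(1, 3), ignore_attr = TRUE)

  q_deg <- intensity_matrix(rbind(c(0, 0, 0), c(1, -2, 1), c(1, 1, -2)))
  expect_error(jump_chain_probabilities(q_deg), "normal")
  expect_error(mean_sojourn_times(q_deg), "normal")
})

test_that("mean sojourn times are reciprocal exit rates in weeks", {
  q <- intensity_matrix(rbind(c(-1, 0.5, 0.5),
                              c(0.125, -0.25, 0.125),
                              c(1 / 64.12 / 2, 1 / 64.12 / 2, -1 / 64.12)))
  s <- mean_sojourn_times(q)
  expect_equal(as.numeric(s), c(1, 4, 64.12), tolerance = 1e-12)
  expect_equal(as.numeric(mean_sojourn_times(ppd_reference_intensity())),
               c(64.12, 6.29, 9.37), tolerance = 1e-12)
})

test_that("stationary distribution solves piQ = 0 and is the t -> Inf limit", {
  # doubly-symmetric generator: uniform stationary law
  q_sym <- intensity_matrix(matrix(0.3, 3, 3) - diag(3) * 0.9)
  expect_equal(as.numeric(stationary_distribution(q_sym)), rep(1 / 3, 3),
               tolerance = 1e-10)

  set.seed(11)
  for (rep in 1:10) {
    q <- random_generator()
    pi_hat <- stationary_distribution(q)
    # oracle: left null space by eigen decomposition
    e <- eigen(t(unclass(q)))
    k <- which.min(abs(e$values))
    pi_or <- Re(e$vectors[, k]); pi_or <- pi_or / sum(pi_or)
    expect_equal(as.numeric(pi_hat), pi_or, tolerance = 1e-8)
    expect_equal(as.numeric(pi_hat %*% unclass(q)), rep(0, 3),
                 tolerance = 1e-10)

    t_long <- 10 * max(as.numeric(mean_sojourn_times(q)))
    p_long <- unclass(transition_probability_matrix(q, t_long))
    for (i in 1:3) {
      expect_equal(p_long[i, ], as.numeric(pi_hat), tolerance = 1e-4,
                   ignore_attr = TRUE)
    }
  }

  # reducible: no transitions at all
  expect_error(stationary_distribution(intensity_matrix(matrix(0, 3, 3))),
               "reducible")
})

test_that("reconstruct_intensity inverts jump/sojourn summaries exactly", {
  set.seed(5)
  for (rep in 1:20) {
    js <- random_jump_sojourn()
    q <- reconstruct_intensity(js$jump, js$sojourn)
    j_back <- unclass(jump_chain_probabilities(q))
    diag(j_back) <- 0
    expect_equal(j_back, js$jump, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(as.numeric(mean_sojourn_times(q)), js$sojourn,
                 tolerance = 1e-12)
  }
  expect_error(reconstruct_intensity(matrix(1, 3, 3), c(1, 2, 3)),
               "sum to 1")
  expect_error(reconstruct_intensity(random_jump_sojourn()$jump, c(1, -1, 2)),
               "positive")
})

test_that("uniform jump rows with unit sojourns give the symmetric generator", {
  j <- matrix(0.5, 3, 3); diag(j) <- 0
  q <- unclass(reconstruct_intensity(j, c(1, 1, 1)))
  expect_equal(diag(q), rep(-1, 3), ignore_attr = TRUE)
  expect_equal(q[upper.tri(q) | lower.tri(q)], rep(0.5, 6))
})

test_that("long-horizon interval probabilities plateau at stationarity", {
  q <- ppd_reference_intensity()
  p2 <- unclass(transition_probability_matrix(q, 104))
  p3 <- unclass(transition_probability_matrix(q, 156))
  expect_lt(max(abs(p2 - p3)), 0.005)
  pi_hat <- stationary_distribution(q)
  expect_equal(p3[1, 3], pi_hat[["severe"]], tolerance = 1e-3)
  expect_equal(p3[2, 3], pi_hat[["severe"]], tolerance = 1e-3)
})
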