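test_that("sigmoid matches its algebraic identities and is stable", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  expect_equal(sigmoid(2.7) + sigmoid(-2.7), 1, tolerance = 1e-12)
  expect_equal(sigmoid(700), 1)
  expect_equal(sigmoid(-700), 0, tolerance = 1e-300)
  expect_true(all(diff(sigmoid(seq(-20, 20, by = 0.1))) > 0))
  expect_error(sigmoid(NA_real_), "finite")
  expect_error(sigmoid(Inf), "finite")
})

test_that("effective drive reduces to the basal weight for empty sums", {
  net <- influence_network(c("X", "Y"), signals = c("S1"),
                           omega0 = c(-1, 2))
  expect_equal(effective_drive(net, c(0.3, 0.8), c(S1 = 5)),
               c(X = -1, Y = 2))
})

test_that("effective drive adds interaction and signal terms", {
  # omega_X0 = -1, omega_{Y->X} = -2 with Y = 0.5, omega_{S1->X} = 1.5
  # with S1 = 2:  W_X = -1 - 1 + 3 = 1
  net <- influence_network(c("X", "Y"), signals = "S1",
                           omega = matrix(c(0, -2, 0, 0), 2, 2),
                           omega0 = c(-1, 0),
                           signal_omega = matrix(c(1.5, 0), 1, 2))
  expect_equal(effective_drive(net, c(0, 0.5), c(S1 = 2))[["X"]], 1)
})

test_that("drive, rhs and Jacobian match independent term-by-term oracles", {
  for (seed in 1:5) {
    net <- random_dense_net(seed)
    set.seed(seed + 100)
    x <- runif(4)
    s <- stats::setNames(runif(3, 0, 2), net$signals)
    # direct summation oracle for the drive
    w_oracle <- sapply(seq_len(4), function(i) {
      tot <- net$omega0[i]
      for (j in seq_len(4)) tot <- tot + net$omega[j, i] * x[j]
      for (k in seq_len(3)) tot <- tot + net$signal_omega[k, i] * s[k]
      unname(tot)
    })
    expect_equal(unname(effective_drive(net, x, s)), w_oracle,
                 tolerance = 1e-12)
    # direct evaluation oracle for the rates
    r_oracle <- unname(net$gamma) *
      (1 / (1 + exp(-unname(net$sigma) * w_oracle)) - x)
    expect_equal(unname(network_rhs(net, x, s)), r_oracle, tolerance = 1e-12)
    # central finite differences for the Jacobian
    J <- network_jacobian(net, x, s)
    h <- 1e-6
    Jfd <- sapply(seq_len(4), function(j) {
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      (network_rhs(net, xp, s) - network_rhs(net, xm, s)) / (2 * h)
    })
    expect_equal(unname(J), unname(Jfd), tolerance = 1e-6)
  }
})

test_that("states at the sigmoid fixed point have zero rates", {
  net <- random_dense_net(11)
  s <- stats::setNames(runif(3), net$signals)
  # one fixed-point iteration sweep makes F(sigma W) consistent with x
  x <- runif(4)
  for (k in 1:500) x <- sigmoid(net$sigma * effective_drive(net, x, s))
  expect_lt(max(abs(network_rhs(net, x, s))), 1e-10)
})

test_that("rate magnitude follows gamma: X = 0, W = 0, gamma = 5 gives 2.5", {
  net <- influence_network("X", gamma = 5, regulators = NULL)
  expect_equal(unname(network_rhs(net, 0)), 2.5)
})

test_that("uncoupled networks have diagonal Jacobian -gamma", {
  net <- influence_network(c("A", "B", "C"), gamma = c(1, 2, 3),
                           omega0 = c(-1, 0, 2), regulators = NULL)
  expect_equal(unname(network_jacobian(net, c(0.1, 0.5, 0.9))),
               diag(c(-1, -2, -3)))
})

test_that("the Jacobian commutes with the swap on symmetric states", {
  net <- get_model("generic1")$network
  J <- network_jacobian(net, c(0.4, 0.4), c(S1 = 1.2))
  P <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(P %*% J %*% P, J, ignore_attr = TRUE, tolerance = 1e-12)
})
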