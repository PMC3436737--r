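test_that("one-node self-activation folds match the 1-D bisection oracle", {
  # gamma = 1, sigma = 4, basal drive -4 + S, self-activation 4: the
  # S-shaped branch has both folds inside the swept range
  net <- one_node_net(auto = 4, omega0 = -4, sigma = 4, gamma = 1)
  br <- trace_branch(net, NULL, "S", c(0, 4))
  folds <- sort(br$special_points$S[br$special_points$kind == "fold"])
  expect_length(folds, 2L)
  oracle <- one_node_folds_oracle(auto = 4, omega0 = -4, sigma = 4)
  expect_equal(folds, oracle, tolerance = 1e-6)
})

test_that("a monotone one-node branch has no special points", {
  net <- one_node_net(auto = 0, omega0 = -1, sigma = 2, gamma = 1)
  br <- trace_branch(net, NULL, "S", c(0, 3))
  expect_equal(nrow(br$special_points), 0L)
})

test_that("branch samples are ordered by arclength within the range", {
  net <- get_model("generic1")$network
  br <- trace_branch(net, NULL, "S1", c(0, 3))
  expect_true(!is.unsorted(br$samples$arclength))
  expect_true(all(br$samples$S1 >= -1e-9))
  expect_true(all(br$samples$S1 <= 3 + 0.1))
})

test_that("starting from a non-steady state is a precondition error", {
  net <- get_model("generic1")$network
  expect_error(trace_branch(net, NULL, "S1", c(0, 3), start = c(0.9, 0.9)),
               "not a steady state")
})

test_that("fold continuation in two signals matches a grid scan", {
  # one-node self-activation with two additive inputs: the fold locus in
  # the (S, S2) plane is a straight line of slope -1 in total drive, which
  # the grid scan sees as the bistability boundary
  net <- influence_network("X", signals = c("S", "S2"),
                           omega = matrix(4, 1, 1), omega0 = -4,
                           sigma = 4, gamma = 1,
                           signal_omega = matrix(c(1, 0.5), 2, 1),
                           regulators = NULL)
  br <- trace_branch(net, c(S2 = 0), "S", c(0, 4))
  f1 <- br$special_points[br$special_points$kind == "fold", ][1, ]
  lc <- continue_fold_locus(net, NULL, "S", "S2",
                            start = list(x = f1$X, p1 = f1$S),
                            p2_from = 0, p2_to = 1, step0 = 0.1)
  expect_identical(attr(lc, "terminal"), "range_end")
  # oracle: at each S2 the fold sits where the one-signal fold would,
  # shifted by -0.5 * S2 in S (drive bookkeeping)
  base <- sort(one_node_folds_oracle(4, -4, 4))[1]
  expect_equal(lc$S, base - 0.5 * lc$S2, tolerance = 1e-5)
})

test_that("criticality switches from supercritical to subcritical with auto-activation", {
  br15 <- trace_branch(get_model("generic3", list(auto_weight = 1.5))$network,
                       NULL, "S1", c(0, 3))
  br32 <- trace_branch(get_model("generic3", list(auto_weight = 3.2))$network,
                       NULL, "S1", c(0, 3))
  for (k in 1:2) {
    expect_identical(classify_pitchfork(br15, k), "supercritical")
    expect_identical(classify_pitchfork(br32, k), "subcritical")
    # the fixed-point-count route agrees with the cubic-coefficient route
    expect_identical(suppressWarnings(classify_pitchfork(br15, k, method = "count")),
                     "supercritical")
    expect_identical(suppressWarnings(classify_pitchfork(br32, k, method = "count")),
                     "subcritical")
  }
})

test_that("pitchfork loci are mirror images in the two polarizing signals", {
  net <- get_model("generic1")$network
  br <- trace_branch(net, NULL, "S1", c(0, 3))
  c2 <- continue_pitchfork_pair(net, par1 = "S1", par2 = "S2", branch = br,
                                p2_max = 0.2)
  c3 <- continue_pitchfork_pair(net, par1 = "S1", par2 = "S3", branch = br,
                                p2_max = 0.2)
  # same par2 path is taken; compare the fold positions pointwise
  n <- min(nrow(c2$loci[[1]]), nrow(c3$loci[[1]]))
  expect_equal(c2$loci[[1]]$S1[1:n], c3$loci[[1]]$S1[1:n], tolerance = 1e-8)
  expect_equal(c2$loci[[2]]$S1[1:n], c3$loci[[2]]$S1[1:n], tolerance = 1e-8)
})

test_that("increasing auto-activation widens the bistable primary-signal range", {
  s1s <- seq(0, 3, length.out = 61)
  widths <- vapply(c(1.5, 2.0, 2.6, 3.2), function(w) {
    net <- get_model("generic3", list(auto_weight = w))$network
    multi <- vapply(s1s, function(v) {
      ss <- suppressWarnings(find_steady_states(net, c(S1 = v), grid_n = 5L))
      sum(ss$stability == "stable") >= 2
    }, TRUE)
    diff(range(s1s[multi]))
  }, 0)
  expect_true(all(diff(widths) > 0))
})
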