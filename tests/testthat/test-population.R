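test_that("zero variability collapses the population onto the basal cell", {
  net <- get_model("generic1")$network
  pop <- sample_population(net, population_config(10, cv = 0, seed = 1))
  for (k in 1:10) {
    expect_equal(pop$params$omega[k, , ], unname(net$omega))
    expect_equal(pop$params$sigma[k, ], unname(net$sigma))
  }
})

test_that("sampling is reproducible from the seed and respects constraints", {
  net <- get_model("generic3")$network
  a <- sample_population(net, population_config(50, 0.05, seed = 99))
  b <- sample_population(net, population_config(50, 0.05, seed = 99))
  expect_identical(a$params, b$params)
  cc <- sample_population(net, population_config(50, 0.05, seed = 100))
  expect_false(identical(a$params, cc$params))
  # absent influences stay exactly absent; rates stay positive
  expect_true(all(a$params$omega[, 1, 2] < 0))     # perturbed inhibition
  expect_true(all(a$params$signal_omega[, 2, 2] == 0)) # S2 -> Y edge absent
  expect_true(all(a$params$sigma > 0))
  expect_true(all(a$params$gamma > 0))
})

test_that("sample means stay within normal-theory bounds of the basal values", {
  net <- get_model("generic1")$network
  pop <- sample_population(net, population_config(200, 0.05, seed = 5))
  se3 <- function(basal) 3 * 0.05 * abs(basal) / sqrt(200)
  expect_lt(abs(mean(pop$params$omega[, 2, 1]) - net$omega[2, 1]),
            se3(net$omega[2, 1]))
  expect_lt(abs(mean(pop$params$omega0[, 1]) - net$omega0[1]),
            se3(net$omega0[1]))
  expect_lt(abs(mean(pop$params$gamma[, 1]) - net$gamma[1]),
            1.1 * se3(net$gamma[1]))  # slight allowance for the >0 redraws
})

test_that("naive equilibration lands every cell in the naive state at rest", {
  net <- get_model("generic1")$network
  pop <- equilibrate_naive(sample_population(net, population_config(100, 0.05, 3)))
  expect_true(all(classify_phenotype(pop$states, net) == "naive"))
  expect_true(all(attr(pop$states, "residual") < 1e-9))
  # cv = 0: all cells at the basal fixed point
  p0 <- equilibrate_naive(sample_population(net, population_config(5, 0, 1)))
  expect_equal(max(apply(p0$states, 2, function(col) diff(range(col)))), 0)
  ss <- find_steady_states(net)
  expect_equal(unname(p0$states[1, ]),
               as.numeric(ss[ss$stability == "stable", net$nodes]),
               tolerance = 1e-7)
})

test_that("a model without a naive resting state is a model error", {
  # basal weights high enough that the rest state is double-positive
  net <- influence_network(c("X", "Y"), signals = c("S1", "S2", "S3"),
                           omega0 = c(1, 1), sigma = 2, gamma = 5,
                           signal_omega = rbind(c(1, 1), c(1, 0), c(0, 1)))
  pop <- sample_population(net, population_config(5, 0.05, 1))
  expect_error(equilibrate_naive(pop), "no naive state")
})

test_that("a single-stage protocol reproduces plain integration per cell", {
  net <- get_model("generic1")$network
  pop <- equilibrate_naive(sample_population(net, population_config(5, 0.05, 8)))
  run <- run_protocol(pop, signal_protocol(c(S1 = 2.8)))
  for (k in 1:5) {
    cell <- influence_network(net$nodes, net$signals,
                              omega = pop$params$omega[k, , ],
                              omega0 = pop$params$omega0[k, ],
                              sigma = pop$params$sigma[k, ],
                              gamma = pop$params$gamma[k, ],
                              signal_omega = pop$params$signal_omega[k, , ])
    tr <- integrate_network(cell, pop$states[k, ], c(S1 = 2.8))
    expect_equal(unname(run$states[k, ]), unname(final_state(tr)),
                 tolerance = 1e-6)
  }
})

test_that("protocols require an equilibrated population unless waived", {
  net <- get_model("generic1")$network
  pop <- sample_population(net, population_config(5, 0.05, 8))
  expect_error(run_protocol(pop, signal_protocol(c(S1 = 1))),
               "not equilibrated")
  pop$states[] <- 0.01
  expect_silent(run_protocol(pop, signal_protocol(c(S1 = 0.1)),
                             waive_equilibration = TRUE))
})

test_that("sequential polarizing-then-primary matches simultaneous treatment", {
  net <- get_model("generic1")$network
  pop <- equilibrate_naive(sample_population(net, population_config(100, 0.05, 21)))
  sim <- composition(run_protocol(pop, signal_protocol(c(S1 = 1.5, S2 = 1))))
  seq <- composition(run_protocol(pop, signal_protocol(c(S2 = 1),
                                                       c(S1 = 1.5, S2 = 1))))
  expect_identical(unclass(sim), unclass(seq))
  expect_equal(unname(unclass(sim)[["XSP"]]), 100L)
})

test_that("primary-then-polarizing shows hysteresis inside the bistable region", {
  net <- get_model("generic1")$network
  pop <- equilibrate_naive(sample_population(net, population_config(100, 0.05, 21)))
  only_primary <- run_protocol(pop, signal_protocol(c(S1 = 1.5)))
  then_pulse <- run_protocol(pop, signal_protocol(c(S1 = 1.5),
                                                  c(S1 = 1.5, S2 = 0.2)))
  expect_identical(as.character(classify_phenotype(only_primary$states, net)),
                   as.character(classify_phenotype(then_pulse$states, net)))
})

test_that("composition grids are deterministic, complete and collapse as cv -> 0", {
  net <- get_model("generic1")$network
  a1 <- list(S1 = seq(0.5, 2.5, length.out = 4))
  a2 <- list(S2 = seq(0, 0.6, length.out = 3))
  g1 <- composition_grid(net, a1, a2, population_config(20, 0.05, seed = 11))
  g2 <- composition_grid(net, a1, a2, population_config(20, 0.05, seed = 11))
  expect_identical(g1$counts, g2$counts)
  g3 <- composition_grid(net, a1, a2, population_config(20, 0.05, seed = 12))
  expect_false(identical(g1$counts, g3$counts))
  expect_true(all(apply(g1$counts, c(1, 2), sum) == 20L))
  # cv -> 0: every grid point is a single phenotype
  g0 <- composition_grid(net, a1, a2, population_config(20, 0, seed = 11))
  expect_true(all(apply(g0$counts, c(1, 2), max) == 20L))
})

test_that("one reused population gives the same naive start at every point", {
  net <- get_model("generic1")$network
  a1 <- list(S1 = c(1.5, 1.5))
  a2 <- list(S2 = c(0, 0))
  g <- composition_grid(net, a1, a2, population_config(30, 0.05, seed = 2),
                        resample = FALSE)
  # identical signals + identical cells => identical compositions
  expect_equal(g$counts[1, 1, ], g$counts[2, 1, ])
  expect_equal(g$counts[1, 1, ], g$counts[1, 2, ])
})

test_that("relaxation-rate asymmetry shifts compositions but not the average-cell map", {
  net <- get_model("generic1")$network
  net2 <- net
  net2$gamma[] <- c(8, 2)   # asymmetric relaxation, same steady states
  a1 <- list(S1 = seq(0.9, 2.1, length.out = 5))
  a2 <- list(S2 = c(0, 0.1))
  m1 <- suppressWarnings(count_attractors_map(net, a1, a2))
  m2 <- suppressWarnings(count_attractors_map(net2, a1, a2))
  expect_identical(m1$signature, m2$signature)
  expect_identical(m1$n_stable, m2$n_stable)
  g1 <- composition_grid(net, list(S1 = 1.5), list(S2 = 0),
                         population_config(100, 0.05, seed = 4))
  g2 <- composition_grid(net2, list(S1 = 1.5), list(S2 = 0),
                         population_config(100, 0.05, seed = 4))
  expect_false(identical(g1$counts, g2$counts))
})

test_that("score_grid attaches scores matching direct evaluation", {
  net <- get_model("generic1")$network
  g <- composition_grid(net, list(S1 = c(1.5)), list(S2 = c(0, 0.8)),
                        population_config(40, 0.05, seed = 13))
  sc <- score_grid(g, c("XSP", "YSP"))
  direct <- heterogeneity_score(
    composition(stats::setNames(g$counts[1, 1, ], dimnames(g$counts)[[3]])),
    c("XSP", "YSP"))$score
  expect_equal(sc[1, 1], direct)
  expect_gt(sc[1, 1], 0.5)   # heterogeneous on the axis
  expect_equal(sc[1, 2], -1) # homogeneous under strong polarizing signal
})
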