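# builders for small test networks and independent oracles

# one-node network with optional self-activation; the signal S enters with
# unit weight, so omega0 + S is the total basal drive
one_node_net <- function(auto = 0, omega0 = 0, sigma = 1, gamma = 1,
                         signal_weight = 1) {
  influence_network(nodes = "X", signals = "S",
                    omega = matrix(auto, 1, 1), omega0 = omega0,
                    sigma = sigma, gamma = gamma,
                    signal_omega = matrix(signal_weight, 1, 1),
                    regulators = NULL)
}

# random two-node network of the mutual-inhibition / auto-activation class
# (monotone interactions: no limit cycles, so basin mapping is well posed)
random_two_node <- function(seed) {
  set.seed(seed)
  om <- matrix(c(runif(1, 0, 2.5), runif(1, -3, 0),
                 runif(1, -3, 0), runif(1, 0, 2.5)), 2, 2)
  influence_network(nodes = c("X", "Y"), signals = c("S1", "S2", "S3"),
                    omega = om,
                    omega0 = runif(2, -2.5, 0.5),
                    sigma = runif(2, 0.8, 2.5),
                    gamma = runif(2, 1, 6),
                    signal_omega = rbind(runif(2, 0, 2), c(runif(1, 0, 2), 0),
                                         c(0, runif(1, 0, 2))))
}

# random dense network (any sign pattern) for algebraic oracles
random_dense_net <- function(seed, n = 4, s = 3) {
  set.seed(seed)
  influence_network(nodes = paste0("N", seq_len(n)),
                    signals = paste0("S", seq_len(s)),
                    omega = matrix(runif(n * n, -2, 2), n, n),
                    omega0 = runif(n, -2, 2),
                    sigma = runif(n, 0.5, 3),
                    gamma = runif(n, 0.5, 5),
                    signal_omega = matrix(runif(s * n, -1, 2), s, n),
                    regulators = NULL)
}

# brute-force basin mapping: integrate from a dense grid of starts and
# cluster the endpoints; independent of the Newton solver
basin_map_oracle <- function(net, signals = NULL, grid_n = 5) {
  g <- seq(0.02, 0.98, length.out = grid_n)
  starts <- as.matrix(expand.grid(g, g))
  ends <- t(apply(starts, 1L, function(x0) {
    final_state(integrate_network(net, x0, signals,
                                  max_time = 500, rate_tol = 1e-10))
  }))
  keep <- rep(TRUE, nrow(ends))
  for (i in seq_len(nrow(ends) - 1L)) {
    if (!keep[i]) next
    d <- apply(abs(sweep(ends[(i + 1):nrow(ends), , drop = FALSE], 2L,
                         ends[i, ])), 1L, max)
    keep[(i + 1):nrow(ends)][d < 1e-4] <- FALSE
  }
  u <- ends[keep, , drop = FALSE]
  u[do.call(order, as.data.frame(u)), , drop = FALSE]
}

# naive double-loop evaluation of the pairwise heterogeneity score
score_oracle <- function(counts, phenotypes, N) {
  cc <- counts[phenotypes]
  n <- length(cc)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + cc[i] + cc[j] - 2 * abs(cc[i] - cc[j])
    }
  }
  unname(s / ((n - 1) * N))
}

# analytic fold locations of the one-node model: along the fixed-point
# branch, S(x) = (logit(x)/sigma - omega0 - auto x) / signal_weight; folds
# are the interior extrema of S(x), located by bisection on dS/dx
one_node_folds_oracle <- function(auto, omega0, sigma, signal_weight = 1) {
  dS <- function(x) 1 / (sigma * x * (1 - x)) - auto
  xs <- seq(1e-4, 1 - 1e-4, length.out = 20001)
  v <- dS(xs)
  folds <- c()
  for (k in which(v[-1] * v[-length(v)] < 0)) {
    lo <- xs[k]; hi <- xs[k + 1]
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (dS(mid) * dS(lo) <= 0) hi <- mid else lo <- mid
    }
    x <- (lo + hi) / 2
    folds <- c(folds, (log(x / (1 - x)) / sigma - omega0 - auto * x) /
                 signal_weight)
  }
  sort(folds)
}
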