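test_that("a monostable model maps to count one everywhere", {
  net <- influence_network(c("X", "Y"), signals = c("S1", "S2", "S3"),
                           omega0 = c(-1, -1), sigma = 1, gamma = 1,
                           signal_omega = rbind(c(1, 1), c(1, 0), c(0, 1)))
  m <- count_attractors_map(net, list(S1 = seq(0, 2, length.out = 7)),
                            list(S2 = seq(0, 1, length.out = 5)))
  expect_true(all(m$n_stable == 1L))
})

test_that("the generic-1 map shows naive / bistable-SP / DP structure", {
  net <- get_model("generic1")$network
  m <- suppressWarnings(
    count_attractors_map(net, list(S1 = seq(0, 3, length.out = 31)),
                         list(S2 = seq(0, 1, length.out = 11))))
  s1 <- m$axis1$values
  row0 <- m$signature[, 1]  # along S2 = 0
  expect_identical(row0[s1 < 0.7], rep("naive", sum(s1 < 0.7)))
  expect_identical(row0[s1 > 0.8 & s1 < 2.3],
                   rep("XSP+YSP", sum(s1 > 0.8 & s1 < 2.3)))
  expect_identical(row0[s1 > 2.4], rep("DP", sum(s1 > 2.4)))
  # strong polarizing signal: monostable everywhere at S2 = 1
  expect_true(all(m$n_stable[, 11] == 1L))
})

test_that("the bistable-region boundary brackets the continuation loci", {
  net <- get_model("generic1")$network
  m <- suppressWarnings(
    count_attractors_map(net, list(S1 = seq(0.4, 2.7, length.out = 47)),
                         list(S2 = seq(0, 0.4, length.out = 17))))
  cc <- continue_pitchfork_pair(net, par1 = "S1", par2 = "S2", p2_max = 0.4)
  d1 <- diff(m$axis1$values[1:2])
  d2 <- diff(m$axis2$values[1:2])
  for (li in 1:2) {
    locus <- cc$loci[[li]]
    for (r in seq(1, nrow(locus), by = 4)) {
      j <- which.min(abs(m$axis2$values - locus$S2[r]))
      if (abs(m$axis2$values[j] - locus$S2[r]) > d2) next
      boundary <- m$n_stable[, j] >= 2
      if (!any(boundary)) next
      edge <- if (li == 1) min(m$axis1$values[boundary])
      else max(m$axis1$values[boundary])
      expect_lt(abs(edge - locus$S1[r]), 1.5 * d1)
    }
  }
})

test_that("symmetric models give mirrored upper and lower halves", {
  net <- get_model("generic1")$network
  a1 <- list(S1 = seq(0, 3, length.out = 19))
  up <- suppressWarnings(count_attractors_map(net, a1, list(S2 = seq(0, 1, length.out = 7))))
  lo <- suppressWarnings(count_attractors_map(net, a1, list(S3 = seq(0, 1, length.out = 7))))
  # exchange XSP <-> YSP and re-canonicalise the label order
  swapped <- function(sig) {
    lev <- c("naive", "XSP", "YSP", "DP")
    vapply(strsplit(chartr("XY", "YX", sig), "+", fixed = TRUE),
           function(p) paste(lev[lev %in% p], collapse = "+"), "")
  }
  expect_identical(swapped(up$signature),
                   as.vector(lo$signature))
  bd <- assemble_bidirectional(up, lo)
  expect_s3_class(bd, "bidirectional_diagram")
})

test_that("assembly rejects mismatched primary axes", {
  net <- get_model("generic1")$network
  up <- suppressWarnings(count_attractors_map(net, list(S1 = seq(0, 3, length.out = 5)),
                                              list(S2 = seq(0, 1, length.out = 3))))
  lo <- suppressWarnings(count_attractors_map(net, list(S1 = seq(0, 2, length.out = 5)),
                                              list(S3 = seq(0, 1, length.out = 3))))
  expect_error(assemble_bidirectional(up, lo), "share an identical")
})

test_that("region counting follows 4-neighbour connectivity", {
  # hand-built diagram: two disconnected patches of the same signature must
  # count as two regions
  mk <- function(sig) {
    structure(list(axis1 = list(name = "S1", values = 1:4),
                   axis2 = list(name = "S2", values = 0:2),
                   n_stable = matrix(1L, 4, 3),
                   signature = sig, fixed = numeric(), threshold = 0.5),
              class = "stability_map")
  }
  up <- mk(matrix(c("A", "B", "B", "A",
                    "A", "B", "B", "A",
                    "C", "C", "C", "C"), 4, 3))
  lo <- mk(matrix(c("A", "B", "B", "A",
                    "D", "D", "D", "D",
                    "D", "D", "D", "D"), 4, 3))
  bd <- assemble_bidirectional(up, lo)
  rt <- region_table(bd)
  # shared row A B B A: A patches connect vertically but not horizontally
  expect_equal(sum(rt$signature == "A"), 2L)
  expect_equal(sum(rt$signature == "B"), 1L)
  expect_equal(nrow(rt), 5L)
  expect_equal(sum(rt$n_cells), 4L * 5L)
})
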