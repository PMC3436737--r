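test_that("the registry lists six models and rejects unknown names", {
  expect_setequal(list_models(),
                  c("generic1", "generic2", "generic3",
                    "prototype1_th1_th2", "prototype2_th1_th17",
                    "prototype3_itreg_th17"))
  expect_error(get_model("nope"), "unknown model")
  expect_error(get_model("generic1", list(auto_weight = 2)), "generic3 only")
  expect_error(get_model("generic3", list(bad = 1)), "unknown override")
})

test_that("generic models share the stated relaxation rate and symmetry", {
  for (nm in c("generic1", "generic2", "generic3")) {
    net <- get_model(nm)$network
    expect_equal(unname(net$gamma), c(5, 5))
  }
  expect_true(is_symmetric_network(get_model("generic1")$network))
  expect_true(is_symmetric_network(get_model("generic3")$network))
})

test_that("every bundle records calibrated provenance and full name maps", {
  for (nm in list_models()) {
    b <- get_model(nm)
    expect_identical(b$provenance, "calibrated")
    expect_true(all(c(b$network$nodes, b$network$signals) %in%
                      names(b$biological_names)))
  }
})

test_that("the generic-3 auto-activation weight is an exposed override", {
  for (w in c(1.5, 2.5, 3.2)) {
    net <- get_model("generic3", list(auto_weight = w))$network
    expect_equal(unname(diag(net$omega)), c(w, w))
  }
})

test_that("mutations transform exactly one parameter and log themselves", {
  p1 <- get_model("prototype1_th1_th2")
  ko <- apply_mutation(p1, mutation_spec("scale_weight",
                                         c("GATA3", "GATA3"), 0.1))
  expect_equal(ko$network$omega["GATA3", "GATA3"],
               p1$network$omega["GATA3", "GATA3"] * 0.1)
  # everything else untouched; original bundle unchanged
  ko$network$omega["GATA3", "GATA3"] <- p1$network$omega["GATA3", "GATA3"]
  expect_equal(ko$network, p1$network)
  expect_length(ko$mutations, 1L)
  expect_length(p1$mutations, 0L)
  # identity mutation reproduces the bundle exactly
  id <- apply_mutation(p1, mutation_spec("scale_weight", c("TCR", "TBET"), 1))
  expect_equal(id$network, p1$network)
  expect_error(apply_mutation(p1, mutation_spec("set_basal", "NOPE", -1)),
               "unknown node")
  expect_error(mutation_spec("scale_weight", "just_one", 2), "target")
})

test_that("the Th1/Th17 T-bet knockout is ten times the basal weight", {
  p2 <- get_model("prototype2_th1_th17")
  expect_equal(unname(p2$network$omega0["TBET"]), -1.7)
  ko <- apply_mutation(p2, mutation_spec("set_basal", "TBET", -17))
  expect_equal(unname(ko$network$omega0["TBET"]),
               10 * unname(p2$network$omega0["TBET"]))
})

test_that("the auto-activation calibration reproduces the registry constants", {
  net <- calibrate_generic3()
  cal <- attr(net, "calibration")
  reg <- get_model("generic3")$network
  expect_equal(unname(net$sigma), unname(reg$sigma), tolerance = 1e-10)
  expect_equal(unname(net$omega0), unname(reg$omega0), tolerance = 1e-9)
  expect_equal(net$signal_omega["S1", 1], reg$signal_omega["S1", 1],
               tolerance = 1e-9)
  expect_lt(cal$pitchfork_residual, 1e-3)
  # without auto-activation the mutual inhibition is below the bistability
  # threshold sigma * w = 4
  expect_lt(unname(net$sigma[1]) * -net$omega["Y", "X"], 4)
})

test_that("the core-motif calibration hits its three bifurcation targets", {
  net <- calibrate_generic1()
  cal <- attr(net, "calibration")
  reg <- get_model("generic1")$network
  expect_equal(net$signal_omega, reg$signal_omega, tolerance = 1e-9)
  expect_equal(unname(net$omega0), unname(reg$omega0), tolerance = 1e-9)
  expect_lt(cal$pitchfork_residual, 1e-3)
  # the fitted polarizing weight places the scan-based cusp on its target
  expect_equal(cal$cusp_drive / cal$b, 0.357, tolerance = 1e-9)
})

test_that("prototype topologies match their influence diagrams", {
  p1 <- get_model("prototype1_th1_th2")$network
  expect_lt(p1$omega["TBET", "GATA3"], 0)      # mutual inhibition
  expect_lt(p1$omega["GATA3", "TBET"], 0)
  expect_gt(p1$omega["TBET", "TBET"], 0)       # auto-activation
  expect_gt(p1$omega["GATA3", "GATA3"], 0)
  expect_true(all(p1$signal_omega["TCR", ] > 0))  # primary drives both
  p2 <- get_model("prototype2_th1_th17")$network
  expect_lt(p2$signal_omega["TGFB_IL6", "TBET"], 0)  # TGF-b represses T-bet
  expect_gt(p2$signal_omega["TGFB_IL6", "RORGT"], 0)
  p3 <- get_model("prototype3_itreg_th17")$network
  expect_lt(p3$signal_omega["IL6", "FOXP3"], 0)
  expect_gt(p3$signal_omega["IL6", "RORGT"], 0)
  expect_lt(p3$signal_omega["ATRA_IL2", "RORGT"], 0)
  expect_gt(p3$signal_omega["ATRA_IL2", "FOXP3"], 0)
})
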