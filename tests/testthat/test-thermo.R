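.thermo_model <- function() {
  mets <- data.frame(id = c("a_c", "b_c"), compartment = "c",
                     formula = "C3H6O3", charge = 0)
  metabolic_model(mets, list(
    list(id = "R1", stoichiometry = c(a_c = -1, b_c = 1), lb = -10,
         ub = 10)))
}

test_that("sign of dG'deg decides direction at unit concentrations", {
  m <- .thermo_model()
  td <- thermo_data(c(R1 = -30), conc_bounds = list(a_c = c(1, 1),
                                                    b_c = c(1, 1)))
  b <- directionality_bounds(m, td)
  expect_equal(b$lb, 0)          # reverse closed
  expect_equal(b$ub, 10)        # forward open
  td2 <- thermo_data(c(R1 = 0), conc_bounds = list(a_c = c(1e-3, 1e3) / 31.6,
                                                   b_c = c(1e-3, 1e3) / 31.6))
  b2 <- directionality_bounds(m, td2)
  expect_equal(b2$lb, -10)      # symmetric range straddles zero
  expect_equal(b2$ub, 10)
})

test_that("the concentration term matches the closed-form bound", {
  m <- .thermo_model()
  RT <- 8.31446261815324e-3 * 298.15
  cb <- list(a_c = c(1e-6, 1e-2), b_c = c(1e-6, 1e-2))
  td <- thermo_data(c(R1 = 5), conc_bounds = cb)
  # min dG' = 5 + RT*(ln cmin(b) - ln cmax(a)); hand computation
  lo <- 5 + RT * (log(1e-6) - log(1e-2))
  hi <- 5 + RT * (log(1e-2) - log(1e-6))
  b <- directionality_bounds(m, td)
  expect_equal(b$ub, if (lo < 0) 10 else 0)
  expect_equal(b$lb, if (hi > 0) -10 else 0)
  expect_lt(lo, 0); expect_gt(hi, 0)   # both directions admitted here
  expect_equal(b$lb, -10); expect_equal(b$ub, 10)
  # narrow the product range so dG' can no longer be negative
  td2 <- thermo_data(c(R1 = 30), conc_bounds = cb)
  b2 <- directionality_bounds(m, td2)
  expect_equal(b2$ub, 0)
})

test_that("bounds are never relaxed and invalid concentrations error", {
  m <- .thermo_model()
  td <- thermo_data(c(R1 = -100))
  b <- directionality_bounds(m, td)
  expect_true(all(b$lb >= m$rxns$lb - 1e-12))
  expect_true(all(b$ub <= m$rxns$ub + 1e-12))
  expect_error(thermo_data(c(R1 = 0), conc_bounds = list(a_c = c(0, 1))),
               "concentration")
  expect_error(thermo_data(c(R1 = 0), conc_bounds = list(a_c = c(2, 1))),
               "concentration")
})

test_that("uncovered reactions pass through and empty data is the identity", {
  toy <- make_toy_gem(toy_spec(seed = 17), certify = FALSE)
  td <- thermo_data(stats::setNames(numeric(0), character(0)))
  b <- directionality_bounds(toy$model, td)
  m2 <- apply_directionality(toy$model, b)
  expect_equal(m2$rxns, toy$model$rxns)
  # and the pipeline output is identical with and without the pre-pass
  gt <- toy$ground_truth[[1]]
  dem <- stats::setNames(gt$demand, gt$sink_id)
  r1 <- generate_lumps(toy$model, toy$partition, dem)
  r2 <- generate_lumps(m2, toy$partition, dem)
  expect_equal(lapply(r1[[1]]$subnetworks, function(s) s$reactions),
               lapply(r2[[1]]$subnetworks, function(s) s$reactions))
  expect_equal(lapply(r1[[1]]$lumps, function(l) l$stoichiometry),
               lapply(r2[[1]]$lumps, function(l) l$stoichiometry))
})

test_that("core-scoped tightening leaves non-core reactions alone", {
  toy <- make_toy_gem(toy_spec(seed = 23), certify = FALSE)
  m <- toy$model
  rid_core <- toy$partition$core_reactions[1]
  rid_nc <- toy$partition$noncore_reactions[1]
  dg <- stats::setNames(c(-50, -50), c(rid_core, rid_nc))
  td <- thermo_data(dg, conc_bounds = stats::setNames(
    rep(list(c(1, 1)), n_metabolites(m)), m$mets$id))
  b_all <- directionality_bounds(m, td, scope = "all")
  b_core <- directionality_bounds(m, td, scope = "core",
                                  partition = toy$partition)
  k_nc <- match(rid_nc, m$rxns$id)
  expect_equal(b_core$lb[k_nc], m$rxns$lb[k_nc])
  expect_true(b_all$lb[k_nc] >= m$rxns$lb[k_nc])
})
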