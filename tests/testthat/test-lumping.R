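test_that("a single-reaction subnetwork lumps to that reaction normalized", {
  m <- tiny_linear_model()
  m <- add_target_sinks(m, "tgt_c")
  pt <- tiny_partition(m)
  sg <- split_and_gate(m, pt)
  sn <- find_min_subnetwork(subnetwork_problem(sg, "sink_tgt_c", 2))
  expect_equal(sn$reactions, "MID2")
  fx <- minimize_net_flux(m, pt, sn)
  expect_equal(fx$values[["MID2"]], 2)
  expect_equal(fx$objective_value, 2)   # demand d on one unit reaction
  lump <- build_lump(sn, fx, m, pt)
  expect_equal(lump$stoichiometry[sort(names(lump$stoichiometry))],
               c(mid_c = -1, tgt_c = 1))
  expect_true(all(lump$balance_report == 0))
})

test_that("L1 minimization confines flux to one route of a diamond", {
  dm <- diamond_model()
  sg <- split_and_gate(dm$model, dm$partition)
  alts <- enumerate_alternatives(subnetwork_problem(sg, "sink_tgt_c", 1.5))
  sn <- alts[[1]]
  fx <- minimize_net_flux(dm$model, dm$partition, sn)
  expect_equal(fx$objective_value, 2 * 1.5)     # two steps at demand
  active <- names(fx$values)[abs(fx$values) > 1e-9]
  expect_setequal(setdiff(active, c("EX_src", "sink_tgt_c")), sn$reactions)
  # lump equals the hand-computed column sum of the chosen route
  lump <- build_lump(sn, fx, dm$model, dm$partition)
  expect_equal(lump$stoichiometry[sort(names(lump$stoichiometry))],
               c(src_c = -1, tgt_c = 1))
})

test_that("lumps contain only core species, target and drained by-products", {
  toy <- make_toy_gem(toy_spec(seed = 63), certify = FALSE)
  gt <- toy$ground_truth[[1]]
  sg <- split_and_gate(toy$model, toy$partition)
  alts <- enumerate_alternatives(
    subnetwork_problem(sg, gt$sink_id, gt$demand))
  for (k in seq_along(alts)) {
    fx <- minimize_net_flux(toy$model, toy$partition, alts[[k]])
    lump <- build_lump(alts[[k]], fx, toy$model, toy$partition)
    drained <- unique(unlist(lapply(
      toy$model$rxns$id[is_exchange(toy$model)],
      function(r) names(reaction_stoich(toy$model, r)))))
    allowed <- c(toy$partition$core_metabolites, lump$target_id, drained)
    expect_true(all(names(lump$stoichiometry) %in% allowed))
    expect_equal(lump$stoichiometry[[lump$target_id]], 1)
    expect_true(all(lump$balance_report == 0))
    # matches the planted ground-truth lump
    want <- gt$lumps[[k]]
    expect_equal(lump$stoichiometry[sort(names(lump$stoichiometry))],
                 want[sort(names(want))])
  }
})

test_that("lumping is invariant to the demand scale", {
  toy <- make_toy_gem(toy_spec(seed = 70), certify = FALSE)
  gt <- toy$ground_truth[[1]]
  sg <- split_and_gate(toy$model, toy$partition)
  sn <- find_min_subnetwork(subnetwork_problem(sg, gt$sink_id, gt$demand))
  l1 <- build_lump(sn, minimize_net_flux(toy$model, toy$partition, sn,
                                         demand = gt$demand),
                   toy$model, toy$partition)
  l2 <- build_lump(sn, minimize_net_flux(toy$model, toy$partition, sn,
                                         demand = gt$demand / 2),
                   toy$model, toy$partition)
  expect_equal(l1$stoichiometry[sort(names(l1$stoichiometry))],
               l2$stoichiometry[sort(names(l2$stoichiometry))])
})

test_that("the elemental audit flags constructed faults", {
  m <- tiny_linear_model()
  # a fabricated lump missing one H2O-equivalent: mid (C3H6O3) -> tgt + "H2O"
  mets <- data.frame(id = c("mid_c", "tgt2_c", "h2o_c"), compartment = "c",
                     formula = c("C3H6O3", "C3H4O2", "H2O"), charge = 0)
  mm <- metabolic_model(mets, list(list(
    id = "X", stoichiometry = c(mid_c = -1, tgt2_c = 1, h2o_c = 1),
    lb = 0, ub = 1)))
  balanced <- c(mid_c = -1, tgt2_c = 1, h2o_c = 1)
  expect_true(all(audit_elemental_balance(balanced, mm) == 0))
  corrupted <- c(mid_c = -1, tgt2_c = 1)      # drop the water
  res <- audit_elemental_balance(corrupted, mm)
  expect_equal(res[["H"]], -2)
  expect_equal(res[["O"]], -1)
  # the empty lump audits to no residuals at all
  expect_length(audit_elemental_balance(stats::setNames(numeric(0),
                                                        character(0)), mm), 0)
  # species without formulas are reported as unaudited
  mm2 <- suppressWarnings(metabolic_model(
    data.frame(id = "x_c", compartment = "c", formula = NA, charge = NA),
    list(list(id = "EX_x", stoichiometry = c(x_c = -1), lb = 0, ub = 1))))
  r2 <- audit_elemental_balance(c(x_c = 1), mm2)
  expect_equal(attr(r2, "unaudited"), "x_c")
})

test_that("identical lumps merge, cofactor-variant lumps stay distinct", {
  toy <- make_toy_gem(toy_spec(planted_paths = list(list(c(3, 2))),
                               distinct_cofactors = FALSE, seed = 83),
                      certify = FALSE)
  gt <- toy$ground_truth[[1]]
  sg <- split_and_gate(toy$model, toy$partition)
  alts <- enumerate_alternatives(
    subnetwork_problem(sg, gt$sink_id, gt$demand))
  lumps <- lapply(alts, function(sn) {
    build_lump(sn, minimize_net_flux(toy$model, toy$partition, sn),
               toy$model, toy$partition)
  })
  uniq <- dedupe_lumps(lumps)
  expect_length(alts, 2)
  expect_length(uniq, 1)                       # same overall stoichiometry
  expect_equal(sort(uniq[[1]]$provenance), c(1, 2))
  # alternating cofactor pairs keep the lumps apart
  toy2 <- make_toy_gem(toy_spec(planted_paths = list(list(c(3, 2))),
                                distinct_cofactors = TRUE, seed = 83),
                       certify = FALSE)
  gt2 <- toy2$ground_truth[[1]]
  sg2 <- split_and_gate(toy2$model, toy2$partition)
  alts2 <- enumerate_alternatives(
    subnetwork_problem(sg2, gt2$sink_id, gt2$demand))
  lumps2 <- lapply(alts2, function(sn) {
    build_lump(sn, minimize_net_flux(toy2$model, toy2$partition, sn),
               toy2$model, toy2$partition)
  })
  expect_length(dedupe_lumps(lumps2), 2)
  # a list of one is returned unchanged
  expect_length(dedupe_lumps(lumps[1]), 1)
})

test_that("equation strings are sorted, signed and human-readable", {
  lump <- structure(list(
    target_id = "ala_c",
    stoichiometry = c(pyr_c = -1, nh4_c = -1, nadph_c = -1, h_c = -1,
                      ala_c = 1, h2o_c = 1, nadp_c = 1),
    provenance = 1L), class = "lumped_reaction")
  expect_equal(
    lump_equation(lump),
    "h_c + nadph_c + nh4_c + pyr_c -> ala_c + h2o_c + nadp_c")
  lump$stoichiometry["pyr_c"] <- -1.5
  expect_match(lump_equation(lump), "1.5 pyr_c")
})
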