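test_that("model construction enforces its invariants", {
  mets <- data.frame(id = c("a_c", "b_c"), compartment = "c",
                     formula = "C3H6O3", charge = 0)
  ok <- list(list(id = "R1", stoichiometry = c(a_c = -1, b_c = 1),
                  lb = 0, ub = 10))
  m <- metabolic_model(mets, ok)
  expect_s3_class(m, "metabolic_model")
  expect_equal(n_reactions(m), 1)
  expect_equal(reaction_stoich(m, "R1"), c(a_c = -1, b_c = 1))
  # undeclared metabolite, duplicate ids, inverted bounds
  expect_error(metabolic_model(mets, list(list(
    id = "R1", stoichiometry = c(zz = -1), lb = 0, ub = 1))), "undeclared")
  expect_error(metabolic_model(rbind(mets, mets[1, ]), ok), "duplicate")
  expect_error(metabolic_model(mets, list(list(
    id = "R1", stoichiometry = c(a_c = -1), lb = 5, ub = 1))),
    "lower bound")
})

test_that("a one-reaction hand-written model survives both formats", {
  mets <- data.frame(id = c("glc_c", "pyr_c"), compartment = "c",
                     formula = c("C6H12O6", "C3H4O3"), charge = c(0, -1))
  m <- metabolic_model(mets, list(list(
    id = "GLY", stoichiometry = c(glc_c = -1, pyr_c = 2), lb = -10,
    ub = 10)), id = "mini")
  for (fmt in c("bigg-json", "sbml-fbc")) {
    path <- tempfile(fileext = if (fmt == "bigg-json") ".json" else ".xml")
    write_model(m, path, fmt)
    m2 <- load_model(path)
    expect_equal(sort(m2$mets$id), sort(m$mets$id))
    expect_equal(reaction_stoich(m2, "GLY"), reaction_stoich(m, "GLY"))
    expect_equal(m2$rxns$lb, m$rxns$lb)
    expect_equal(m2$rxns$ub, m$rxns$ub)
    expect_equal(m2$mets$formula[match(m$mets$id, m2$mets$id)],
                 m$mets$formula)
  }
})

test_that("generator output round-trips through JSON to an equal model", {
  toy <- make_toy_gem(toy_spec(seed = 42), certify = FALSE)
  path <- tempfile(fileext = ".json")
  write_model(toy$model, path)
  m2 <- load_model(path)
  m1 <- toy$model
  expect_equal(sort(m2$rxns$id), sort(m1$rxns$id))
  perm_m <- match(m1$mets$id, m2$mets$id)
  perm_r <- match(m1$rxns$id, m2$rxns$id)
  expect_lt(max(abs(m1$S - m2$S[perm_m, perm_r])), 1e-9)
  expect_equal(m2$rxns$lb[perm_r], m1$rxns$lb)
  expect_equal(m2$rxns$ub[perm_r], m1$rxns$ub)
  expect_equal(m2$mets$formula[perm_m], m1$mets$formula)
  expect_equal(m2$objective, m1$objective)
  expect_equal(m2$medium, m1$medium)
})

test_that("unparsable files and missing formulas are reported", {
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_model(bad), "JSON")
  nometa <- tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x", reactions = list()), nometa,
                       auto_unbox = TRUE)
  expect_error(load_model(nometa), "metabolites")
  # formula-less species load with a warning, not an error
  m <- metabolic_model(
    data.frame(id = "a_c", compartment = "c", formula = NA, charge = NA),
    list(list(id = "EX_a", stoichiometry = c(a_c = -1), lb = 0, ub = 1)))
  p <- tempfile(fileext = ".json")
  write_model(m, p)
  expect_warning(load_model(p), "formula")
})

test_that("SBML output is readable by an independent COBRA implementation", {
  toy <- make_toy_gem(toy_spec(seed = 5), certify = FALSE)
  path <- tempfile(fileext = ".xml")
  write_model(toy$model, path, "sbml-fbc")
  out <- suppressWarnings(system2(
    solver_python(),
    c("-c", shQuote(sprintf(
      paste0("import cobra; m = cobra.io.read_sbml_model('%s'); ",
             "print(len(m.metabolites), len(m.reactions), ",
             "round(m.slim_optimize(), 9))"), path))),
    stdout = TRUE, stderr = FALSE))
  vals <- strsplit(tail(out, 1), " ")[[1]]
  expect_equal(as.integer(vals[1]), n_metabolites(toy$model))
  expect_equal(as.integer(vals[2]), n_reactions(toy$model))
  expect_equal(as.numeric(vals[3]), fba(toy$model)$objective_value,
               tolerance = 1e-6)
})

test_that("target drains are added with the documented shape", {
  m <- tiny_linear_model()
  m2 <- add_target_sinks(m, "tgt_c")
  expect_equal(n_reactions(m2), n_reactions(m) + 1)
  expect_equal(reaction_stoich(m2, "sink_tgt_c"), c(tgt_c = -1))
  expect_equal(m2$rxns$lb[match("sink_tgt_c", m2$rxns$id)], 0)
  # empty target list is the identity
  expect_equal(n_reactions(add_target_sinks(m, character(0))),
               n_reactions(m))
  # produced role injects instead of draining
  m3 <- add_target_sinks(m, "tgt_c", role = "produced")
  expect_equal(reaction_stoich(m3, "sink_tgt_c"), c(tgt_c = 1))
  # id collisions get deterministic suffixes
  expect_message(m4 <- add_target_sinks(m2, "tgt_c"), "suffixing")
  expect_true("sink_tgt_c_1" %in% m4$rxns$id)
  expect_error(add_target_sinks(m, "nope_c"), "unknown metabolite")
})

test_that("sinks scale to many targets and the count matches", {
  toy <- make_toy_gem(toy_spec(planted_paths = list(list(c(2, 1)),
                                                    list(c(2, 1))),
                               seed = 9, with_biomass = TRUE),
                      certify = FALSE)
  drains <- grep("^sink_", toy$model$rxns$id, value = TRUE)
  expect_equal(length(drains), 2)
  expect_equal(sort(drains), c("sink_bbb1_c", "sink_bbb2_c"))
})
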