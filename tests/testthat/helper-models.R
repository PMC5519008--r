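# Hand-built micro-models shared across tests.  Everything is constructed in
# code; no fixture files.

# src -> mid -> tgt, all C3H6O3 isomers; MID2 is the only non-core step.
tiny_linear_model <- function() {
  mets <- data.frame(
    id = c("src_c", "mid_c", "tgt_c", "orphan_c"),
    compartment = "c",
    formula = c("C3H6O3", "C3H6O3", "C3H6O3", "C2H4O2"),
    charge = 0)
  rxns <- list(
    list(id = "EX_src", stoichiometry = c(src_c = -1), lb = -5, ub = 1000,
         subsystem = "exchange"),
    list(id = "CORE1", stoichiometry = c(src_c = -1, mid_c = 1),
         lb = -1000, ub = 1000, subsystem = "core"),
    list(id = "MID2", stoichiometry = c(mid_c = -1, tgt_c = 1),
         lb = 0, ub = 1000, subsystem = "noncore"))
  metabolic_model(mets, rxns, medium = c(EX_src = 5), id = "tiny")
}

# partition for tiny_linear_model after sinks are added
tiny_partition <- function(model) {
  define_core(model, "CORE1", gate_transports = FALSE)
}

# diamond: two parallel 2-step routes from the core precursor to the target
diamond_model <- function() {
  mets <- data.frame(
    id = c("src_c", "a_c", "b_c", "tgt_c"),
    compartment = "c",
    formula = "C3H6O3", charge = 0)
  rxns <- list(
    list(id = "EX_src", stoichiometry = c(src_c = -1), lb = -5, ub = 1000,
         subsystem = "exchange"),
    list(id = "UP1", stoichiometry = c(src_c = -1, a_c = 1), lb = 0,
         ub = 1000),
    list(id = "UP2", stoichiometry = c(src_c = -1, b_c = 1), lb = 0,
         ub = 1000),
    list(id = "DOWN1", stoichiometry = c(a_c = -1, tgt_c = 1), lb = 0,
         ub = 1000),
    list(id = "DOWN2", stoichiometry = c(b_c = -1, tgt_c = 1), lb = 0,
         ub = 1000))
  m <- metabolic_model(mets, rxns, medium = c(EX_src = 5), id = "diamond")
  m <- add_target_sinks(m, "tgt_c")
  list(model = m,
       partition = define_core(m, character(0),
                               extra_core_metabolites = "src_c",
                               gate_transports = FALSE))
}

# a model whose target has no producing reaction at all
blocked_model <- function() {
  mets <- data.frame(id = c("src_c", "stranded_c"), compartment = "c",
                     formula = "C3H6O3", charge = 0)
  rxns <- list(
    list(id = "EX_src", stoichiometry = c(src_c = -1), lb = -5, ub = 1000,
         subsystem = "exchange"))
  m <- metabolic_model(mets, rxns, medium = c(EX_src = 5), id = "blocked")
  m <- add_target_sinks(m, "stranded_c")
  list(model = m,
       partition = define_core(m, character(0), gate_transports = FALSE))
}

# the toy-spec battery used by the oracle-equivalence acceptance test:
# varied route layouts, balancer counts and decoys, all with <= 14 non-core
# reactions
acceptance_specs <- function(n = 50) {
  layouts <- list(
    list(paths = list(list(c(3, 2))), nb = 1, dead = 2, extra = FALSE),
    list(paths = list(list(c(2, 2))), nb = 2, dead = 2, extra = TRUE),
    list(paths = list(list(c(4, 1))), nb = 1, dead = 1, extra = TRUE),
    list(paths = list(list(c(1, 3))), nb = 0, dead = 2, extra = FALSE),
    list(paths = list(list(c(2, 1)), list(c(2, 1))), nb = 1, dead = 1,
         extra = FALSE))
  lapply(seq_len(n), function(k) {
    ly <- layouts[[(k - 1) %% length(layouts) + 1]]
    toy_spec(n_core_reactions = 2 + k %% 3,
             planted_paths = ly$paths,
             branch_balancers = ly$nb,
             n_dead_ends = ly$dead,
             extra_path = ly$extra,
             distinct_cofactors = k %% 2 == 0,
             seed = 1000L + k)
  })
}

expect_same_sets <- function(got, want) {
  got <- lapply(got, sort); want <- lapply(want, sort)
  expect_equal(length(got), length(want))
  for (s in want) {
    expect_true(any(vapply(got, identical, logical(1), y = s)),
                label = paste("set", paste(s, collapse = "+"), "found"))
  }
}
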