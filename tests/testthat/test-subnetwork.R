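test_that("a planted unique route is recovered exactly", {
  toy <- make_toy_gem(toy_spec(planted_paths = list(list(c(3, 1))),
                               seed = 101), certify = FALSE)
  gt <- toy$ground_truth[[1]]
  sg <- split_and_gate(toy$model, toy$partition)
  sn <- find_min_subnetwork(subnetwork_problem(sg, gt$sink_id, gt$demand))
  expect_equal(sn$size, gt$smin)
  expect_equal(sn$reactions, gt$minimal_sets[[1]])
  # oracle agrees
  oracle <- brute_force_min_subnetworks(toy$model, toy$partition,
                                        gt$sink_id, gt$demand)
  expect_same_sets(oracle, gt$minimal_sets)
  # reported metabolites are the species the reactions touch
  jj <- match(sn$reactions, toy$model$rxns$id)
  expect_setequal(sn$metabolites, toy$model$mets$id[
    Matrix::rowSums(abs(toy$model$S[, jj, drop = FALSE])) > 0])
})

test_that("a core-producible target needs an empty subnetwork", {
  toy <- make_toy_gem(toy_spec(seed = 55), certify = FALSE)
  m <- add_target_sinks(toy$model, "pre_c")   # the core precursor itself
  pt <- define_core(m, toy$partition$core_reactions,
                    gate_transports = FALSE)
  sg <- split_and_gate(m, pt)
  sn <- find_min_subnetwork(subnetwork_problem(sg, "sink_pre_c", 1))
  expect_equal(sn$size, 0)
  expect_length(sn$reactions, 0)
  expect_true(verify_subnetwork(m, pt, sn, check_minimality = TRUE))
})

test_that("two disjoint equal routes give exactly two alternatives", {
  dm <- diamond_model()
  sg <- split_and_gate(dm$model, dm$partition)
  pr <- subnetwork_problem(sg, "sink_tgt_c", 1)
  alts <- enumerate_alternatives(pr, mode = "minimal-only")
  expect_length(alts, 2)
  expect_same_sets(lapply(alts, function(s) s$reactions),
                   list(c("DOWN1", "UP1"), c("DOWN2", "UP2")))
  expect_false(attr(alts, "truncated"))
  # the brute-force oracle returns the same two 2-sets
  oracle <- brute_force_min_subnetworks(dm$model, dm$partition,
                                        "sink_tgt_c", 1)
  expect_equal(attr(oracle, "smin"), 2)
  expect_same_sets(oracle, lapply(alts, function(s) s$reactions))
})

test_that("max_count = 1 returns only the first minimal solution", {
  dm <- diamond_model()
  sg <- split_and_gate(dm$model, dm$partition)
  pr <- subnetwork_problem(sg, "sink_tgt_c", 1)
  one <- enumerate_alternatives(pr, max_count = 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$size, 2)
  expect_true(attr(one, "truncated"))
})

test_that("up-to-size mode also reports longer subnetworks", {
  toy <- make_toy_gem(toy_spec(planted_paths = list(list(c(2, 1))),
                               extra_path = TRUE, branch_balancers = 0,
                               n_dead_ends = 0, seed = 77), certify = FALSE)
  gt <- toy$ground_truth[[1]]
  sg <- split_and_gate(toy$model, toy$partition)
  pr <- subnetwork_problem(sg, gt$sink_id, gt$demand)
  minimal <- enumerate_alternatives(pr, mode = "minimal-only")
  expect_length(minimal, 1)
  wider <- enumerate_alternatives(pr, mode = "up-to-size",
                                  size_cap = gt$smin + 1)
  expect_length(wider, 2)          # the planted route plus the longer decoy
  expect_equal(vapply(wider, function(s) s$size, numeric(1)),
               c(gt$smin, gt$smin + 1))
})

test_that("a target with no producer raises a blocked-target condition", {
  bm <- blocked_model()
  sg <- split_and_gate(bm$model, bm$partition, carbon_cap = 100)
  pr <- subnetwork_problem(sg, "sink_stranded_c", 1)
  expect_error(find_min_subnetwork(pr), class = "lumpnet_blocked_target")
  expect_error(enumerate_alternatives(pr),
               class = "lumpnet_blocked_target")
  expect_error(
    brute_force_min_subnetworks(bm$model, bm$partition, "sink_stranded_c",
                                1),
    class = "lumpnet_blocked_target")
})

test_that("verification detects both incomplete and padded subnetworks", {
  toy <- make_toy_gem(toy_spec(planted_paths = list(list(c(3, 1))),
                               seed = 19), certify = FALSE)
  gt <- toy$ground_truth[[1]]
  sg <- split_and_gate(toy$model, toy$partition)
  sn <- find_min_subnetwork(subnetwork_problem(sg, gt$sink_id, gt$demand))
  expect_true(verify_subnetwork(toy$model, toy$partition, sn,
                                check_minimality = TRUE))
  # dropping the balancer (the Fig-2-style branch) breaks feasibility
  crippled <- sn
  crippled$reactions <- setdiff(sn$reactions, "BAL1")
  expect_false(verify_subnetwork(toy$model, toy$partition, crippled))
  # padding with a decoy keeps feasibility but loses minimality
  padded <- sn
  padded$reactions <- c(sn$reactions, "DEAD1")
  expect_true(verify_subnetwork(toy$model, toy$partition, padded))
  expect_false(verify_subnetwork(toy$model, toy$partition, padded,
                                 check_minimality = TRUE))
})

test_that("enlarging the core never increases the minimal size", {
  for (seed in c(3, 14, 27)) {
    toy <- make_toy_gem(toy_spec(seed = seed), certify = FALSE)
    gt <- toy$ground_truth[[1]]
    sg <- split_and_gate(toy$model, toy$partition)
    s0 <- find_min_subnetwork(
      subnetwork_problem(sg, gt$sink_id, gt$demand))$size
    # promote one subnetwork reaction into the core
    promoted <- union(toy$partition$core_reactions,
                      gt$minimal_sets[[1]][1])
    pt2 <- define_core(toy$model, promoted, gate_transports = FALSE)
    sg2 <- split_and_gate(toy$model, pt2)
    s1 <- find_min_subnetwork(
      subnetwork_problem(sg2, gt$sink_id, gt$demand))$size
    expect_lte(s1, s0)
  }
})
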