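# Parameterized toy models with planted cores, planted minimal subnetworks,
# and exact synthetic chemistry, plus the exhaustive brute-force oracle that
# certifies MILP and lumping output at desk scale.
#
# Construction guarantees elemental balance: every planted path carries the
# precursor's formula forward, shedding side-metabolite formulas (and H2 to a
# cofactor) along the way, so each reaction balances by integer atom
# bookkeeping and the target's formula is determined by conservation.
# Side metabolites emitted along a path cannot be balanced by the core
# directly; a dedicated isomerizing "balancer" reaction converts each to a
# secretable core twin, forcing branched (non-linear) minimal subnetworks.

#' Specification of a toy model
#'
#' @param n_core_reactions Length of the linear core chain from the carbon
#'   source to the precursor.
#' @param planted_paths Per-target path layout: a list with one element per
#'   target, each a list of `c(length, count)` pairs.  The default plants a
#'   single target with two disjoint 3-step routes.
#' @param branch_balancers Number of side metabolites every route emits at
#'   its first step; each needs its balancer reaction in any feasible
#'   subnetwork.
#' @param n_dead_ends Decoy reactions into dead-end metabolites (never able
#'   to carry steady-state flux).
#' @param extra_path Plant one additional longer (non-minimal) route per
#'   target.
#' @param distinct_cofactors Alternate NAD/NADP-style cofactor pairs between
#'   a target's routes, so alternative subnetworks yield distinct lumps.
#' @param with_biomass Add a biomass reaction consuming all targets.
#' @param uptake Carbon-source uptake bound (mmol/gDW/h).
#' @param element_palette Elements available for synthetic side-metabolite
#'   formulas.
#' @param seed Integer; fully determines the generated model.
#' @return A `toy_spec`.
#' @export
toy_spec <- function(n_core_reactions = 3,
                     planted_paths = list(list(c(3, 2))),
                     branch_balancers = 1,
                     n_dead_ends = 2,
                     extra_path = FALSE,
                     distinct_cofactors = FALSE,
                     with_biomass = TRUE,
                     uptake = 10,
                     element_palette = c("C", "H", "O", "N"),
                     seed = 1L) {
  stopifnot(n_core_reactions >= 1, branch_balancers >= 0, uptake > 0)
  structure(list(n_core_reactions = n_core_reactions,
                 planted_paths = planted_paths,
                 branch_balancers = branch_balancers,
                 n_dead_ends = n_dead_ends,
                 extra_path = extra_path,
                 distinct_cofactors = distinct_cofactors,
                 with_biomass = with_biomass,
                 uptake = uptake,
                 element_palette = element_palette,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

#' @noRd
.comp_plus <- function(a, b) {
  for (e in names(b)) a[e] <- (if (e %in% names(a)) a[[e]] else 0) + b[[e]]
  a
}

#' @noRd
.comp_minus <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- stats::setNames(rep(0, length(keys)), keys); av[names(a)] <- a
  av[names(b)] <- av[names(b)] - b
  if (any(av < 0)) stop("toy generation error: side groups exceed the ",
                        "precursor formula (target would be blocked)")
  av[av > 0]
}

#' Generate a toy model with planted ground truth
#'
#' Builds a model from a [toy_spec()]: a linear core from a glucose-like
#' source to a precursor, cofactor-regeneration and secretion reactions in
#' the core, and per target several disjoint non-core routes plus shared
#' balancer reactions and decoys.  The minimal subnetworks and the lump of
#' each route are known by construction; with `certify = TRUE` they are
#' re-verified against the brute-force oracle before the fixture is emitted.
#'
#' @param spec A `toy_spec`.
#' @param certify Re-verify the planted ground truth with
#'   [brute_force_min_subnetworks()] (slower; generation fails loudly on any
#'   disagreement).
#' @return List with `model` (sink-augmented), `partition`, `mu_max`, and
#'   `ground_truth`: per target a list with `sink_id`, `demand`, `smin`,
#'   `minimal_sets` (list of reaction-id vectors) and `lumps` (named
#'   stoichiometries, one per route).
#' @export
make_toy_gem <- function(spec, certify = TRUE) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  src_comp <- c(C = 6, H = 12, O = 6)
  mets <- list(list(id = "src_c", name = "carbon source", compartment = "c",
                    formula = formula_string(src_comp), charge = 0))
  rxns <- list(list(id = "EX_src", stoichiometry = c(src_c = -1),
                    lb = -spec$uptake, ub = 1000, subsystem = "exchange"))
  add_met <- function(id, comp, name = id) {
    mets[[length(mets) + 1L]] <<- list(id = id, name = name,
                                       compartment = "c",
                                       formula = formula_string(comp),
                                       charge = 0)
  }
  add_rxn <- function(id, st, lb = 0, ub = 1000, subsystem = "toy") {
    rxns[[length(rxns) + 1L]] <<- list(id = id, stoichiometry = st,
                                       lb = lb, ub = ub,
                                       subsystem = subsystem)
  }
  # core chain src -> ... -> pre (iso-formula)
  chain <- c(paste0("ccm", seq_len(spec$n_core_reactions - 1)), "pre_c")
  prev <- "src_c"
  core_rxns <- character(0)
  for (k in seq_along(chain)) {
    add_met(chain[k], src_comp)
    rid <- sprintf("CORE%d", k)
    add_rxn(rid, stats::setNames(c(-1, 1), c(prev, chain[k])),
            lb = -1000, subsystem = "core chain")
    core_rxns <- c(core_rxns, rid)
    prev <- chain[k]
  }
  # cofactor pairs: reduced form carries two extra hydrogens
  cof_base <- list(nad = c(C = 10, H = 12, N = 2, O = 6),
                   nadp = c(C = 10, H = 12, N = 2, O = 9))
  for (cf in names(cof_base)) {
    add_met(paste0(cf, "_c"), cof_base[[cf]])
    add_met(paste0(cf, "h_c"), .comp_plus(cof_base[[cf]], c(H = 2)))
  }
  add_met("h2_c", c(H = 2))
  add_rxn("NADH_OX", c(nadh_c = -1, nad_c = 1, h2_c = 1),
          subsystem = "cofactor regeneration")
  add_rxn("NADPH_OX", c(nadph_c = -1, nadp_c = 1, h2_c = 1),
          subsystem = "cofactor regeneration")
  add_rxn("EX_h2", c(h2_c = -1), lb = 0, subsystem = "exchange")
  core_rxns <- c(core_rxns, "NADH_OX", "NADPH_OX")
  # shared side metabolites, their core twins and balancer reactions;
  # side groups may only draw from the source's own elements
  nb <- spec$branch_balancers
  side_ids <- character(0); balancers <- character(0)
  side_comps <- list()
  side_total <- stats::setNames(numeric(0), character(0))
  pal <- intersect(spec$element_palette, names(src_comp))
  for (b in seq_len(nb)) {
    repeat {
      comp <- c(C = sample(0:1, 1), H = sample(0:2, 1) * 2,
                O = sample(0:1, 1))
      comp <- comp[comp > 0 & names(comp) %in% pal]
      if (length(comp)) break
    }
    wid <- sprintf("w%d_c", b); twin <- sprintf("w%dsec_c", b)
    add_met(wid, comp); add_met(twin, comp)
    add_rxn(sprintf("BAL%d", b), stats::setNames(c(-1, 1), c(wid, twin)),
            subsystem = "balancer")
    add_rxn(sprintf("EX_w%d", b), stats::setNames(-1, twin), lb = 0,
            subsystem = "exchange")
    side_ids <- c(side_ids, wid)
    side_comps[[wid]] <- comp
    balancers <- c(balancers, sprintf("BAL%d", b))
    for (e in names(comp)) {
      side_total[e] <- (if (e %in% names(side_total)) side_total[[e]]
                        else 0) + comp[[e]]
    }
  }
  # planted routes per target
  targets <- sprintf("bbb%d_c", seq_along(spec$planted_paths))
  truth <- list()
  for (t in seq_along(spec$planted_paths)) {
    pairs <- spec$planted_paths[[t]]
    lens <- unlist(lapply(pairs, function(p) rep(p[1], p[2])))
    if (spec$extra_path) lens <- c(lens, max(lens) + 1L)
    use_redox <- all(lens >= 2)
    t_comp <- .comp_minus(src_comp, side_total)
    if (use_redox) t_comp <- .comp_minus(t_comp, c(H = 2))
    add_met(targets[t], t_comp, name = sprintf("building block %d", t))
    route_sets <- list(); route_lumps <- list()
    for (p in seq_along(lens)) {
      L <- lens[p]
      cof <- if (spec$distinct_cofactors && p %% 2 == 0) "nadp" else "nad"
      ids <- character(0)
      cur <- "pre_c"
      cur_comp <- src_comp
      for (s in seq_len(L)) {
        last <- s == L
        nxt_comp <- cur_comp
        st <- stats::setNames(-1, cur)
        if (s == 1 && nb > 0) {          # shed all side groups at step 1
          for (wid in side_ids) {
            st[wid] <- 1
            nxt_comp <- .comp_minus(nxt_comp, side_comps[[wid]])
          }
        }
        if (s == min(2, L) && use_redox && s > 1) {   # redox step
          st[paste0(cof, "_c")] <- -1
          st[paste0(cof, "h_c")] <- 1
          nxt_comp <- .comp_minus(nxt_comp, c(H = 2))
        }
        nxt <- if (last) targets[t] else sprintf("x_t%d_p%d_%d_c", t, p, s)
        if (!last) add_met(nxt, nxt_comp)
        st[nxt] <- 1
        rid <- sprintf("PATH_t%d_p%d_s%d", t, p, s)
        add_rxn(rid, st, subsystem = "planted route")
        ids <- c(ids, rid)
        cur <- nxt; cur_comp <- nxt_comp
      }
      route_sets[[p]] <- sort(c(ids, balancers))
      lump <- stats::setNames(-1, "pre_c")
      for (wid in side_ids) lump[sub("_c$", "sec_c", wid)] <- 1
      if (use_redox) {
        lump[paste0(cof, "_c")] <- -1
        lump[paste0(cof, "h_c")] <- 1
      }
      lump[targets[t]] <- 1
      route_lumps[[p]] <- lump
    }
    smin <- min(lens) + nb
    keep <- which(lens + nb == smin)
    truth[[targets[t]]] <- list(
      sink_id = paste0("sink_", targets[t]),
      smin = smin,
      minimal_sets = route_sets[keep],
      lumps = route_lumps[keep])
  }
  # decoys: dead-end consumers of the precursor
  for (d in seq_len(spec$n_dead_ends)) {
    did <- sprintf("dead%d_c", d)
    add_met(did, src_comp)
    add_rxn(sprintf("DEAD%d", d), stats::setNames(c(-1, 1), c("pre_c", did)),
            subsystem = "dead end")
  }
  biomass_id <- NA_character_
  if (spec$with_biomass) {
    nj <- stats::setNames(sample(c(0.5, 1, 1.5, 2), length(targets),
                                 replace = TRUE), targets)
    add_rxn("Biomass", -nj, subsystem = "biomass")
    biomass_id <- "Biomass"
  }
  model <- metabolic_model(
    do.call(rbind, lapply(mets, as.data.frame)), rxns,
    objective = biomass_id,
    medium = c(EX_src = spec$uptake),
    id = sprintf("toy_seed%d", spec$seed))
  mu_max <- if (spec$with_biomass) fba(model)$objective_value else NA_real_
  model <- add_target_sinks(model, targets)
  partition <- define_core(model, core_rxns, gate_transports = FALSE)
  for (t in targets) {
    nj_t <- if (spec$with_biomass) {
      abs(reaction_stoich(model, "Biomass")[[t]])
    } else 1
    truth[[t]]$demand <- if (spec$with_biomass) nj_t * mu_max else 1e-3
  }
  out <- list(model = model, partition = partition, mu_max = mu_max,
              ground_truth = truth, spec = spec)
  if (certify) .certify_toy(out)
  out
}

#' @noRd
.certify_toy <- function(toy) {
  for (t in names(toy$ground_truth)) {
    gt <- toy$ground_truth[[t]]
    oracle <- brute_force_min_subnetworks(
      toy$model, toy$partition, gt$sink_id, gt$demand,
      max_size = gt$smin)
    found <- lapply(oracle, sort)
    planted <- gt$minimal_sets
    same <- length(found) == length(planted) &&
      all(vapply(planted, function(s) {
        any(vapply(found, identical, logical(1), y = s))
      }, logical(1)))
    if (!same) {
      stop(sprintf("toy certification failed for '%s': planted %d sets, %s",
                   t, length(planted),
                   sprintf("oracle found %d", length(found))))
    }
  }
  invisible(toy)
}

#' Exhaustive oracle: all minimum-cardinality feasible subnetworks
#'
#' Enumerates subsets of the non-core reactions by increasing cardinality and
#' tests each by LP feasibility (core + always-on + subset + target drain at
#' the demanded flux), stopping at the first cardinality admitting a feasible
#' subset.  At that cardinality every feasible subset is inclusion-minimal,
#' so the result is exactly the collection the gating MILP should find in
#' minimal-only mode.  Independent of the MILP code path.
#'
#' @param model Sink-augmented `metabolic_model`.
#' @param partition A `core_partition` with at most ~20 non-core reactions.
#' @param target_sink_id The target's drain.
#' @param demand Required drain flux.
#' @param max_size Largest cardinality to try (default: all non-core).
#' @return List of sorted reaction-id vectors; `attr(, "smin")` holds the
#'   minimum size.  Raises `lumpnet_blocked_target` if nothing feasible up
#'   to `max_size`.
#' @export
brute_force_min_subnetworks <- function(model, partition, target_sink_id,
                                        demand,
                                        max_size = NULL) {
  gated <- partition$noncore_reactions
  max_size <- min(max_size %||% length(gated), length(gated))
  p <- .lp_base(model)
  p$c <- rep(0, n_reactions(model))
  # demand the target, close the other drains
  js <- match(target_sink_id, model$rxns$id)
  if (is.na(js)) stop(sprintf("drain '%s' not in model", target_sink_id))
  p$lb[js] <- demand
  for (r in setdiff(.drain_ids(model), target_sink_id)) {
    j <- match(r, model$rxns$id)
    p$lb[j] <- 0; p$ub[j] <- 0
  }
  gj <- match(gated, model$rxns$id)
  for (size in 0:max_size) {
    subsets <- if (size == 0) list(integer(0)) else
      utils::combn(length(gated), size, simplify = FALSE)
    variants <- lapply(subsets, function(sel) {
      closed <- gj[setdiff(seq_along(gated), sel)]
      list(bidx = closed, blb = rep(0, length(closed)),
           bub = rep(0, length(closed)), want_x = FALSE)
    })
    feas <- logical(length(variants))
    chunk <- 2000L
    for (start in seq(1, length(variants), by = chunk)) {
      idx <- start:min(start + chunk - 1L, length(variants))
      pp <- p; pp$mode <- "batch"; pp$variants <- variants[idx]
      sols <- solve_problems(list(pp))[[1]]$solutions
      feas[idx] <- vapply(sols, function(s) s$status == "optimal",
                          logical(1))
    }
    if (any(feas)) {
      out <- lapply(subsets[feas], function(sel) sort(gated[sel]))
      attr(out, "smin") <- size
      return(out)
    }
  }
  stop(errorCondition(
    sprintf("target drain '%s' infeasible with up to %d non-core reactions",
            target_sink_id, max_size),
    class = "lumpnet_blocked_target"))
}

#' Two-route yield fixture with hand-derivable carbon yields
#'
#' A small model built for yield ranking: one 6-carbon target reachable by
#' two single-reaction routes from different core precursors.  Route A uses a
#' 7-carbon precursor (core converts 7 source molecules into 6 of it) and
#' loses one CH2O per target: C-mol yield 6/7.  Route B uses an 8-carbon
#' precursor and loses two CH2O: yield 6/8.  Both values follow from carbon
#' conservation alone.
#'
#' @param uptake Source uptake bound.
#' @return List with `model` (sink-augmented), `partition`, `target`,
#'   `source`, and `expected_yields` (named: route A, route B).
#' @export
make_yield_toy <- function(uptake = 7) {
  comp6 <- c(C = 6, H = 12, O = 6)
  mets <- list(
    list(id = "src_c", name = "source", compartment = "c",
         formula = formula_string(comp6), charge = 0),
    list(id = "preA_c", name = "7C precursor", compartment = "c",
         formula = "C7H14O7", charge = 0),
    list(id = "preB_c", name = "8C precursor", compartment = "c",
         formula = "C8H16O8", charge = 0),
    list(id = "w_c", name = "1C by-product", compartment = "c",
         formula = "CH2O", charge = 0),
    list(id = "bbb1_c", name = "6C target", compartment = "c",
         formula = formula_string(comp6), charge = 0))
  rxns <- list(
    list(id = "EX_src", stoichiometry = c(src_c = -1), lb = -uptake,
         ub = 1000, subsystem = "exchange"),
    list(id = "COREA", stoichiometry = c(src_c = -7, preA_c = 6),
         lb = 0, ub = 1000, subsystem = "core"),
    list(id = "COREB", stoichiometry = c(src_c = -4, preB_c = 3),
         lb = 0, ub = 1000, subsystem = "core"),
    list(id = "EX_w", stoichiometry = c(w_c = -1), lb = 0, ub = 1000,
         subsystem = "exchange"),
    list(id = "ROUTEA", stoichiometry = c(preA_c = -1, bbb1_c = 1, w_c = 1),
         lb = 0, ub = 1000, subsystem = "route"),
    list(id = "ROUTEB", stoichiometry = c(preB_c = -1, bbb1_c = 1, w_c = 2),
         lb = 0, ub = 1000, subsystem = "route"))
  model <- metabolic_model(do.call(rbind, lapply(mets, as.data.frame)), rxns,
                           medium = c(EX_src = uptake), id = "yield_toy")
  model <- add_target_sinks(model, "bbb1_c")
  partition <- define_core(model, c("COREA", "COREB"),
                           extra_core_metabolites = "w_c",
                           gate_transports = FALSE)
  list(model = model, partition = partition,
       target = "bbb1_c", source = "src_c",
       expected_yields = c(A = 6 / 7, B = 6 / 8))
}
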