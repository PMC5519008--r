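# Reduced-model assembly: core + lumped reactions + the parent model's
# transports/exchanges/sinks over the retained species + biomass.  A second
# MILP fixes the maximal biomass yield of the candidate model and minimizes
# the number of active lumps, discarding redundant alternatives.

#' Assemble the candidate reduced model from all lumps
#'
#' @param model The parent `metabolic_model` (with biomass reaction).
#' @param partition A `core_partition`.
#' @param lumps List of (deduplicated) `lumped_reaction`s.
#' @param biomass_id Biomass reaction id (default: model objective).
#' @param include_sinks Which parent-model boundary sinks/demands to carry
#'   over: `"auto"` keeps every one whose species is retained.
#' @return A `metabolic_model` comprising the core reactions, all lumps, the
#'   parent's transport and exchange reactions that touch only retained
#'   species, and the biomass reaction, with the parent's objective.
#' @export
assemble_candidate_model <- function(model, partition, lumps,
                                     biomass_id = model$objective,
                                     include_sinks = "auto") {
  if (is.na(biomass_id) || !biomass_id %in% model$rxns$id) {
    stop("candidate model needs a biomass reaction")
  }
  lump_species <- unique(unlist(lapply(lumps, function(l) {
    names(l$stoichiometry)
  })))
  biomass_species <- names(reaction_stoich(model, biomass_id))
  species <- unique(c(partition$core_metabolites, lump_species,
                      biomass_species))
  boundary <- model$rxns$id[is_exchange(model) | is_transport(model)]
  boundary <- setdiff(boundary, .drain_ids(model))
  if (!identical(include_sinks, "auto")) {
    boundary <- setdiff(boundary, setdiff(.drain_ids(model), include_sinks))
  }
  b_keep <- boundary[vapply(boundary, function(r) {
    all(names(reaction_stoich(model, r)) %in% species)
  }, logical(1))]
  keep <- unique(c(partition$core_reactions, b_keep, biomass_id))
  cand <- subset_model(model, keep, keep_objective = FALSE)
  # lump columns may reference species outside the kept reactions
  missing_mets <- setdiff(intersect(species, model$mets$id), cand$mets$id)
  if (length(missing_mets)) {
    cand$mets <- rbind(cand$mets,
                       model$mets[match(missing_mets, model$mets$id), ])
    cand$S <- rbind(cand$S, Matrix::Matrix(0, length(missing_mets),
                                           n_reactions(cand), sparse = TRUE))
    rownames(cand$S) <- cand$mets$id
  }
  lump_rxns <- lapply(seq_along(lumps), function(k) {
    list(id = sprintf("LUMP_%s_%d", lumps[[k]]$target_id, k),
         stoichiometry = lumps[[k]]$stoichiometry,
         lb = 0, ub = Inf, subsystem = "lumped reaction")
  })
  cand <- add_reactions(cand, lump_rxns)
  cand$objective <- biomass_id
  # every biomass substrate needs a producer among the kept reactions
  bio <- reaction_stoich(cand, biomass_id)
  orphans <- Filter(function(m) {
    row <- cand$S[match(m, cand$mets$id), ]
    prod <- sum(row > 0) - (bio[[m]] > 0)
    prod == 0
  }, names(bio)[bio < 0])
  if (length(orphans)) {
    stop("biomass species without any producer in the candidate model: ",
         paste(unlist(orphans), collapse = ", "))
  }
  cand$medium <- model$medium
  cand
}

#' Select a minimal set of lumps at fixed maximal biomass yield
#'
#' Computes the candidate model's maximal growth `mu*` by FBA, fixes
#' `v_biomass >= mu* (1 - 1e-6)`, gates every lump with a binary (as in the
#' subnetwork MILP), and maximizes the number of closed gates.  The returned
#' model keeps only the selected lumps and re-attains
#' `mu >= mu* (1 - 1e-4)`.
#'
#' @param candidate Candidate model from [assemble_candidate_model()].
#' @param lumps The lump list used to build it (for provenance).
#' @param carbon_cap Gating constant; default [default_carbon_cap()].
#' @return A `reduced_model`: `model`, `selected_lumps`, `mu_at_medium`,
#'   `mu_candidate`.
#' @export
select_minimal_lump_set <- function(candidate, lumps, carbon_cap = NULL) {
  opt <- fba(candidate)
  if (opt$status != "optimal" || opt$objective_value <= 0) {
    stop("candidate model does not grow; cannot select lumps")
  }
  mu_star <- opt$objective_value
  if (is.null(carbon_cap)) carbon_cap <- default_carbon_cap(candidate)
  lump_ids <- grep("^LUMP_", candidate$rxns$id, value = TRUE)
  n <- n_reactions(candidate)
  g <- length(lump_ids)
  jj <- match(lump_ids, candidate$rxns$id)
  A <- cbind(candidate$S, Matrix::Matrix(0, n_metabolites(candidate), g,
                                         sparse = TRUE))
  gate <- Matrix::sparseMatrix(
    i = rep(seq_len(g), 2), j = c(jj, n + seq_len(g)),
    x = c(rep(1, g), rep(carbon_cap, g)), dims = c(g, n + g))
  p <- list(
    A = rbind(A, gate),
    rlb = c(rep(0, n_metabolites(candidate)), rep(-Inf, g)),
    rub = c(rep(0, n_metabolites(candidate)), rep(carbon_cap, g)),
    lb = c(candidate$rxns$lb, rep(0, g)),
    ub = c(pmin(candidate$rxns$ub, ifelse(seq_len(n) %in% jj, carbon_cap,
                                          Inf)),
           rep(1, g)),
    integrality = c(rep(0L, n), rep(1L, g)),
    c = c(rep(0, n), rep(1, g)), sense = "max")
  jb <- match(candidate$objective, candidate$rxns$id)
  p$lb[jb] <- max(p$lb[jb], mu_star * (1 - 1e-6))
  sol <- solve_single(p)
  if (sol$status != "optimal") {
    stop("lump-selection MILP infeasible at the fixed biomass yield; ",
         "try relaxing the yield tolerance")
  }
  x <- as.numeric(sol$x)
  sel <- lump_ids[x[n + seq_len(g)] < 0.5]
  reduced <- subset_model(candidate,
                          setdiff(candidate$rxns$id,
                                  setdiff(lump_ids, sel)))
  reduced$objective <- candidate$objective
  mu_red <- fba(reduced)$objective_value
  if (is.na(mu_red) || mu_red < mu_star * (1 - 1e-4)) {
    stop("reduced model fails to re-attain the fixed biomass yield")
  }
  sel_idx <- as.integer(sub("^LUMP_.*_(\\d+)$", "\\1", sel))
  structure(list(model = reduced,
                 selected_lumps = lumps[sel_idx],
                 selected_ids = sel,
                 mu_candidate = mu_star,
                 mu_at_medium = mu_red),
            class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  cat(sprintf(paste0("<reduced_model: %d reactions, %d selected lump(s), ",
                     "mu = %.4g/h>\n"),
              n_reactions(x$model), length(x$selected_lumps),
              x$mu_at_medium))
  invisible(x)
}

#' Maximal growth rate of a reduced model at a medium
#'
#' @param reduced A `reduced_model` (or plain `metabolic_model`).
#' @param medium Optional named uptake vector applied via [set_medium()].
#' @return Specific growth rate (1/h); also stored in `mu_at_medium` when a
#'   `reduced_model` is given.
#' @export
validate_growth <- function(reduced, medium = NULL) {
  model <- if (inherits(reduced, "reduced_model")) reduced$model else reduced
  if (!is.null(medium)) model <- set_medium(model, medium)
  mu <- fba(model)$objective_value
  if (inherits(reduced, "reduced_model")) reduced$mu_at_medium <- mu
  mu
}
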