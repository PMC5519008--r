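#' Define the core / non-core partition of a model
#'
#' The core (`R_core` with its metabolite set `M_core`) is the user-selected
#' subsystem — classically glycolysis, pentose phosphate pathway, TCA cycle,
#' by-product formation and part of the electron transport chain — whose
#' metabolites act as the allowed precursor pool.  Everything else is
#' non-core and subject to binary gating, except reactions in `always_on`
#' (never gated, never counted in a subnetwork).
#'
#' @param model A `metabolic_model`.
#' @param core_reactions Character vector of reaction ids forming the core.
#' @param extra_core_metabolites Metabolite ids added to `M_core` even if no
#'   core reaction touches them (cofactor pairs, inorganics).
#' @param gate_transports When `FALSE`, boundary exchange reactions are
#'   exempted from gating (placed in `always_on`).  Inter-compartment
#'   transports remain gated either way: compartmentalized models treat them
#'   like single enzymatic reactions.
#' @param always_on Additional reaction ids exempt from gating (e.g. the
#'   biomass reaction or maintenance demands).
#' @return A `core_partition` object with fields `core_reactions`,
#'   `noncore_reactions`, `always_on`, `core_metabolites`,
#'   `noncore_metabolites`.
#' @export
define_core <- function(model, core_reactions,
                        extra_core_metabolites = character(),
                        gate_transports = TRUE,
                        always_on = character()) {
  stopifnot_rxns(model, core_reactions, "core reaction")
  stopifnot_rxns(model, always_on, "always-on reaction")
  stopifnot_mets(model, extra_core_metabolites)
  if (!gate_transports) {
    always_on <- union(always_on, model$rxns$id[is_exchange(model)])
  }
  # target drains and the biomass objective are problem artifacts, not
  # members of R_ncGEM: never gate them
  drains <- model$rxns$id[model$rxns$subsystem %in%
                            c("target drain", "composite demand")]
  always_on <- union(always_on, drains)
  if (!is.na(model$objective)) {
    always_on <- union(always_on, model$objective)
  }
  core_reactions <- setdiff(core_reactions, always_on)
  noncore <- setdiff(model$rxns$id, union(core_reactions, always_on))
  jj <- match(core_reactions, model$rxns$id)
  touched <- if (length(jj)) {
    model$mets$id[Matrix::rowSums(abs(model$S[, jj, drop = FALSE])) > 0]
  } else character(0)
  core_mets <- union(touched, extra_core_metabolites)
  structure(list(
    core_reactions = core_reactions,
    noncore_reactions = noncore,
    always_on = always_on,
    core_metabolites = core_mets,
    noncore_metabolites = setdiff(model$mets$id, core_mets)
  ), class = "core_partition")
}

#' @export
print.core_partition <- function(x, ...) {
  cat(sprintf(paste0("<core_partition: %d core / %d non-core reactions ",
                     "(%d always-on); %d core metabolites>\n"),
              length(x$core_reactions), length(x$noncore_reactions),
              length(x$always_on), length(x$core_metabolites)))
  invisible(x)
}

#' Default flux-scale constant for binary gating
#'
#' The gating constraint `F + B + C z <= C` needs a constant `C` at least as
#' large as any feasible single-reaction flux.  With a single bounded carbon
#' source the tightest valid choice is (carbon atoms of the source) x (its
#' uptake bound) — total carbon-atom influx bounds every carbon-carrying
#' flux; with multiple or unbounded carbon sources an arbitrary big constant
#' stands in.
#'
#' @param model A `metabolic_model`.
#' @param big_m Fallback constant (default 1000).
#' @return A positive scalar.
#' @export
default_carbon_cap <- function(model, big_m = 1000) {
  ex <- which(is_exchange(model) & model$rxns$lb < 0)
  carbons <- vapply(ex, function(j) {
    met <- names(reaction_stoich(model, model$rxns$id[j]))
    comp <- tryCatch(parse_formula(model$mets$formula[match(met, model$mets$id)]),
                     error = function(e) numeric(0))
    if ("C" %in% names(comp)) comp[["C"]] else 0
  }, numeric(1))
  carbon_sources <- ex[carbons > 0]
  if (length(carbon_sources) != 1) return(big_m)
  lbv <- model$rxns$lb[carbon_sources]
  if (!is.finite(lbv)) return(big_m)
  unname(carbons[carbons > 0] * (-lbv))
}

#' Split reactions into forward/backward parts and attach binary gates
#'
#' Every reaction `i` is split as `v_i = F_i - B_i` with `F_i, B_i >= 0`
#' (irreversible reactions get `B_i = 0`).  Every non-core reaction gets a
#' binary `z_i` and the gating constraint `F_i + B_i + C z_i <= C`: `z_i = 1`
#' forces the reaction off in both directions, `z_i = 0` relaxes it to the
#' flux cap `C`.  Gating is direction-unbiased by construction.
#'
#' @param model A `metabolic_model`.
#' @param partition A `core_partition`.
#' @param carbon_cap The constant `C`; default [default_carbon_cap()].
#' @return A `split_gated_model`: the MILP skeleton (constraint matrix,
#'   bounds, integrality, variable layout) shared by all per-target problems.
#' @export
split_and_gate <- function(model, partition, carbon_cap = NULL) {
  if (is.null(carbon_cap)) carbon_cap <- default_carbon_cap(model)
  if (!is.numeric(carbon_cap) || carbon_cap <= 0) {
    stop("carbon_cap must be a positive number")
  }
  n <- n_reactions(model); m <- n_metabolites(model)
  gated <- partition$noncore_reactions
  g <- length(gated)
  gj <- match(gated, model$rxns$id)
  # columns: F (1..n), B (n+1..2n), z (2n+1 .. 2n+g)
  Ssplit <- cbind(model$S, -model$S,
                  Matrix::Matrix(0, m, g, sparse = TRUE))
  gate_rows <- Matrix::sparseMatrix(
    i = c(seq_len(g), seq_len(g), seq_len(g)),
    j = c(gj, n + gj, 2L * n + seq_len(g)),
    x = c(rep(1, 2 * g), rep(carbon_cap, g)),
    dims = c(g, 2L * n + g))
  forced <- which(model$rxns$lb > 0 | model$rxns$ub < 0)
  net_rows <- Matrix::sparseMatrix(
    i = c(seq_along(forced), seq_along(forced)),
    j = c(forced, n + forced),
    x = c(rep(1, length(forced)), rep(-1, length(forced))),
    dims = c(length(forced), 2L * n + g))
  A <- rbind(Ssplit, gate_rows, net_rows)
  rlb <- c(rep(0, m), rep(-Inf, g), model$rxns$lb[forced])
  rub <- c(rep(0, m), rep(carbon_cap, g), model$rxns$ub[forced])
  lb <- c(rep(0, 2 * n), rep(0, g))
  ub <- c(pmax(model$rxns$ub, 0), pmax(-model$rxns$lb, 0), rep(1, g))
  structure(list(
    base = model,
    partition = partition,
    carbon_cap = carbon_cap,
    n = n,
    gated = gated,
    z_index = stats::setNames(2L * n + seq_len(g), gated),
    A = A, rlb = rlb, rub = rub, lb = lb, ub = ub,
    integrality = c(rep(0L, 2 * n), rep(1L, g))
  ), class = "split_gated_model")
}

#' @export
print.split_gated_model <- function(x, ...) {
  cat(sprintf("<split_gated_model: %d reactions, %d binaries, C = %g>\n",
              x$n, length(x$gated), x$carbon_cap))
  invisible(x)
}

#' @noRd
.sg_problem <- function(sg, cvec, sense = "max") {
  list(A = sg$A, rlb = sg$rlb, rub = sg$rub, lb = sg$lb, ub = sg$ub,
       integrality = sg$integrality, c = cvec, sense = sense)
}

#' Net fluxes from a split-model solution vector
#' @noRd
.sg_net_flux <- function(sg, x) {
  stats::setNames(x[seq_len(sg$n)] - x[sg$n + seq_len(sg$n)],
                  sg$base$rxns$id)
}

#' FBA on the split model with all gates open
#'
#' Used to confirm that splitting and gating preserve the original optimum:
#' with every `z = 0` the feasible set equals the original model's restricted
#' to `|v_i| <= C` on gated reactions.
#'
#' @param sg A `split_gated_model`.
#' @param objective Reaction id to maximize.
#' @return As [fba()].
#' @export
split_fba <- function(sg, objective = sg$base$objective) {
  j <- match(objective, sg$base$rxns$id)
  if (is.na(j)) stop(sprintf("objective '%s' not in model", objective))
  cvec <- rep(0, length(sg$lb))
  cvec[j] <- 1; cvec[sg$n + j] <- -1
  p <- .sg_problem(sg, cvec)
  p$ub[sg$z_index] <- 0                # all gates open
  p$integrality[] <- 0L
  sol <- solve_single(p)
  list(status = sol$status,
       objective_value = if (sol$status == "optimal") sol$objective else NA_real_,
       fluxes = if (sol$status == "optimal") .sg_net_flux(sg, as.numeric(sol$x)))
}
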