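# Flux balance analysis over net fluxes: maximize c'v subject to S v = 0 and
# lb <= v <= ub.  These LPs are the workhorse behind growth computation,
# yield analysis, the brute-force oracle and subnetwork verification.

#' @noRd
.lp_base <- function(model) {
  list(A = model$S,
       rlb = rep(0, n_metabolites(model)),
       rub = rep(0, n_metabolites(model)),
       lb = model$rxns$lb, ub = model$rxns$ub,
       integrality = rep(0L, n_reactions(model)))
}

#' Flux balance analysis
#'
#' Maximizes the flux of `objective` subject to steady state and bounds.
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id to maximize (default: model objective).
#' @param sense `"max"` or `"min"`.
#' @return List with `status`, `objective_value`, and `fluxes` (named vector,
#'   `NULL` unless optimal).
#' @export
fba <- function(model, objective = model$objective, sense = "max") {
  if (is.na(objective)) stop("model has no objective reaction; pass one")
  j <- match(objective, model$rxns$id)
  if (is.na(j)) stop(sprintf("objective '%s' not in model", objective))
  p <- .lp_base(model)
  p$c <- replace(rep(0, n_reactions(model)), j, 1)
  p$sense <- sense
  sol <- solve_single(p)
  list(status = sol$status,
       objective_value = if (sol$status == "optimal") sol$objective else NA_real_,
       fluxes = if (sol$status == "optimal") {
         stats::setNames(as.numeric(sol$x), model$rxns$id)
       })
}

#' Flux variability analysis
#'
#' Computes the attainable flux range of each requested reaction, optionally
#' with the objective fixed at a fraction of its optimum.
#'
#' @param model A `metabolic_model`.
#' @param reactions Reaction ids (default: all).
#' @param fraction_of_optimum If non-`NULL`, first maximize the model
#'   objective and constrain it to at least this fraction of the optimum.
#' @return `data.frame` with `id`, `min`, `max`.
#' @export
fva <- function(model, reactions = model$rxns$id,
                fraction_of_optimum = NULL) {
  stopifnot_rxns(model, reactions)
  p <- .lp_base(model)
  p$c <- rep(0, n_reactions(model))
  if (!is.null(fraction_of_optimum)) {
    opt <- fba(model)
    if (opt$status != "optimal") stop("FBA not optimal; cannot fix objective")
    j <- match(model$objective, model$rxns$id)
    p$lb[j] <- max(p$lb[j], fraction_of_optimum * opt$objective_value)
  }
  jj <- match(reactions, model$rxns$id)
  variants <- unlist(lapply(jj, function(j) {
    cvec <- replace(rep(0, n_reactions(model)), j, 1)
    list(list(c = cvec, sense = "min"), list(c = cvec, sense = "max"))
  }), recursive = FALSE)
  p$mode <- "batch"; p$variants <- variants
  sols <- solve_problems(list(p))[[1]]$solutions
  getobj <- function(s) if (s$status == "optimal") s$objective else NA_real_
  data.frame(
    id = reactions,
    min = vapply(sols[seq(1, length(sols), 2)], getobj, numeric(1)),
    max = vapply(sols[seq(2, length(sols), 2)], getobj, numeric(1)),
    stringsAsFactors = FALSE)
}
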