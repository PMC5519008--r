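#' Construct a metabolic model
#'
#' A `metabolic_model` holds the stoichiometric matrix of a constraint-based
#' model together with metabolite annotations (compartment, chemical formula,
#' charge), flux bounds, the objective reaction, and the medium (maximum
#' uptake flux per exchange reaction).  Reversibility is encoded purely via
#' bounds (`lb < 0`); compartments are part of metabolite identity, so the
#' same chemical species in two compartments is two metabolites.
#'
#' @param metabolites `data.frame` with columns `id`, `name`, `compartment`,
#'   `formula`, `charge` (the last four optional; missing formulas are
#'   tolerated and flagged for exclusion from elemental audits).
#' @param reactions List of reactions; each a list with `id`, `stoichiometry`
#'   (named numeric, metabolite id -> signed coefficient), `lb`, `ub`, and
#'   optional `name`, `subsystem`.
#' @param objective Id of the objective (biomass) reaction, or `NA`.
#' @param medium Named numeric vector, exchange reaction id -> maximum uptake
#'   flux (mmol/gDW/h).
#' @param id Model identifier.
#' @param rational_cap Coefficients are snapped to the nearest rational with
#'   denominator below this cap (exact cancellation in the lumping step relies
#'   on it); `NULL` disables snapping.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = NA_character_,
                            medium = NULL, id = "model",
                            rational_cap = 1e6) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!"id" %in% names(metabolites)) stop("metabolites need an 'id' column")
  for (col in c("name", "compartment", "formula")) {
    if (!col %in% names(metabolites)) metabolites[[col]] <- NA_character_
  }
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_real_
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "))
  }
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  m <- nrow(metabolites); n <- length(reactions)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  lb <- numeric(n); ub <- numeric(n)
  nm <- character(n); subsys <- character(n)
  for (k in seq_len(n)) {
    r <- reactions[[k]]
    st <- r$stoichiometry
    st <- st[st != 0]
    midx <- match(names(st), metabolites$id)
    if (anyNA(midx)) {
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   r$id, paste(names(st)[is.na(midx)], collapse = ", ")))
    }
    coef <- as.numeric(st)
    if (!is.null(rational_cap)) coef <- snap_rational(coef, rational_cap, 1e-9)
    trip_i <- c(trip_i, midx); trip_j <- c(trip_j, rep(k, length(st)))
    trip_x <- c(trip_x, coef)
    lb[k] <- r$lb; ub[k] <- r$ub
    if (lb[k] > ub[k]) {
      stop(sprintf("reaction '%s': lower bound exceeds upper bound", r$id))
    }
    nm[k] <- r$name %||% r$id
    subsys[k] <- r$subsystem %||% NA_character_
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(m, n),
                            dimnames = list(metabolites$id, rxn_ids))
  if (!is.na(objective) && !objective %in% rxn_ids) {
    stop(sprintf("objective reaction '%s' not in model", objective))
  }
  structure(list(
    id = id,
    mets = metabolites[, c("id", "name", "compartment", "formula", "charge")],
    rxns = data.frame(id = rxn_ids, name = nm, lb = lb, ub = ub,
                      subsystem = subsys, stringsAsFactors = FALSE),
    S = S,
    objective = objective,
    medium = medium %||% stats::setNames(numeric(0), character(0))
  ), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions",
              x$id, nrow(x$mets), nrow(x$rxns)))
  if (!is.na(x$objective)) cat(sprintf(", objective '%s'", x$objective))
  cat(">\n")
  invisible(x)
}

#' Number of reactions / metabolites
#' @param model A `metabolic_model`.
#' @return Integer count.
#' @export
n_reactions <- function(model) nrow(model$rxns)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$mets)

#' Stoichiometry of one reaction
#' @param model A `metabolic_model`.
#' @param rxn_id Reaction id.
#' @return Named numeric vector of nonzero coefficients.
#' @export
reaction_stoich <- function(model, rxn_id) {
  j <- match(rxn_id, model$rxns$id)
  if (is.na(j)) stop(sprintf("reaction '%s' not in model", rxn_id))
  col <- stats::setNames(as.numeric(model$S[, j]), rownames(model$S))
  col[col != 0]
}

#' @noRd
stopifnot_rxns <- function(model, ids, what = "reaction") {
  bad <- setdiff(ids, model$rxns$id)
  if (length(bad)) {
    stop(sprintf("unknown %s id(s): %s", what, paste(bad, collapse = ", ")))
  }
}

#' @noRd
stopifnot_mets <- function(model, ids) {
  bad <- setdiff(ids, model$mets$id)
  if (length(bad)) {
    stop("unknown metabolite id(s): ", paste(bad, collapse = ", "))
  }
}

#' Identify exchange reactions
#'
#' An exchange is a reaction touching exactly one metabolite (a system
#' boundary, including sinks and demands).
#' @param model A `metabolic_model`.
#' @return Logical vector along `model$rxns$id`.
#' @export
is_exchange <- function(model) {
  Matrix::colSums(model$S != 0) == 1
}

#' Identify inter-compartment transport reactions
#' @param model A `metabolic_model`.
#' @return Logical vector along `model$rxns$id`.
#' @export
is_transport <- function(model) {
  comp <- stats::setNames(model$mets$compartment, model$mets$id)
  vapply(model$rxns$id, function(rid) {
    st <- reaction_stoich(model, rid)
    length(unique(comp[names(st)])) > 1
  }, logical(1), USE.NAMES = FALSE)
}

#' Add reactions to a model
#' @param model A `metabolic_model`.
#' @param reactions List of reaction lists (as in [metabolic_model()]).
#' @return The extended model.
#' @export
add_reactions <- function(model, reactions) {
  all_rxns <- c(
    lapply(model$rxns$id, function(rid) {
      k <- match(rid, model$rxns$id)
      list(id = rid, stoichiometry = reaction_stoich(model, rid),
           lb = model$rxns$lb[k], ub = model$rxns$ub[k],
           name = model$rxns$name[k], subsystem = model$rxns$subsystem[k])
    }),
    reactions)
  metabolic_model(model$mets, all_rxns, objective = model$objective,
                  medium = model$medium, id = model$id, rational_cap = NULL)
}

#' Restrict a model to a set of reactions
#'
#' Keeps the named reactions and every metabolite they touch.  Steady state in
#' the restricted model is imposed on exactly those metabolites.
#'
#' @param model A `metabolic_model`.
#' @param rxn_ids Reactions to keep.
#' @param keep_objective Retain the objective if it survives the cut.
#' @return A `metabolic_model`.
#' @export
subset_model <- function(model, rxn_ids, keep_objective = TRUE) {
  stopifnot_rxns(model, rxn_ids)
  jj <- match(unique(rxn_ids), model$rxns$id)
  keep_met <- Matrix::rowSums(abs(model$S[, jj, drop = FALSE])) > 0
  obj <- model$objective
  if (!keep_objective || is.na(obj) || !obj %in% model$rxns$id[jj]) {
    obj <- NA_character_
  }
  structure(list(
    id = model$id,
    mets = model$mets[keep_met, , drop = FALSE],
    rxns = model$rxns[jj, , drop = FALSE],
    S = model$S[keep_met, jj, drop = FALSE],
    objective = obj,
    medium = model$medium[names(model$medium) %in% model$rxns$id[jj]]
  ), class = "metabolic_model")
}

#' Add one irreversible drain per target metabolite
#'
#' For every target this appends a boundary reaction `sink_<id>` that removes
#' the species (coefficient -1, bounds `[0, Inf)`), so that its individual
#' production can be demanded.  Targets with `role = "produced"` (biomass
#' by-products such as diphosphate, which a subnetwork must *consume*) get a
#' supply reaction instead (coefficient +1): forcing flux through it injects
#' the species at the demanded rate.
#'
#' @param model A `metabolic_model`.
#' @param targets Character vector of metabolite ids.
#' @param role `"consumed"` (default) or `"produced"`, recycled along
#'   `targets`.
#' @return The model with one new reaction per target.
#' @export
add_target_sinks <- function(model, targets,
                             role = c("consumed", "produced")) {
  if (!length(targets)) return(model)
  stopifnot_mets(model, targets)
  role <- if (missing(role)) "consumed" else
    match.arg(role, several.ok = TRUE)
  role <- rep(role, length.out = length(targets))
  new <- vector("list", length(targets))
  existing <- model$rxns$id
  for (k in seq_along(targets)) {
    rid <- paste0("sink_", targets[k])
    while (rid %in% existing) {        # deterministic suffixing on collision
      message(sprintf("sink id '%s' already taken; suffixing", rid))
      rid <- paste0(rid, "_1")
    }
    existing <- c(existing, rid)
    coef <- if (role[k] == "produced") 1 else -1
    new[[k]] <- list(id = rid,
                     stoichiometry = stats::setNames(coef, targets[k]),
                     lb = 0, ub = Inf, subsystem = "target drain")
  }
  add_reactions(model, new)
}

#' Add a composite demand reaction
#'
#' Used for targets that are whole sub-stoichiometries rather than single
#' species: growth-associated ATP hydrolysis and the adenylate-pool imbalance
#' of the biomass reaction.  The reaction consumes/produces the given
#' stoichiometry; forcing flux through it demands that the rest of the network
#' balance it.
#'
#' @param model A `metabolic_model`.
#' @param stoichiometry Named numeric vector (metabolite id -> coefficient).
#' @param id Reaction id.
#' @return The extended model.
#' @export
add_demand_reaction <- function(model, stoichiometry, id) {
  stopifnot_mets(model, names(stoichiometry))
  add_reactions(model, list(list(id = id, stoichiometry = stoichiometry,
                                 lb = 0, ub = Inf,
                                 subsystem = "composite demand")))
}

#' Set the growth medium
#'
#' Updates both the medium table and the uptake bounds: every exchange listed
#' in `medium` gets `lb = -uptake`; every other exchange is restricted to
#' secretion only.
#'
#' @param model A `metabolic_model`.
#' @param medium Named numeric vector, exchange id -> maximum uptake flux.
#' @return The updated model.
#' @export
set_medium <- function(model, medium) {
  stopifnot_rxns(model, names(medium), "exchange")
  ex <- is_exchange(model)
  for (k in which(ex)) {
    rid <- model$rxns$id[k]
    model$rxns$lb[k] <- if (rid %in% names(medium)) -medium[[rid]]
                        else max(model$rxns$lb[k], 0)
  }
  model$medium <- medium
  model
}
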