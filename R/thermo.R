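# Thermodynamic directionality pre-pass.
#
# Full thermodynamics-based flux analysis couples explicit Gibbs-energy
# variables to flux-direction binaries inside the MILP.  Here thermodynamics
# enters as a pluggable pre-pass instead: user-supplied standard transformed
# Gibbs energies and metabolite concentration ranges are turned into
# tightened per-reaction directionality bounds, which the subnetwork MILP
# then consumes like any other bounds.  With no thermodynamic data the
# pipeline is bit-identical to mass-balance-only mode.

R_GAS_KJ <- 8.31446261815324e-3  # kJ/mol/K

#' Container for reaction-level thermodynamic data
#'
#' @param delta_g_prime_deg Named numeric, reaction id -> standard
#'   transformed Gibbs energy (kJ/mol).
#' @param uncertainty Named numeric, reaction id -> kJ/mol (default 0).
#' @param conc_bounds Named list, metabolite id -> `c(min, max)` molar
#'   concentration bounds; species not listed use `default_conc`.
#' @param default_conc Default concentration range (molar).
#' @param temperature Kelvin.
#' @return A `thermo_data` object.
#' @export
thermo_data <- function(delta_g_prime_deg, uncertainty = NULL,
                        conc_bounds = list(),
                        default_conc = c(1e-6, 0.02),
                        temperature = 298.15) {
  uncertainty <- uncertainty %||%
    stats::setNames(rep(0, length(delta_g_prime_deg)),
                    names(delta_g_prime_deg))
  for (b in c(conc_bounds, list(default_conc))) {
    if (length(b) != 2 || b[1] <= 0 || b[1] > b[2]) {
      stop("concentration bounds must satisfy 0 < min <= max")
    }
  }
  structure(list(delta_g_prime_deg = delta_g_prime_deg,
                 uncertainty = uncertainty,
                 conc_bounds = conc_bounds,
                 default_conc = default_conc,
                 temperature = temperature),
            class = "thermo_data")
}

#' Tighten reaction directionality from Gibbs-energy data
#'
#' For each covered reaction the range of
#' `dG' = dG'deg + RT * sum_m n_m ln(c_m)` over the concentration boxes is
#' computed in closed form (each term is monotone in `c_m`).  The forward
#' direction is admitted iff `min dG' - uncertainty < 0`; the reverse iff
#' `max dG' + uncertainty > 0`.  Returned bounds are never wider than the
#' model's own; uncovered reactions pass through unchanged.
#'
#' @param model A `metabolic_model`.
#' @param data A `thermo_data`.
#' @param scope `"all"` or `"core"` (restrict tightening to core reactions;
#'   needs `partition`).
#' @param partition A `core_partition`, required for `scope = "core"`.
#' @return `data.frame` with `id`, `lb`, `ub` for every model reaction.
#' @export
directionality_bounds <- function(model, data, scope = c("all", "core"),
                                  partition = NULL) {
  scope <- match.arg(scope)
  covered <- intersect(names(data$delta_g_prime_deg), model$rxns$id)
  if (scope == "core") {
    if (is.null(partition)) stop("scope='core' needs a partition")
    covered <- intersect(covered, partition$core_reactions)
  }
  out <- model$rxns[, c("id", "lb", "ub")]
  RT <- R_GAS_KJ * data$temperature
  for (rid in covered) {
    st <- reaction_stoich(model, rid)
    lo <- hi <- data$delta_g_prime_deg[[rid]]
    for (m in names(st)) {
      cb <- data$conc_bounds[[m]] %||% data$default_conc
      n <- st[[m]]
      terms <- RT * n * log(cb)
      lo <- lo + min(terms); hi <- hi + max(terms)
    }
    u <- data$uncertainty[[rid]] %||% 0
    fwd <- (lo - u) < 0
    rev <- (hi + u) > 0
    k <- match(rid, out$id)
    if (!fwd) out$ub[k] <- min(out$ub[k], 0)
    if (!rev) out$lb[k] <- max(out$lb[k], 0)
  }
  out
}

#' Apply directionality bounds to a model
#'
#' @param model A `metabolic_model`.
#' @param bounds Output of [directionality_bounds()] (or any data.frame with
#'   `id`, `lb`, `ub`).
#' @return The model with updated bounds (never wider than before).
#' @export
apply_directionality <- function(model, bounds) {
  k <- match(bounds$id, model$rxns$id)
  if (anyNA(k)) stop("bounds reference unknown reactions")
  model$rxns$lb[k] <- pmax(model$rxns$lb[k], bounds$lb)
  model$rxns$ub[k] <- pmin(model$rxns$ub[k], bounds$ub)
  if (any(model$rxns$lb > model$rxns$ub)) {
    stop("directionality bounds leave an empty flux interval")
  }
  model
}
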