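#' Decompose a biomass reaction into building blocks, GAM and the adenylate
#' imbalance
#'
#' Splits the biomass stoichiometry into three exhaustive parts:
#'
#' * `gam_atp` — growth-associated maintenance: the largest `alpha` such that
#'   `alpha * (ATP + H2O -> ADP + Pi + H)` is a sub-stoichiometry of the
#'   biomass reaction (mmol ATP hydrolysed per gDW);
#' * `adenylate_imbalance` — the leftover ATP/ADP after removing GAM.  Real
#'   biomass formulations consume slightly more ATP than they return as ADP,
#'   which is a net demand for de-novo adenylate-pool synthesis;
#' * `entries` — every other substrate (`role = "consumed"`, demand
#'   `n_j > 0` mmol/gDW) and product (`role = "produced"`, e.g. diphosphate,
#'   which synthesis subnetworks must re-absorb).
#'
#' The decomposition is lossless: [biomass_stoich()] applied to the result
#' reproduces the biomass column of the stoichiometric matrix exactly.
#'
#' @param model A `metabolic_model`.
#' @param biomass_id Biomass reaction id (default: the model objective).
#' @param atp_id,adp_id,h2o_id,pi_id,h_id Metabolite ids of the GAM species;
#'   by default matched against BiGG-style names (`atp_c`, ...).
#' @return A `biomass_composition` object.
#' @export
parse_biomass <- function(model, biomass_id = model$objective,
                          atp_id = NULL, adp_id = NULL, h2o_id = NULL,
                          pi_id = NULL, h_id = NULL) {
  if (is.na(biomass_id) || !biomass_id %in% model$rxns$id) {
    stop(sprintf("biomass reaction '%s' not in model", biomass_id))
  }
  st <- reaction_stoich(model, biomass_id)
  guess <- function(given, pattern) {
    if (!is.null(given)) return(given)
    hit <- grep(pattern, names(st), ignore.case = TRUE, value = TRUE)
    if (length(hit) == 1) hit else NA_character_
  }
  ids <- c(atp = guess(atp_id, "^atp(_[a-z0-9]+)?$"),
           adp = guess(adp_id, "^adp(_[a-z0-9]+)?$"),
           h2o = guess(h2o_id, "^h2o(_[a-z0-9]+)?$"),
           pi = guess(pi_id, "^pi(_[a-z0-9]+)?$"),
           h = guess(h_id, "^h(_[a-z0-9]+)?$"))
  coef <- function(id) if (!is.na(id) && id %in% names(st)) st[[id]] else 0
  # alpha * (ATP + H2O -> ADP + Pi + H) must fit inside the stoichiometry
  gam_parts <- c(atp = -coef(ids[["atp"]]), h2o = -coef(ids[["h2o"]]),
                 adp = coef(ids[["adp"]]), pi = coef(ids[["pi"]]),
                 h = coef(ids[["h"]]))
  gam <- 0
  if (gam_parts[["atp"]] > 0 && gam_parts[["adp"]] > 0) {
    limiting <- gam_parts[c("atp", "adp") ]
    present <- gam_parts[c("h2o", "pi", "h")]
    gam <- min(c(limiting, present[present > 0]))
  }
  residual <- st
  if (gam > 0) {
    sgn <- c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)
    for (p in names(sgn)) {
      id <- ids[[p]]
      if (!is.na(id) && id %in% names(residual)) {
        residual[[id]] <- residual[[id]] - sgn[[p]] * gam
      }
    }
  }
  # leftover adenylate species go to the imbalance, everything else to entries
  aden <- c(ids[["atp"]], ids[["adp"]])
  aden <- aden[!is.na(aden)]
  aden_detail <- residual[names(residual) %in% aden]
  aden_detail <- aden_detail[abs(aden_detail) > 1e-12]
  imbalance <- sum(abs(aden_detail))
  rest <- residual[!names(residual) %in% aden]
  rest <- rest[abs(rest) > 1e-12]
  entries <- data.frame(
    bbb_id = names(rest),
    n_j = abs(as.numeric(rest)),
    role = ifelse(rest < 0, "consumed", "produced"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(entries = entries,
                 gam_atp = gam,
                 adenylate_imbalance = imbalance,
                 adenylate_detail = aden_detail,
                 gam_ids = ids,
                 biomass_id = biomass_id),
            class = "biomass_composition")
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat(sprintf(
    "<biomass_composition '%s': %d consumed, %d produced, GAM %.4g, %s>\n",
    x$biomass_id, sum(x$entries$role == "consumed"),
    sum(x$entries$role == "produced"), x$gam_atp,
    sprintf("adenylate imbalance %.4g", x$adenylate_imbalance)))
  invisible(x)
}

#' Reassemble the biomass stoichiometry from its decomposition
#'
#' Inverse of [parse_biomass()]; used to check that the decomposition is
#' lossless.
#'
#' @param composition A `biomass_composition`.
#' @return Named numeric vector (metabolite id -> coefficient).
#' @export
biomass_stoich <- function(composition) {
  out <- stats::setNames(
    ifelse(composition$entries$role == "consumed", -1, 1) *
      composition$entries$n_j,
    composition$entries$bbb_id)
  add <- function(out, id, val) {
    if (is.na(id) || val == 0) return(out)
    out[id] <- (if (id %in% names(out)) out[[id]] else 0) + val
    out
  }
  ids <- composition$gam_ids
  g <- composition$gam_atp
  sgn <- c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)
  for (p in names(sgn)) out <- add(out, ids[[p]], sgn[[p]] * g)
  for (id in names(composition$adenylate_detail)) {
    out <- add(out, id, composition$adenylate_detail[[id]])
  }
  out[out != 0]
}

#' The GAM hydrolysis stoichiometry of a composition
#'
#' Returns `gam_atp * (ATP + H2O -> ADP + Pi + H)` as a named vector, suitable
#' for [add_demand_reaction()] when treating GAM as a lumping target.
#'
#' @param composition A `biomass_composition`.
#' @return Named numeric vector (empty when `gam_atp` is zero).
#' @export
gam_stoich <- function(composition) {
  if (composition$gam_atp == 0) return(stats::setNames(numeric(0), character(0)))
  ids <- composition$gam_ids
  sgn <- c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)
  keep <- names(ids)[!is.na(ids)]
  stats::setNames(sgn[keep] * composition$gam_atp, ids[keep])
}
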