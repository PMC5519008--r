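# Carbon-mole yield ranking of alternative lumps on "mini" core models:
# core + one lump + the target drain + the medium exchanges, nothing else.
# yield = (C-atoms(target) * v_sink) / (C-atoms(source) * v_uptake).

#' Assemble the mini model for one lumped reaction
#'
#' @param model The parent `metabolic_model` (sink-augmented).
#' @param partition A `core_partition`.
#' @param lump A `lumped_reaction`.
#' @return A `metabolic_model` containing the core reactions, the boundary
#'   exchanges touching mini-model species, the lump (as irreversible
#'   reaction `LUMP_<target>`), and the target's drain.
#' @export
build_mini_model <- function(model, partition, lump) {
  target <- lump$target_id
  stopifnot_mets(model, names(lump$stoichiometry))
  species <- unique(c(partition$core_metabolites, names(lump$stoichiometry)))
  ex_ids <- model$rxns$id[is_exchange(model)]
  ex_ids <- setdiff(ex_ids, .drain_ids(model))
  ex_keep <- ex_ids[vapply(ex_ids, function(r) {
    all(names(reaction_stoich(model, r)) %in% species)
  }, logical(1))]
  sink_id <- paste0("sink_", target)
  keep <- unique(c(partition$core_reactions, ex_keep,
                   if (sink_id %in% model$rxns$id) sink_id))
  mini <- subset_model(model, keep, keep_objective = FALSE)
  missing_mets <- setdiff(names(lump$stoichiometry), mini$mets$id)
  if (length(missing_mets)) {
    # species only the lump touches (e.g. the target) enter via the lump
    mini$mets <- rbind(mini$mets,
                       model$mets[match(missing_mets, model$mets$id), ])
    mini$S <- rbind(mini$S, Matrix::Matrix(0, length(missing_mets),
                                           n_reactions(mini), sparse = TRUE))
    rownames(mini$S) <- mini$mets$id
  }
  mini <- add_reactions(mini, list(list(
    id = paste0("LUMP_", target),
    stoichiometry = lump$stoichiometry,
    lb = 0, ub = Inf, subsystem = "lumped reaction")))
  if (!sink_id %in% mini$rxns$id) {
    mini <- add_target_sinks(mini, target)
  }
  mini
}

#' Carbon-mole yield of a target on a carbon source
#'
#' Maximizes the target drain flux by LP on a mini model and reports
#' `(C-atoms(target) * v_sink) / (C-atoms(source) * v_uptake)`, with the
#' uptake taken at the LP optimum (the source exchange is bounded by the
#' medium).
#'
#' @param mini A mini model from [build_mini_model()].
#' @param target Target metabolite id.
#' @param source Carbon-source metabolite id (its exchange must exist with a
#'   finite uptake bound).
#' @param lump Optional `lumped_reaction` carried into the record.
#' @return A `yield_record`: `lump`, `carbon_source`, `yield_cmol`,
#'   `optimum_fluxes`.
#' @export
cmol_yield <- function(mini, target, source, lump = NULL) {
  stopifnot_mets(mini, c(target, source))
  atoms <- function(met) {
    f <- mini$mets$formula[match(met, mini$mets$id)]
    comp <- parse_formula(f)
    if (!"C" %in% names(comp)) {
      stop(sprintf("metabolite '%s' has no carbon or no formula", met))
    }
    comp[["C"]]
  }
  ex_ids <- setdiff(mini$rxns$id[is_exchange(mini)], .drain_ids(mini))
  src_ex <- ex_ids[vapply(ex_ids, function(r) {
    source %in% names(reaction_stoich(mini, r))
  }, logical(1))]
  if (length(src_ex) != 1) {
    stop(sprintf("expected exactly one exchange for source '%s'", source))
  }
  if (!is.finite(mini$rxns$lb[match(src_ex, mini$rxns$id)])) {
    stop(sprintf("source exchange '%s' has no finite uptake bound", src_ex))
  }
  sink_id <- paste0("sink_", target)
  opt <- fba(mini, objective = sink_id)
  if (opt$status != "optimal") {
    stop(sprintf("mini model cannot export '%s' (%s)", target, opt$status))
  }
  v_sink <- opt$objective_value
  v_up <- -opt$fluxes[[src_ex]]
  y <- if (v_up <= 1e-12) 0 else (atoms(target) * v_sink) / (atoms(source) * v_up)
  structure(list(lump = lump,
                 carbon_source = source,
                 target = target,
                 yield_cmol = y,
                 optimum_fluxes = opt$fluxes),
            class = "yield_record")
}

#' @export
print.yield_record <- function(x, ...) {
  cat(sprintf("<yield_record: %s from %s, C-mol yield %.4f>\n",
              x$target, x$carbon_source, x$yield_cmol))
  invisible(x)
}

#' Rank lumped reactions by carbon-mole yield
#'
#' Sorted descending by yield; ties broken by lump size (number of
#' participants) then lexicographically by equation string, so the order is
#' deterministic.
#'
#' @param records List of `yield_record`s sharing target and source.
#' @return The reordered list, with `rank` fields set.
#' @export
rank_lumps <- function(records) {
  if (!length(records)) return(records)
  tgt <- unique(vapply(records, function(r) r$target, character(1)))
  src <- unique(vapply(records, function(r) r$carbon_source, character(1)))
  if (length(tgt) != 1 || length(src) != 1) {
    stop("all records must share target and carbon source")
  }
  y <- vapply(records, function(r) r$yield_cmol, numeric(1))
  sz <- vapply(records, function(r) {
    if (is.null(r$lump)) 0L else length(r$lump$stoichiometry)
  }, integer(1))
  eq <- vapply(records, function(r) {
    if (is.null(r$lump)) "" else lump_equation(r$lump)
  }, character(1))
  ord <- order(-y, sz, eq)
  out <- records[ord]
  for (k in seq_along(out)) out[[k]]$rank <- k
  out
}

#' Yield report table
#'
#' @param records Ranked list from [rank_lumps()].
#' @return `data.frame` with target, equation, yield and rank.
#' @export
yield_table <- function(records) {
  data.frame(
    target = vapply(records, function(r) r$target, character(1)),
    lump = vapply(records, function(r) {
      if (is.null(r$lump)) "" else lump_equation(r$lump)
    }, character(1)),
    yield = round(vapply(records, function(r) r$yield_cmol, numeric(1)), 2),
    rank = vapply(records, function(r) r$rank %||% NA_integer_, integer(1)),
    stringsAsFactors = FALSE)
}
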