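# Minimal-subnetwork MILP and integer-cut enumeration.
#
# Per target j the problem is: maximize the number of closed gates
# (sum of z_i over non-core reactions) subject to steady state S v = 0, the
# gating constraints, and a forced synthesis flux v_sink >= demand, where
# demand = n_j * mu_max by default.  The set {i : z_i = 0} at the optimum is
# the smallest subnetwork able to synthesize the target from the core.
# Alternatives are enumerated by appending, after each solution, the integer
# cut sum_{k in R_sub} z_k >= 1, which forces at least one previously used
# reaction to be dropped.

#' @noRd
.drain_ids <- function(model) {
  model$rxns$id[model$rxns$subsystem %in%
                  c("target drain", "composite demand")]
}

# Bound patches shared by all per-target problems: open only this target's
# drain, close the drains of every other target, and demand the flux.
#' @noRd
.target_patch <- function(sg, target_sink_id, demand) {
  model <- sg$base
  drains <- .drain_ids(model)
  if (!target_sink_id %in% drains) {
    stopifnot_rxns(model, target_sink_id, "target drain")
    drains <- union(drains, target_sink_id)
  }
  others <- setdiff(drains, target_sink_id)
  jo <- match(others, model$rxns$id)
  jt <- match(target_sink_id, model$rxns$id)
  idx <- c(jo, jt)                      # F columns
  list(bidx = idx,
       blb = c(rep(0, length(jo)), demand),
       bub = c(rep(0, length(jo)), sg$ub[jt]))
}

#' Build the per-target minimal-subnetwork problem
#'
#' @param sg A `split_gated_model` (built on the model *after*
#'   [add_target_sinks()]).
#' @param target_sink_id Id of the target's drain reaction.
#' @param demand Required synthesis flux (mmol/gDW/h); typically
#'   `n_j * mu_max`.  Must be positive.
#' @return A `subnetwork_problem`.
#' @export
subnetwork_problem <- function(sg, target_sink_id, demand) {
  if (!is.numeric(demand) || demand <= 0) stop("demand must be positive")
  cvec <- rep(0, length(sg$lb))
  cvec[sg$z_index] <- 1
  structure(list(sg = sg,
                 target_sink_id = target_sink_id,
                 demand = demand,
                 c = cvec,
                 patch = .target_patch(sg, target_sink_id, demand)),
            class = "subnetwork_problem")
}

#' @noRd
.problem_spec <- function(problem) {
  sg <- problem$sg
  p <- .sg_problem(sg, problem$c, "max")
  pt <- problem$patch
  p$lb[pt$bidx] <- pt$blb
  p$ub[pt$bidx] <- pt$bub
  p
}

#' @noRd
.subnetwork_from_active <- function(problem, active_cols, rank) {
  sg <- problem$sg
  rxns <- names(sg$z_index)[match(active_cols, sg$z_index)]
  jj <- match(rxns, sg$base$rxns$id)
  mets <- if (length(jj)) {
    sg$base$mets$id[Matrix::rowSums(abs(sg$base$S[, jj, drop = FALSE])) > 0]
  } else character(0)
  structure(list(
    target_id = sub("^sink_", "", problem$target_sink_id),
    sink_id = problem$target_sink_id,
    demand = problem$demand,
    reactions = sort(rxns),
    metabolites = mets,
    size = length(rxns),
    rank = rank
  ), class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork for '%s': %d reaction(s)%s>\n", x$target_id,
              x$size,
              if (x$size) paste0(": ", paste(x$reactions, collapse = ", "))
              else " (core-producible)"))
  invisible(x)
}

#' Find the smallest subnetwork synthesizing a target
#'
#' Solves the gating MILP once.  The optimum has size
#' `|R_ncGEM| - sum(z)`; at a maximum of `sum(z)` no unnecessary gate stays
#' open, so the active set is exactly the minimal subnetwork.
#'
#' @param problem A `subnetwork_problem`.
#' @return A `subnetwork`.  Raises a condition of class
#'   `lumpnet_blocked_target` when the MILP is infeasible (the target cannot
#'   be made from core + medium).
#' @export
find_min_subnetwork <- function(problem) {
  p <- .problem_spec(problem)
  sol <- solve_single(p)
  if (sol$status != "optimal") {
    stop(errorCondition(
      sprintf("target '%s' is blocked: %s",
              problem$target_sink_id, sol$status),
      class = "lumpnet_blocked_target"))
  }
  x <- as.numeric(sol$x)
  active <- problem$sg$z_index[x[problem$sg$z_index] < 0.5]
  .subnetwork_from_active(problem, active, rank = 1L)
}

#' Enumerate alternative minimal subnetworks with integer cuts
#'
#' After each solution the cut `sum_{k in R_sub} z_k >= 1` is appended, so
#' the next solution differs in at least one reaction.  In `"minimal-only"`
#' mode iteration stops as soon as the optimum's size exceeds the first
#' (minimal) size; since all minimal subnetworks share one cardinality, the
#' returned collection is exactly the set of minimal subnetworks.  In
#' `"up-to-size"` mode iteration continues while the size stays within
#' `size_cap`.
#'
#' @param problem A `subnetwork_problem`.
#' @param mode `"minimal-only"` or `"up-to-size"`.
#' @param size_cap Largest admitted size in `"up-to-size"` mode.
#' @param max_count Hard cap on the number of solutions; hitting it is
#'   recorded as `attr(result, "truncated")`, not an error.
#' @return List of `subnetwork` objects, ordered by (size, discovery order);
#'   pairwise distinct as reaction sets.
#' @export
enumerate_alternatives <- function(problem,
                                   mode = c("minimal-only", "up-to-size"),
                                   size_cap = NULL, max_count = 1000L) {
  mode <- match.arg(mode)
  if (mode == "up-to-size" && is.null(size_cap)) {
    stop("size_cap is required in up-to-size mode")
  }
  p <- .problem_spec(problem)
  p$mode <- "enumerate"
  p$gate_idx <- unname(problem$sg$z_index)
  p$stop <- mode
  p$size_cap <- size_cap %||% -1L
  p$max_count <- max_count
  res <- solve_problems(list(p))[[1]]
  sols <- res$solutions
  if (!length(sols)) {
    stop(errorCondition(
      sprintf("target '%s' is blocked", problem$target_sink_id),
      class = "lumpnet_blocked_target"))
  }
  out <- lapply(seq_along(sols), function(k) {
    .subnetwork_from_active(problem, as.integer(sols[[k]]$active) + 1L, k)
  })
  ord <- order(vapply(out, function(s) s$size, numeric(1)))
  out <- out[ord]
  for (k in seq_along(out)) out[[k]]$rank <- k
  attr(out, "truncated") <- isTRUE(res$truncated)
  out
}

#' Assemble the core-plus-subnetwork model for one target
#'
#' Keeps the core, the always-on reactions, the subnetwork reactions and the
#' target's drain; the drains of other targets are dropped.
#'
#' @param model The sink-augmented `metabolic_model`.
#' @param partition A `core_partition`.
#' @param subnetwork_rxns Reaction ids of the subnetwork.
#' @param sink_id The target's drain id.
#' @return A `metabolic_model`.
#' @export
assemble_submodel <- function(model, partition, subnetwork_rxns, sink_id) {
  other_drains <- setdiff(.drain_ids(model), sink_id)
  keep <- setdiff(
    unique(c(partition$core_reactions, partition$always_on,
             subnetwork_rxns, sink_id)),
    other_drains)
  subset_model(model, keep)
}

#' Verify that a subnetwork can sustain its target demand
#'
#' LP check on the core-plus-subnetwork model: feasible with
#' `v_sink >= demand`?  With `check_minimality = TRUE` additionally requires
#' that deleting any single subnetwork reaction makes the LP infeasible.
#'
#' @param model The sink-augmented `metabolic_model`.
#' @param partition A `core_partition`.
#' @param subnetwork A `subnetwork` (or character vector of reaction ids).
#' @param demand Required sink flux; defaults to the subnetwork's own.
#' @param check_minimality Also check single-deletion infeasibility.
#' @return `TRUE` or `FALSE`.
#' @export
verify_subnetwork <- function(model, partition, subnetwork, demand = NULL,
                              check_minimality = FALSE) {
  if (inherits(subnetwork, "subnetwork")) {
    rxns <- subnetwork$reactions
    sink_id <- subnetwork$sink_id
    demand <- demand %||% subnetwork$demand
  } else {
    stop("subnetwork must be a 'subnetwork' object")
  }
  sub <- assemble_submodel(model, partition, rxns, sink_id)
  p <- .lp_base(sub)
  p$c <- rep(0, n_reactions(sub))
  js <- match(sink_id, sub$rxns$id)
  p$lb[js] <- demand
  variants <- list(list(want_x = FALSE))
  if (check_minimality && length(rxns)) {
    variants <- c(variants, lapply(rxns, function(r) {
      j <- match(r, sub$rxns$id)
      list(bidx = j, blb = 0, bub = 0, want_x = FALSE)
    }))
  }
  p$mode <- "batch"; p$variants <- variants
  sols <- solve_problems(list(p))[[1]]$solutions
  ok <- sols[[1]]$status == "optimal"
  if (ok && check_minimality && length(rxns)) {
    ok <- all(vapply(sols[-1], function(s) s$status != "optimal", logical(1)))
  }
  ok
}
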