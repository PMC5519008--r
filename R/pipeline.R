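#' Run the full subnetwork-and-lumping pipeline for a set of targets
#'
#' For each target: build the per-target gating MILP, enumerate (alternative)
#' minimal subnetworks, verify each one by LP, collapse each into a lumped
#' reaction via L1 net-flux minimization, and deduplicate the lumps.
#' Targets producible by the core alone yield an empty subnetwork and no
#' lump; blocked targets are reported, not fatal.
#'
#' @param model Sink-augmented `metabolic_model` (see [add_target_sinks()]).
#' @param partition A `core_partition`.
#' @param demands Named numeric vector: target drain id -> required flux
#'   (typically `n_j * mu_max`; use [parse_biomass()] and [fba()] to obtain
#'   them).
#' @param mode,size_cap,max_count Passed to [enumerate_alternatives()].
#' @param carbon_cap Gating constant; default [default_carbon_cap()].
#' @return A list keyed by drain id; each element has `subnetworks` (list),
#'   `lumps` (deduplicated list), and `status` (`"ok"`, `"core"`, or
#'   `"blocked"`).
#' @export
generate_lumps <- function(model, partition, demands,
                           mode = "minimal-only", size_cap = NULL,
                           max_count = 100L, carbon_cap = NULL) {
  sg <- split_and_gate(model, partition, carbon_cap)
  out <- list()
  for (sink_id in names(demands)) {
    res <- list(subnetworks = list(), lumps = list(), status = "ok")
    problem <- subnetwork_problem(sg, sink_id, demands[[sink_id]])
    subs <- tryCatch(
      enumerate_alternatives(problem, mode = mode, size_cap = size_cap,
                             max_count = max_count),
      lumpnet_blocked_target = function(e) e)
    if (inherits(subs, "error")) {
      res$status <- "blocked"
      out[[sink_id]] <- res
      next
    }
    res$subnetworks <- subs
    if (length(subs) == 1 && subs[[1]]$size == 0) {
      res$status <- "core"            # producible by the core alone
      out[[sink_id]] <- res
      next
    }
    lumps <- lapply(subs, function(sn) {
      fx <- minimize_net_flux(model, partition, sn)
      build_lump(sn, fx, model, partition)
    })
    res$lumps <- dedupe_lumps(lumps)
    out[[sink_id]] <- res
  }
  out
}

#' Tabulate enumerated subnetworks
#'
#' @param results Output of [generate_lumps()].
#' @return `data.frame` with one row per subnetwork: `target`, `size`,
#'   `rank`, and the semicolon-joined reaction ids.
#' @export
subnetworks_table <- function(results) {
  rows <- list()
  for (sink_id in names(results)) {
    for (sn in results[[sink_id]]$subnetworks) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = sn$target_id, size = sn$size, rank = sn$rank,
        reactions = paste(sn$reactions, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(target = character(0), size = integer(0),
                      rank = integer(0), reactions = character(0)))
  }
  do.call(rbind, rows)
}

#' Write subnetworks as TSV
#' @param results Output of [generate_lumps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subnetworks_tsv <- function(results, path) {
  utils::write.table(subnetworks_table(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write lumped reactions as structured JSON
#' @param results Output of [generate_lumps()] (or a plain list of lumps).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lumps_json <- function(results, path) {
  lumps <- if (all(vapply(results, inherits, logical(1), "lumped_reaction"))) {
    results
  } else {
    unlist(lapply(results, function(r) r$lumps), recursive = FALSE)
  }
  doc <- lapply(lumps, function(l) {
    list(target = l$target_id,
         equation = lump_equation(l),
         stoichiometry = as.list(l$stoichiometry),
         provenance = l$provenance,
         balance_report = as.list(l$balance_report))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
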