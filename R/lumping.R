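# Collapsing a subnetwork into one lumped reaction.
#
# On the core + subnetwork + drain model, minimizing the L1 norm of the
# subnetwork's net fluxes at fixed target demand yields a stoichiometrically
# proportional flux distribution; the flux-weighted sum of the subnetwork's
# stoichiometric columns, normalized per mmol of target, is the lumped
# reaction.  Because every member reaction is elementally balanced, so is the
# lump; non-core intermediates cancel exactly, leaving only core metabolites,
# the target, and drained by-products.

#' Minimize the total net flux through a subnetwork at fixed demand
#'
#' Splits every reaction of the core-plus-subnetwork model into forward and
#' backward parts, fixes the target drain at `demand`, and minimizes
#' `sum(F_i + B_i)` over the subnetwork reactions (core fluxes are free).
#' A second solve with a deterministically jittered objective (relative
#' 1e-7) is returned alongside to let [build_lump()] flag degenerate optima.
#'
#' @param model The sink-augmented `metabolic_model`.
#' @param partition A `core_partition`.
#' @param subnetwork A `subnetwork`.
#' @param demand Fixed drain flux; defaults to the subnetwork's own.
#' @return A `flux_distribution`: `values` (net flux per reaction of the
#'   assembled model), `values_alt` (jittered re-solve), `objective_value`
#'   (minimal L1 norm over the subnetwork), `sink_id`, `demand`.
#' @export
minimize_net_flux <- function(model, partition, subnetwork, demand = NULL) {
  demand <- demand %||% subnetwork$demand
  sub <- assemble_submodel(model, partition, subnetwork$reactions,
                           subnetwork$sink_id)
  n <- n_reactions(sub); m <- n_metabolites(sub)
  A <- cbind(sub$S, -sub$S)
  lb <- rep(0, 2 * n)
  ub <- c(pmax(sub$rxns$ub, 0), pmax(-sub$rxns$lb, 0))
  js <- match(subnetwork$sink_id, sub$rxns$id)
  lb[js] <- demand; ub[js] <- demand          # v_sink = demand, B_sink = 0
  ub[n + js] <- 0
  forced <- which(sub$rxns$lb > 0 | sub$rxns$ub < 0)
  forced <- setdiff(forced, js)
  if (length(forced)) {
    net <- Matrix::sparseMatrix(
      i = rep(seq_along(forced), 2), j = c(forced, n + forced),
      x = rep(c(1, -1), each = length(forced)), dims = c(length(forced), 2 * n))
    A <- rbind(A, net)
    rlb <- c(rep(0, m), sub$rxns$lb[forced])
    rub <- c(rep(0, m), sub$rxns$ub[forced])
  } else {
    rlb <- rep(0, m); rub <- rep(0, m)
  }
  jj <- match(subnetwork$reactions, sub$rxns$id)
  cvec <- rep(0, 2 * n)
  cvec[c(jj, n + jj)] <- 1
  # deterministic jitter for degeneracy detection
  set.seed(sum(utf8ToInt(paste(subnetwork$reactions, collapse = ""))) %% 1e6)
  jit <- cvec
  jit[c(jj, n + jj)] <- 1 + 1e-7 * stats::runif(2 * length(jj))
  p <- list(A = A, rlb = rlb, rub = rub, lb = lb, ub = ub,
            integrality = rep(0L, 2 * n), c = cvec, sense = "min",
            mode = "batch",
            variants = list(list(want_x = TRUE),
                            list(c = jit, want_x = TRUE)))
  sols <- solve_problems(list(p))[[1]]$solutions
  if (sols[[1]]$status != "optimal") {
    stop(errorCondition(
      sprintf("net-flux minimization infeasible for subnetwork of '%s'",
              subnetwork$target_id),
      class = "lumpnet_thermo_infeasible"))
  }
  getv <- function(s) {
    x <- as.numeric(s$x)
    stats::setNames(x[seq_len(n)] - x[n + seq_len(n)], sub$rxns$id)
  }
  structure(list(values = getv(sols[[1]]),
                 values_alt = if (sols[[2]]$status == "optimal")
                   getv(sols[[2]]),
                 objective_value = sols[[1]]$objective,
                 sink_id = subnetwork$sink_id,
                 demand = demand),
            class = "flux_distribution")
}

#' @noRd
.lump_coefficients <- function(subnetwork, values, model, tol) {
  jj <- match(subnetwork$reactions, model$rxns$id)
  v <- values[subnetwork$reactions]
  raw <- as.numeric(model$S[, jj, drop = FALSE] %*% v)
  names(raw) <- model$mets$id
  raw
}

#' Collapse a subnetwork into a lumped reaction
#'
#' The lump coefficient of metabolite `m` is
#' `sum_{i in R_sub} S[m, i] * v_i / v_sink`, i.e. the net production per
#' mmol of target.  Coefficients below `tol` are dropped; the rest are
#' snapped to small rationals (denominator cap `den_cap`) so the target's
#' coefficient is exactly +1.  Any surviving non-core intermediate above
#' tolerance signals a flux distribution that is not steady for the
#' subnetwork alone and raises `lumpnet_lumping_residue`.
#'
#' @param subnetwork A `subnetwork`.
#' @param flux A `flux_distribution` from [minimize_net_flux()].
#' @param model The sink-augmented `metabolic_model`.
#' @param partition A `core_partition`.
#' @param tol Cleanup tolerance (default 1e-6).
#' @param den_cap Denominator cap for rationalization (default 48).
#' @return A `lumped_reaction` with fields `target_id`, `stoichiometry`
#'   (target coefficient +1), `provenance` (subnetwork ranks), and
#'   `balance_report` (element -> residual); `attr(, "degenerate")` is set
#'   when an alternative L1 optimum yields a different lump.
#' @export
build_lump <- function(subnetwork, flux, model, partition,
                       tol = 1e-6, den_cap = 48) {
  target <- subnetwork$target_id
  make <- function(values) {
    raw <- .lump_coefficients(subnetwork, values, model, tol)
    if (abs(raw[[target]]) < 1e-9) {
      stop(sprintf("subnetwork carries no net flux to target '%s'", target))
    }
    coefs <- raw / abs(raw[[target]])
    # participants allowed: core metabolites, the target, drained by-products
    drained <- unique(unlist(lapply(
      model$rxns$id[is_exchange(model)],
      function(r) names(reaction_stoich(model, r)))))
    allowed <- unique(c(partition$core_metabolites, target, drained))
    bad <- setdiff(names(coefs)[abs(coefs) > tol], allowed)
    if (length(bad)) {
      stop(errorCondition(
        sprintf("non-core intermediate(s) survive lumping for '%s': %s",
                target, paste(bad, collapse = ", ")),
        class = "lumpnet_lumping_residue"))
    }
    coefs <- coefs[abs(coefs) > tol]
    snapped <- snap_rational(coefs, den_cap, tol)
    stats::setNames(as.numeric(snapped), names(coefs))
  }
  st <- make(flux$values)
  degenerate <- FALSE
  if (!is.null(flux$values_alt)) {
    st_alt <- tryCatch(make(flux$values_alt), error = function(e) NULL)
    degenerate <- is.null(st_alt) || !.same_stoich(st, st_alt, tol)
  }
  lump <- structure(list(target_id = target,
                         stoichiometry = st,
                         provenance = subnetwork$rank,
                         balance_report = NULL),
                    class = "lumped_reaction")
  lump$balance_report <- audit_elemental_balance(lump, model)
  attr(lump, "degenerate") <- degenerate
  lump
}

#' @noRd
.same_stoich <- function(a, b, tol = 1e-6) {
  keys <- union(names(a), names(b))
  av <- stats::setNames(rep(0, length(keys)), keys); av[names(a)] <- a
  bv <- stats::setNames(rep(0, length(keys)), keys); bv[names(b)] <- b
  all(abs(av - bv) <= tol * pmax(1, abs(av)))
}

#' Audit the elemental and charge balance of a lumped reaction
#'
#' @param lump A `lumped_reaction` (or named stoichiometry vector).
#' @param model A `metabolic_model` providing formulas and charges.
#' @return Named numeric vector of residuals per element (plus `charge`);
#'   exactly zero for a balanced lump.  Participants without formulas are
#'   listed in `attr(, "unaudited")` and skipped.
#' @export
audit_elemental_balance <- function(lump, model) {
  st <- if (inherits(lump, "lumped_reaction")) lump$stoichiometry else lump
  if (!length(st)) {
    return(structure(stats::setNames(numeric(0), character(0)),
                     unaudited = character(0)))
  }
  cm <- composition_matrix(model, names(st))
  audited <- setdiff(names(st), cm$unaudited)
  res <- as.numeric(cm$E[, audited, drop = FALSE] %*% st[audited])
  names(res) <- rownames(cm$E)
  res[abs(res) < 1e-9] <- 0
  structure(res, unaudited = cm$unaudited)
}

#' Format a lumped reaction as an equation string
#'
#' Reactants and products are each sorted alphabetically and joined with
#' `" + "`, in the `"A + 2 B -> C"` style of classical lumped-pathway tables.
#'
#' @param lump A `lumped_reaction`.
#' @param digits Significant digits for non-integer coefficients.
#' @return A single string.
#' @export
lump_equation <- function(lump, digits = 6) {
  st <- lump$stoichiometry
  fmt <- function(ids) {
    ids <- sort(ids)
    paste(vapply(ids, function(m) {
      a <- abs(st[[m]])
      if (abs(a - round(a)) < 1e-9) a <- round(a)
      if (a == 1) m else paste(format(a, digits = digits), m)
    }, character(1)), collapse = " + ")
  }
  paste(fmt(names(st)[st < 0]), "->", fmt(names(st)[st > 0]))
}

#' @export
print.lumped_reaction <- function(x, ...) {
  cat(sprintf("<lumped_reaction '%s'%s>\n  %s\n", x$target_id,
              if (isTRUE(attr(x, "degenerate"))) " [degenerate L1 optimum]"
              else "",
              lump_equation(x)))
  invisible(x)
}

#' Collapse duplicate lumped reactions
#'
#' Alternative subnetworks frequently collapse to the same overall reaction;
#' lumps equal up to `tol` in every coefficient are merged (provenance lists
#' concatenated), keeping first-occurrence order.
#'
#' @param lumps List of `lumped_reaction` objects.
#' @param tol Coefficient comparison tolerance.
#' @return List of unique `lumped_reaction` objects.
#' @export
dedupe_lumps <- function(lumps, tol = 1e-6) {
  out <- list()
  for (lp in lumps) {
    hit <- 0L
    for (k in seq_along(out)) {
      if (out[[k]]$target_id == lp$target_id &&
          .same_stoich(out[[k]]$stoichiometry, lp$stoichiometry, tol)) {
        hit <- k; break
      }
    }
    if (hit) {
      out[[hit]]$provenance <- c(out[[hit]]$provenance, lp$provenance)
    } else {
      out[[length(out) + 1L]] <- lp
    }
  }
  out
}
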