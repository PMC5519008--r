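#' Parse a chemical formula into element counts
#'
#' Parses formulas in Hill-style notation (`"C6H12O6"`, `"H"`, `"SO4"`) into a
#' named integer vector of atom counts.  An empty or missing formula yields an
#' empty vector, which downstream elemental audits treat as "unaudited".
#'
#' @param formula A single formula string, or `NA`.
#' @return Named numeric vector of atom counts (possibly empty).
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("SO4")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("parse_formula() expects a single string")
  if (is.na(formula) || !nzchar(formula)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  # tokens: one element symbol followed by an optional count
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  matched <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(matched)) != nchar(formula)) {
    stop(sprintf("cannot parse chemical formula '%s'", formula))
  }
  elements <- sub("[0-9]+$", "", matched)
  counts <- as.numeric(ifelse(grepl("[0-9]+$", matched),
                              sub("^[A-Za-z]+", "", matched), "1"))
  out <- numeric(0)
  for (k in seq_along(elements)) {        # repeated symbols accumulate
    e <- elements[k]
    out[e] <- (if (e %in% names(out)) out[[e]] else 0) + counts[k]
  }
  out
}

#' @noRd
formula_string <- function(counts) {
  counts <- counts[counts != 0]
  if (!length(counts)) return("")
  ord <- order(names(counts))
  # Hill order: C first, H second, rest alphabetical
  nm <- names(counts)[ord]
  nm <- c(nm[nm == "C"], nm[nm == "H"], nm[!nm %in% c("C", "H")])
  paste0(nm, ifelse(counts[nm] == 1, "", counts[nm]), collapse = "")
}

#' Element-by-metabolite composition matrix
#'
#' @param model A `metabolic_model`.
#' @param metabolites Metabolite ids (default: all).
#' @return List with `E` (elements x metabolites matrix, including a `charge`
#'   row) and `unaudited` (ids lacking a formula).
#' @export
composition_matrix <- function(model, metabolites = model$mets$id) {
  idx <- match(metabolites, model$mets$id)
  if (anyNA(idx)) {
    stop("unknown metabolite(s): ",
         paste(metabolites[is.na(idx)], collapse = ", "))
  }
  comps <- lapply(model$mets$formula[idx], function(f) {
    tryCatch(parse_formula(f), error = function(e) NULL)
  })
  unaudited <- metabolites[vapply(comps, is.null, logical(1)) |
                             model$mets$formula[idx] %in% c(NA, "")]
  elements <- sort(unique(unlist(lapply(comps, names))))
  E <- matrix(0, nrow = length(elements) + 1L, ncol = length(metabolites),
              dimnames = list(c(elements, "charge"), metabolites))
  for (k in seq_along(metabolites)) {
    ck <- comps[[k]]
    if (!is.null(ck) && length(ck)) E[names(ck), k] <- ck
  }
  E["charge", ] <- ifelse(is.na(model$mets$charge[idx]), 0,
                          model$mets$charge[idx])
  list(E = E, unaudited = unaudited)
}
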