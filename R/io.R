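# Model readers/writers: BiGG-dialect JSON and SBML Level 3 with the FBC
# package.  Both are intentionally minimal-but-standard: they cover the
# entities the algorithms need (species with compartment/formula/charge,
# reactions with bounds and stoichiometry, the objective) and round-trip
# models written by this package; annotation/GPR payloads are ignored.

#' Load a metabolic model from disk
#'
#' @param path File path.
#' @param format `"bigg-json"`, `"sbml-fbc"`, or `"auto"` (by extension:
#'   `.json` vs `.xml`/`.sbml`).
#' @return A `metabolic_model`.  Metabolites without a chemical formula are
#'   loaded with an empty composition and a warning; elemental audits skip
#'   them.
#' @export
load_model <- function(path, format = c("auto", "bigg-json", "sbml-fbc")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "bigg-json",
                     xml = , sbml = "sbml-fbc",
                     stop(sprintf("cannot infer model format from '.%s'", ext)))
  }
  model <- switch(format,
                  "bigg-json" = read_bigg_json(path),
                  "sbml-fbc" = read_sbml_fbc(path))
  nofor <- is.na(model$mets$formula) | !nzchar(model$mets$formula)
  if (any(nofor)) {
    warning(sprintf("%d metabolite(s) lack a chemical formula %s",
                    sum(nofor), "and will be skipped by elemental audits"))
  }
  model
}

#' Write a metabolic model to disk
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @param format `"bigg-json"` or `"sbml-fbc"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("bigg-json", "sbml-fbc")) {
  format <- match.arg(format)
  switch(format,
         "bigg-json" = write_bigg_json(model, path),
         "sbml-fbc" = write_sbml_fbc(model, path))
  invisible(path)
}

#' @noRd
read_bigg_json <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s' as JSON: %s",
                                     path, conditionMessage(e))))
  for (key in c("metabolites", "reactions")) {
    if (is.null(doc[[key]])) {
      stop(sprintf("not a BiGG model: missing '%s' element", key))
    }
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without an 'id' element")
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% NA_character_,
               formula = m$formula %||% NA_character_,
               charge = as.numeric(m$charge %||% NA_real_),
               stringsAsFactors = FALSE)
  }))
  objective <- NA_character_
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without an 'id' element")
    st <- vapply(r$metabolites, as.numeric, numeric(1))
    if (isTRUE((r$objective_coefficient %||% 0) != 0)) {
      objective <<- r$id
    }
    debound <- function(v) {           # |b| >= 1e30 encodes +/- infinity
      v <- as.numeric(v)
      if (abs(v) >= 1e30) sign(v) * Inf else v
    }
    list(id = r$id, stoichiometry = st,
         lb = debound(r$lower_bound %||% -1000),
         ub = debound(r$upper_bound %||% 1000),
         name = r$name %||% r$id, subsystem = r$subsystem %||% NA_character_)
  })
  medium <- stats::setNames(numeric(0), character(0))
  if (!is.null(doc$medium)) {
    medium <- vapply(doc$medium, as.numeric, numeric(1))
  }
  metabolic_model(mets, rxns, objective = objective, medium = medium,
                  id = doc$id %||% tools::file_path_sans_ext(basename(path)))
}

#' @noRd
write_bigg_json <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$mets)), function(k) {
      m <- model$mets[k, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(seq_len(nrow(model$rxns)), function(k) {
      r <- model$rxns[k, ]
      enbound <- function(v) if (is.infinite(v)) sign(v) * 1e30 else v
      list(id = r$id, name = r$name,
           metabolites = as.list(reaction_stoich(model, r$id)),
           lower_bound = enbound(r$lb), upper_bound = enbound(r$ub),
           subsystem = r$subsystem,
           objective_coefficient =
             if (!is.na(model$objective) && r$id == model$objective) 1 else 0)
    }),
    medium = as.list(model$medium))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

# -- SBML Level 3 + FBC ------------------------------------------------------

.SBML_NS <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

#' @noRd
.sbml_sanitize <- function(id) gsub("[^A-Za-z0-9_]", "_", id)

#' @noRd
read_sbml_fbc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf(
                    "cannot parse '%s' as XML: %s", path,
                    conditionMessage(e))))
  ns <- .SBML_NS
  mdl <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in SBML file")
  # flux-bound parameters
  pars <- xml2::xml_find_all(mdl, ".//sbml:listOfParameters/sbml:parameter",
                             ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  spnodes <- xml2::xml_find_all(mdl, ".//sbml:listOfSpecies/sbml:species", ns)
  if (!length(spnodes)) stop("SBML model has no <species>")
  strip <- function(x) sub("^M_", "", x)
  mets <- data.frame(
    id = strip(xml2::xml_attr(spnodes, "id")),
    name = xml2::xml_attr(spnodes, "name"),
    compartment = xml2::xml_attr(spnodes, "compartment"),
    formula = xml2::xml_attr(spnodes, "chemicalFormula"),
    charge = as.numeric(xml2::xml_attr(spnodes, "charge")),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  rxnodes <- xml2::xml_find_all(mdl, ".//sbml:listOfReactions/sbml:reaction",
                                ns)
  rxns <- lapply(rxnodes, function(nd) {
    rid <- sub("^R_", "", xml2::xml_attr(nd, "id"))
    sref <- function(which, sign) {
      refs <- xml2::xml_find_all(nd, sprintf("./sbml:%s/sbml:speciesReference",
                                             which), ns)
      if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
        strip(xml2::xml_attr(refs, "species")))
    }
    st <- c(sref("listOfReactants", -1), sref("listOfProducts", +1))
    st <- tapply(st, names(st), sum)   # species on both sides collapse
    lbp <- xml2::xml_attr(nd, "lowerFluxBound")
    ubp <- xml2::xml_attr(nd, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else -1000
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    list(id = rid, stoichiometry = stats::setNames(as.numeric(st), names(st)),
         lb = lb, ub = ub, name = xml2::xml_attr(nd, "name") %||% rid)
  })
  objective <- NA_character_
  objref <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (!inherits(objref, "xml_missing")) {
    objective <- sub("^R_", "", xml2::xml_attr(objref, "reaction"))
  }
  metabolic_model(mets, rxns, objective = objective,
                  id = xml2::xml_attr(mdl, "id") %||% "model")
}

#' @noRd
write_sbml_fbc <- function(model, path) {
  # collect distinct bound values as shared parameters, COBRA-style
  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bid <- function(v) {
    if (v == Inf) return("cap_inf")
    if (v == -Inf) return("cap_minus_inf")
    paste0("cap_", gsub("[^0-9A-Za-z]", "_", format(v, digits = 15)))
  }
  par_xml <- paste0(vapply(bounds, function(v) {
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            bid(v), format(v, digits = 15))
  }, character(1)), collapse = "\n")
  comps <- unique(model$mets$compartment)
  comps[is.na(comps)] <- "c"
  comp_xml <- paste0(sprintf(
    '      <compartment id="%s" constant="true"/>', unique(comps)),
    collapse = "\n")
  sp_xml <- paste0(vapply(seq_len(nrow(model$mets)), function(k) {
    m <- model$mets[k, ]
    extra <- ""
    if (!is.na(m$formula) && nzchar(m$formula)) {
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', m$formula))
    }
    if (!is.na(m$charge)) {
      extra <- paste0(extra, sprintf(' fbc:charge="%d"', as.integer(m$charge)))
    }
    sprintf(paste0('      <species id="M_%s" name="%s" compartment="%s"',
                   ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                   ' constant="false"%s/>'),
            .sbml_sanitize(m$id), m$name,
            if (is.na(m$compartment)) "c" else m$compartment, extra)
  }, character(1)), collapse = "\n")
  rx_xml <- paste0(vapply(seq_len(nrow(model$rxns)), function(k) {
    r <- model$rxns[k, ]
    st <- reaction_stoich(model, r$id)
    side <- function(sel, tag) {
      if (!any(sel)) return("")
      refs <- paste0(vapply(which(sel), function(q) {
        sprintf(paste0('          <speciesReference species="M_%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                .sbml_sanitize(names(st)[q]),
                format(abs(st[q]), digits = 15))
      }, character(1)), collapse = "\n")
      sprintf("        <%s>\n%s\n        </%s>", tag, refs, tag)
    }
    body <- paste(c(side(st < 0, "listOfReactants"),
                    side(st > 0, "listOfProducts")), collapse = "\n")
    sprintf(paste0('      <reaction id="R_%s" name="%s" reversible="%s" ',
                   'fast="false" fbc:lowerFluxBound="%s" ',
                   'fbc:upperFluxBound="%s">\n%s\n      </reaction>'),
            .sbml_sanitize(r$id), r$name,
            if (r$lb < 0) "true" else "false",
            bid(r$lb), bid(r$ub), body)
  }, character(1)), collapse = "\n")
  obj_xml <- ""
  if (!is.na(model$objective)) {
    obj_xml <- sprintf(paste0(
      '    <fbc:listOfObjectives fbc:activeObjective="obj">\n',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">\n',
      '        <fbc:listOfFluxObjectives>\n',
      '          <fbc:fluxObjective fbc:reaction="R_%s" ',
      'fbc:coefficient="1"/>\n',
      '        </fbc:listOfFluxObjectives>\n',
      '      </fbc:objective>\n',
      '    </fbc:listOfObjectives>\n'), .sbml_sanitize(model$objective))
  }
  xml <- sprintf(
    paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
           '<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
           'fbc:required="false">\n',
           '  <model id="%s" fbc:strict="true">\n',
           '    <listOfCompartments>\n%s\n    </listOfCompartments>\n',
           '    <listOfSpecies>\n%s\n    </listOfSpecies>\n',
           '    <listOfParameters>\n%s\n    </listOfParameters>\n',
           '    <listOfReactions>\n%s\n    </listOfReactions>\n',
           '%s',
           '  </model>\n</sbml>\n'),
    .SBML_NS[["sbml"]], .SBML_NS[["fbc"]], .sbml_sanitize(model$id),
    comp_xml, sp_xml, par_xml, rx_xml, obj_xml)
  writeLines(xml, path)
  invisible(path)
}
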