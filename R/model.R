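## Metabolic model container, validation, exchange detection and the
## extracellular-namespace harmonisation used to build the shared pool.

#' Construct a metabolic model
#'
#' A `metabolic_model` holds the stoichiometric matrix (metabolites x
#' reactions), flux bounds, the biomass objective and the auto-detected set
#' of exchange reactions.  Exchange reactions follow the genome-scale sign
#' convention: each involves exactly one metabolite with coefficient -1, so
#' that negative flux is uptake from the extracellular pool and positive
#' flux is secretion into it.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `compartment`,
#'   `formula` (may be `NA`) and optionally `molar_mass` (g/mol; computed
#'   from `formula` when missing).
#' @param stoichiometry numeric matrix, rows named by metabolite id,
#'   columns by reaction id.
#' @param reactions data.frame with columns `id`, `lb`, `ub`
#'   (mmol/gDW/h).
#' @param objective id of the biomass reaction.
#' @param regime oxygen-regime metadata flag used by the screening layer:
#'   `"facultative"` (default), `"aerobe"` (obligate aerobe, excluded from
#'   anaerobic screens) or `"anaerobe"`.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, stoichiometry, reactions,
                            objective, regime = "facultative") {
  stoichiometry <- as.matrix(stoichiometry)
  rownames(stoichiometry) <- metabolites$id
  colnames(stoichiometry) <- reactions$id
  if (!"molar_mass" %in% names(metabolites)) {
    metabolites$molar_mass <- molar_mass(metabolites$formula)
  } else {
    miss <- is.na(metabolites$molar_mass)
    metabolites$molar_mass[miss] <- molar_mass(metabolites$formula[miss])
  }
  m <- structure(
    list(id = id, metabolites = metabolites,
         stoichiometry = stoichiometry, reactions = reactions,
         objective = objective, regime = regime,
         exchanges = character(0)),
    class = "metabolic_model")
  m$exchanges <- detect_exchanges(m)
  validate_model(m)
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions, %d exchanges\n",
              x$id, nrow(x$metabolites), nrow(x$reactions),
              length(x$exchanges)))
  cat(sprintf("  objective: %s  regime: %s\n", x$objective, x$regime))
  invisible(x)
}

## Exchange reactions: exactly one metabolite, coefficient -1.
detect_exchanges <- function(model) {
  S <- model$stoichiometry
  nz <- colSums(S != 0)
  cand <- which(nz == 1)
  keep <- vapply(cand, function(j) {
    S[which(S[, j] != 0), j] == -1
  }, logical(1))
  colnames(S)[cand[keep]]
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: declared metabolites only, `lb <= ub`
#' everywhere, exchange convention, and an existing biomass objective.
#' Errors with a message naming the offending element.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  S <- model$stoichiometry
  if (!identical(rownames(S), model$metabolites$id))
    stop("stoichiometry rows do not match declared metabolites in model '",
         model$id, "'")
  if (!identical(colnames(S), model$reactions$id))
    stop("stoichiometry columns do not match declared reactions in model '",
         model$id, "'")
  bad <- model$reactions$lb > model$reactions$ub
  if (any(bad))
    stop("lower bound exceeds upper bound for reaction '",
         model$reactions$id[which(bad)[1]], "'")
  if (is.na(model$objective) || !model$objective %in% model$reactions$id)
    stop("no biomass objective: model '", model$id,
         "' does not declare a valid objective reaction")
  invisible(model)
}

## Metabolite id carried by each exchange reaction (named by exchange id).
exchange_metabolites <- function(model) {
  S <- model$stoichiometry
  vapply(model$exchanges, function(ex) {
    rownames(S)[which(S[, ex] != 0)]
  }, character(1))
}

#' Read a metabolic model from file
#'
#' Supports SBML Level 3 with the FBC package and the BiGG-style JSON model
#' dialect.  Exchange reactions are auto-detected (single metabolite with
#' coefficient -1) and molar masses computed from chemical formulas where
#' present.
#'
#' @param path file path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension).
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("JSON parse failure in '", path, "': ",
                         conditionMessage(e)))
  mets <- do.call(rbind, lapply(doc$metabolites, function(m)
    data.frame(id = m$id,
               compartment = m$compartment %||% "",
               formula = m$formula %||% NA_character_,
               stringsAsFactors = FALSE)))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r)
    data.frame(id = r$id, lb = as.numeric(r$lower_bound),
               ub = as.numeric(r$upper_bound), stringsAsFactors = FALSE)))
  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$id))
  for (r in doc$reactions) {
    for (mid in names(r$metabolites)) {
      if (!mid %in% mets$id)
        stop("reaction '", r$id, "' references undeclared metabolite '",
             mid, "'")
      S[mid, r$id] <- as.numeric(r$metabolites[[mid]])
    }
  }
  obj <- NA_character_
  for (r in doc$reactions) {
    if (!is.null(r$objective_coefficient) &&
        as.numeric(r$objective_coefficient) != 0) obj <- r$id
  }
  metabolic_model(id = doc$id %||% basename(path),
                  metabolites = mets, stoichiometry = S, reactions = rxns,
                  objective = obj,
                  regime = doc$regime %||% "facultative")
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("SBML parse failure in '", path, "': ",
                         conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(model_node, ns)))
    stop("SBML parse failure in '", path, "': no <model> element")

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns),
    stringsAsFactors = FALSE)

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0) stop("SBML parse failure in '", path,
                            "': no reactions")
  get_bound <- function(node, attr, default) {
    ref <- xml2::xml_attr(node, attr, ns)
    if (is.na(ref)) return(default)
    if (ref %in% names(pval)) pval[[ref]] else suppressWarnings(as.numeric(ref))
  }
  rxns <- data.frame(
    id = xml2::xml_attr(rx, "id"),
    lb = vapply(rx, get_bound, numeric(1), attr = "fbc:lowerFluxBound",
                default = -LP_BIG),
    ub = vapply(rx, get_bound, numeric(1), attr = "fbc:upperFluxBound",
                default = LP_BIG),
    stringsAsFactors = FALSE)
  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (i in seq_along(rx)) {
    node <- rx[[i]]
    rid <- rxns$id[i]
    for (ref in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      mid <- xml2::xml_attr(ref, "species")
      if (!mid %in% mets$id)
        stop("reaction '", rid, "' references undeclared species '", mid, "'")
      S[mid, rid] <- S[mid, rid] - as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      mid <- xml2::xml_attr(ref, "species")
      if (!mid %in% mets$id)
        stop("reaction '", rid, "' references undeclared species '", mid, "'")
      S[mid, rid] <- S[mid, rid] + as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
  }
  obj_node <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  obj <- if (!inherits(obj_node, "xml_missing"))
    xml2::xml_attr(obj_node, "fbc:reaction", ns) else NA_character_
  if (is.na(obj))
    stop("no biomass objective: '", path,
         "' declares no fbc flux objective")
  regime <- xml2::xml_attr(model_node, "regime")
  metabolic_model(id = xml2::xml_attr(model_node, "id"),
                  metabolites = mets, stoichiometry = S, reactions = rxns,
                  objective = obj,
                  regime = if (is.na(regime)) "facultative" else regime)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metabolic model to file
#'
#' Inverse of [read_model()]; round-tripping preserves stoichiometry,
#' bounds and the objective exactly.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  if (format == "json") write_model_json(model, path) else
    write_model_sbml(model, path)
  invisible(path)
}

write_model_json <- function(model, path) {
  S <- model$stoichiometry
  rlist <- lapply(seq_len(nrow(model$reactions)), function(j) {
    nz <- which(S[, j] != 0)
    out <- list(id = model$reactions$id[j],
                metabolites = as.list(S[nz, j]),
                lower_bound = model$reactions$lb[j],
                upper_bound = model$reactions$ub[j])
    names(out$metabolites) <- rownames(S)[nz]
    if (identical(model$reactions$id[j], model$objective))
      out$objective_coefficient <- 1
    out
  })
  mlist <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    mm <- model$metabolites
    out <- list(id = mm$id[i], compartment = mm$compartment[i])
    if (!is.na(mm$formula[i])) out$formula <- mm$formula[i]
    out
  })
  doc <- list(id = model$id, regime = model$regime,
              metabolites = mlist, reactions = rlist)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  bnd_id <- function(j, side) sprintf("%s_%s", side, model$reactions$id[j])
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" regime="%s" fbc:strict="true">',
            esc(model$id), model$regime),
    '    <listOfCompartments>')
  for (cmp in unique(model$metabolites$compartment))
    lines <- c(lines, sprintf('      <compartment id="%s" constant="true"/>',
                              esc(cmp)))
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    mm <- model$metabolites
    fml <- if (is.na(mm$formula[i])) "" else
      sprintf(' fbc:chemicalFormula="%s"', mm$formula[i])
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" compartment="%s" hasOnlySubstanceUnits',
             '="false" boundaryCondition="false" constant="false"%s/>'),
      esc(mm$id[i]), esc(mm$compartment[i]), fml))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (j in seq_len(nrow(model$reactions))) {
    lines <- c(lines,
      sprintf('      <parameter id="%s" value="%.17g" constant="true"/>',
              bnd_id(j, "lb"), model$reactions$lb[j]),
      sprintf('      <parameter id="%s" value="%.17g" constant="true"/>',
              bnd_id(j, "ub"), model$reactions$ub[j]))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  S <- model$stoichiometry
  for (j in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[j]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(rid), tolower(model$reactions$lb[j] < 0),
      bnd_id(j, "lb"), bnd_id(j, "ub")))
    sub <- which(S[, j] < 0); prod <- which(S[, j] > 0)
    if (length(sub)) {
      lines <- c(lines, '        <listOfReactants>')
      for (i in sub) lines <- c(lines, sprintf(
        '          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
        esc(rownames(S)[i]), -S[i, j]))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>')
      for (i in prod) lines <- c(lines, sprintf(
        '          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
        esc(rownames(S)[i]), S[i, j]))
      lines <- c(lines, '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(model$objective)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
}

#' Harmonise extracellular namespaces across models
#'
#' Maps each model's extracellular metabolites (identified by a compartment
#' id suffix, default `"_e"` on the metabolite id or compartment `"e"`)
#' onto a shared pool namespace.  Identical BiGG-style ids collapse onto
#' one pool id, and the legacy bracket compartment notation (`glc__D[e]`)
#' is normalised onto the suffix convention (`glc__D_e`); unmappable ids
#' are carried through under their local id with a warning.  Two distinct
#' metabolites of one model normalising onto the same pool id is a
#' collision error.
#'
#' @param models list of `metabolic_model` objects.
#' @param suffix extracellular id suffix convention (default `"_e"`).
#' @return object of class `namespace_map`: list with `pool_ids` (union)
#'   and `maps` (per model, named character vector local id -> pool id).
#' @export
harmonize_extracellular <- function(models, suffix = "_e") {
  if (length(models) < 1) stop("at least one model required")
  csuf <- sub("^_", "", suffix)
  maps <- lapply(models, function(m) {
    ex_mets <- unique(unname(exchange_metabolites(m)))
    pool <- vapply(ex_mets, function(id) {
      bracket <- paste0("\\[", csuf, "\\]$")
      if (grepl(bracket, id)) sub(bracket, suffix, id)
      else if (endsWith(id, suffix) ||
          m$metabolites$compartment[match(id, m$metabolites$id)] ==
            csuf) id else {
        warning("metabolite '", id, "' in model '", m$id,
                "' does not follow the extracellular convention; ",
                "carried through under its local id")
        id
      }
    }, character(1))
    if (anyDuplicated(pool))
      stop("collision: two metabolites of model '", m$id,
           "' map to pool id '", pool[duplicated(pool)][1], "'")
    pool
  })
  names(maps) <- vapply(models, `[[`, character(1), "id")
  structure(list(pool_ids = sort(unique(unlist(maps, use.names = FALSE))),
                 maps = maps),
            class = "namespace_map")
}

#' Static growth check of a model on a medium
#'
#' Quality-control gate: solves a single FBA with uptake bounds implied by
#' the medium (transport-limited Michaelis-Menten term only, no biomass
#' availability term).  Metabolites absent from the medium cannot be taken
#' up.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium()] object.
#' @param kinetics an [uptake_kinetics()] object.
#' @return list with `mu` (1/h; 0 when the optimum is zero) and `status`
#'   (`"optimal"` or `"infeasible"` - an infeasible LP is distinct from
#'   zero growth).
#' @export
check_model_growth <- function(model, medium,
                               kinetics = uptake_kinetics()) {
  ex_met <- exchange_metabolites(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  for (k in seq_along(model$exchanges)) {
    ex <- model$exchanges[k]
    j <- match(ex, model$reactions$id)
    S_j <- medium$concentrations[ex_met[k]]
    S_j <- if (is.na(S_j)) 0 else unname(S_j)
    vmax <- kin_param(kinetics, ex_met[k], "V_max")
    km <- kin_param(kinetics, ex_met[k], "K_m")
    lb[j] <- max(lb[j], -vmax * S_j / (km + S_j))
  }
  sol <- fba(model, lb, ub)
  list(mu = sol$mu,
       status = if (sol$status == "optimal") "optimal" else "infeasible")
}
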