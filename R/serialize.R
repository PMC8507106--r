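# Plain-text model interchange: a JSON dialect that round-trips rn_model /
# rn_parameters losslessly, and a minimal SBML Level 3 Version 1 export for
# cross-checking assembled models in external simulators.

#' Serialize a model (and optionally its parameters) to JSON
#'
#' @param model An [rn_model()].
#' @param params Optional [rn_parameters()] stored alongside.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, params = NULL) {
  obj <- list(
    name = model$name,
    notes = model$notes,
    inputs = as.list(model$inputs),
    species = lapply(model$species, function(s)
      list(name = s$name, conc = s$conc, role = s$role)),
    reactions = lapply(model$reactions, function(r) list(
      id = r$id, kind = r$kind,
      substrates = as.list(r$substrates), products = as.list(r$products),
      modifiers = r$modifiers, params = as.list(r$params)))
  )
  if (!is.null(params)) {
    obj$parameters <- list(values = as.list(params$values),
                           provenance = params$provenance)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model_json()]
#'
#' @param path File path.
#' @return A list with elements `model` ([rn_model()]) and `params`
#'   ([rn_parameters()] or `NULL`).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  species <- lapply(obj$species, function(s)
    rn_species(s$name, s$conc, if (is.null(s$role)) "" else s$role))
  reactions <- lapply(obj$reactions, function(r) {
    rn_reaction(r$id, r$kind,
                substrates = unlist(r$substrates) %||% numeric(),
                products = unlist(r$products) %||% numeric(),
                modifiers = lapply(r$modifiers, function(m)
                  list(species = m$species, type = m$type, param = m$param)),
                params = unlist(r$params))
  })
  inputs <- if (length(obj$inputs)) unlist(obj$inputs) else numeric()
  model <- rn_model(obj$name, species, reactions, inputs,
                    notes = obj$notes %||% "")
  params <- NULL
  if (!is.null(obj$parameters)) {
    params <- rn_parameters(unlist(obj$parameters$values),
                            provenance = obj$parameters$provenance %||% "file")
  }
  list(model = model, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- SBML export -------------------------------------------------------------

.mml <- function(s) s
.mml_ci <- function(x) paste0("<ci>", x, "</ci>")
.mml_cn <- function(v) paste0("<cn>", format(v, digits = 17), "</cn>")
.mml_apply <- function(op, ...) {
  paste0("<apply><", op, "/>", paste0(..., collapse = ""), "</apply>")
}
.mml_times <- function(factors) {
  factors <- factors[nzchar(factors)]
  if (length(factors) == 1L) factors else .mml_apply("times", factors)
}

.reaction_mathml <- function(r, clamped) {
  ref <- function(nm) .mml_ci(nm) # species and parameters both map to <ci>
  facs <- character(0)
  for (m in r$modifiers) {
    if (m$type == "activator") facs <- c(facs, ref(m$species))
    if (m$type == "inhibitor") {
      facs <- c(facs, .mml_apply("divide", c(.mml_cn(1),
        .mml_apply("plus", c(.mml_cn(1),
          .mml_apply("times", c(ref(m$param), ref(m$species))))))))
    }
  }
  drv <- NULL
  for (m in r$modifiers) if (m$type == "driver") drv <- m$species
  if (is.null(drv) && length(r$substrates)) drv <- names(r$substrates)[1]
  core <- switch(r$kind,
    synthesis = ref(r$params[["k"]]),
    decay = .mml_apply("times", c(ref(r$params[["k"]]),
                                  ref(names(r$substrates)[1]))),
    mass_action = {
      subs <- unlist(lapply(names(r$substrates), function(s) {
        st <- r$substrates[[s]]
        if (st == 1) ref(s) else .mml_apply("power", c(ref(s), .mml_cn(st)))
      }))
      .mml_apply("times", c(ref(r$params[["k"]]), subs))
    },
    michaelis_menten = .mml_apply("times", c(ref(r$params[["vmax"]]),
      .mml_apply("divide", c(ref(drv),
        .mml_apply("plus", c(ref(r$params[["km"]]), ref(drv))))))),
    hill = {
      pw <- function(b) .mml_apply("power", c(b, ref(r$params[["n"]])))
      .mml_apply("times", c(ref(r$params[["vmax"]]),
        .mml_apply("divide", c(pw(ref(drv)),
          .mml_apply("plus", c(pw(ref(r$params[["km"]])), pw(ref(drv))))))))
    })
  body <- .mml_times(c(core, facs))
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', body, "</math>")
}

#' Export a model to SBML Level 3 Version 1
#'
#' A minimal, standards-conformant export (one compartment, species,
#' parameters, reactions with MathML kinetic laws) intended for
#' cross-checking the assembled network in external SBML simulators.
#' Clamped inputs are exported as boundary-condition species.
#'
#' @param model An [rn_model()].
#' @param params An [rn_parameters()].
#' @param path File path for the `.xml` output.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, params, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  sp_xml <- c(
    vapply(model$species, function(s) sprintf(
      '<species id="%s" compartment="cell" initialConcentration="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(s$name), format(s$conc, digits = 17)), character(1)),
    vapply(names(model$inputs), function(nm) sprintf(
      '<species id="%s" compartment="cell" initialConcentration="%s" hasOnlySubstanceUnits="false" boundaryCondition="true" constant="true"/>',
      esc(nm), format(model$inputs[[nm]], digits = 17)), character(1)))
  par_xml <- vapply(names(params$values), function(nm) sprintf(
    '<parameter id="%s" value="%s" constant="true"/>',
    esc(nm), format(params$values[[nm]], digits = 17)), character(1))
  rx_xml <- vapply(model$reactions, function(r) {
    sref <- function(v) vapply(names(v), function(s) sprintf(
      '<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
      s, format(v[[s]], digits = 17)), character(1))
    mref <- vapply(r$modifiers, function(m) sprintf(
      '<modifierSpeciesReference species="%s"/>', m$species), character(1))
    act_clamped <- vapply(r$modifiers, function(m)
      m$type == "activator" && m$species %in% names(model$inputs), logical(1))
    paste0('<reaction id="', esc(r$id), '" reversible="false">',
      if (length(r$substrates)) paste0("<listOfReactants>",
        paste0(sref(r$substrates), collapse = ""), "</listOfReactants>") else "",
      if (length(r$products)) paste0("<listOfProducts>",
        paste0(sref(r$products), collapse = ""), "</listOfProducts>") else "",
      if (length(mref)) paste0("<listOfModifiers>",
        paste0(mref, collapse = ""), "</listOfModifiers>") else "",
      "<kineticLaw>", .reaction_mathml(r, names(model$inputs)), "</kineticLaw>",
      "</reaction>")
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="', gsub("[^A-Za-z0-9_]", "_", model$name), '">',
    '<listOfCompartments><compartment id="cell" spatialDimensions="3" size="1" constant="true"/></listOfCompartments>',
    "<listOfSpecies>", paste0(sp_xml, collapse = ""), "</listOfSpecies>",
    "<listOfParameters>", paste0(par_xml, collapse = ""), "</listOfParameters>",
    "<listOfReactions>", paste0(rx_xml, collapse = ""), "</listOfReactions>",
    "</model></sbml>")
  # validate well-formedness before writing
  xml2::read_xml(doc)
  writeLines(doc, path)
  invisible(path)
}
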