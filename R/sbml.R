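# SBML Level 3 Version 1 serialization of model systems, written and parsed
# directly as XML. Only the model's own rate-law family is supported:
# mass-action products of a single rate constant and species concentrations,
# evaluated in one compartment. The clamped extracellular ligand of
# non-depleting models is encoded as a boundary-condition species referenced
# as a reaction modifier, the standard SBML idiom for an external input.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.mathml_ns <- "http://www.w3.org/1998/Math/MathML"

.sbml_unit_defs <- function() {
  list(
    nanomolar = list(c("mole", 1, -9), c("litre", -1, 0)),
    nanomolar_per_second = list(c("mole", 1, -9), c("litre", -1, 0), c("second", -1, 0)),
    per_second = list(c("second", -1, 0)),
    per_nanomolar_per_second = list(c("mole", -1, -9), c("litre", 1, 0), c("second", -1, 0)),
    per_nanomolar2_per_second = list(c("mole", -2, -9), c("litre", 2, 0), c("second", -1, 0))
  )
}

.unit_id <- function(unit_string) {
  switch(unit_string,
         "nM/s" = "nanomolar_per_second",
         "1/s" = "per_second",
         "1/(nM s)" = "per_nanomolar_per_second",
         "1/(nM^2 s)" = "per_nanomolar2_per_second",
         "1" = "dimensionless",
         "dimensionless")
}

#' Export a model system to SBML
#'
#' Writes an SBML Level 3 Version 1 document with explicit unit definitions
#' (nanomole/liter, seconds), all compartments, species (initial
#' concentrations in nM), global parameters and mass-action kinetic laws
#' spelled out in MathML. The document round-trips through [import_sbml()].
#'
#' @param system A `tgf_model`.
#' @param path Output file path (.xml).
#' @return A `tgf_sbml_handle` with the level/version tag, species, reaction
#'   and parameter counts (matching the in-memory system; the clamped-input
#'   boundary species is not counted), and the validation status from
#'   [validate_sbml()].
#' @export
export_sbml <- function(system, path) {
  stopifnot(inherits(system, "tgf_model"))
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns, level = "3", version = "1")
  mid <- paste0("tgfsmad_", system$variant$mechanism,
                if (system$variant$ligand_depletion) "_depletion" else "")
  model <- xml2::xml_add_child(doc, "model", id = mid,
                               substanceUnits = "nanomole", timeUnits = "second",
                               volumeUnits = "litre", extentUnits = "nanomole")

  lud <- xml2::xml_add_child(model, "listOfUnitDefinitions")
  for (uid in names(.sbml_unit_defs())) {
    ud <- xml2::xml_add_child(lud, "unitDefinition", id = uid)
    lou <- xml2::xml_add_child(ud, "listOfUnits")
    for (u in .sbml_unit_defs()[[uid]])
      xml2::xml_add_child(lou, "unit", kind = u[1], exponent = u[2],
                          scale = u[3], multiplier = "1")
  }

  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (i in seq_len(nrow(system$compartments)))
    xml2::xml_add_child(loc, "compartment",
                        id = system$compartments$name[i],
                        spatialDimensions = "3",
                        size = format(system$compartments$volume[i], digits = 17),
                        units = "litre", constant = "true")

  needs_input <- any(system$ligand_driven)
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(system$species)))
    xml2::xml_add_child(los, "species",
                        id = system$species$name[i],
                        compartment = system$species$compartment[i],
                        initialConcentration =
                          format(system$species$initial[i], digits = 17),
                        substanceUnits = "nanomole",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  if (needs_input)
    xml2::xml_add_child(los, "species", id = "TGFb",
                        compartment = "extracellular",
                        initialConcentration = "0",
                        substanceUnits = "nanomole",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "true", constant = "false")

  params <- system$params
  units <- attr(params, "units")
  lop <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in names(params))
    xml2::xml_add_child(lop, "parameter", id = nm,
                        value = format(unname(params[[nm]]), digits = 17),
                        units = .unit_id(units[[nm]]), constant = "true")
  xml2::xml_add_child(lop, "parameter", id = "k_in_complex",
                      value = format(params[["CIF"]] * params[["k_in_S2"]],
                                     digits = 17),
                      units = "per_second", constant = "true")

  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_along(system$reactions)) {
    r <- system$reactions[[j]]
    rn <- xml2::xml_add_child(lor, "reaction", id = r$id, reversible = "false")
    st <- r$stoich[r$stoich != 0]
    reactants <- st[st < 0]
    products <- st[st > 0]
    catalysts <- setdiff(names(r$kinetics), names(st))
    if (length(reactants) > 0) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (nm in names(reactants))
        xml2::xml_add_child(lr, "speciesReference", species = nm,
                            stoichiometry = format(-reactants[[nm]]),
                            constant = "true")
    }
    if (length(products) > 0) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (nm in names(products))
        xml2::xml_add_child(lp, "speciesReference", species = nm,
                            stoichiometry = format(products[[nm]]),
                            constant = "true")
    }
    if (length(catalysts) > 0 || r$ligand_driven) {
      lm <- xml2::xml_add_child(rn, "listOfModifiers")
      for (nm in catalysts)
        xml2::xml_add_child(lm, "modifierSpeciesReference", species = nm)
      if (r$ligand_driven)
        xml2::xml_add_child(lm, "modifierSpeciesReference", species = "TGFb")
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = .mathml_ns)
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", r$compartment)
    xml2::xml_add_child(ap, "ci", r$k_name)
    for (nm in names(r$kinetics))
      for (rep in seq_len(r$kinetics[[nm]]))
        xml2::xml_add_child(ap, "ci", nm)
    if (r$ligand_driven) xml2::xml_add_child(ap, "ci", "TGFb")
  }

  xml2::write_xml(doc, path)
  val <- validate_sbml(path)
  structure(list(path = path, level = 3L, version = 1L,
                 n_species = nrow(system$species),
                 n_reactions = length(system$reactions),
                 n_parameters = length(params),
                 valid = val$valid, errors = val$errors),
            class = "tgf_sbml_handle")
}

#' @export
print.tgf_sbml_handle <- function(x, ...) {
  cat("SBML L", x$level, "V", x$version, " document: ", x$n_species,
      " species, ", x$n_reactions, " reactions, ", x$n_parameters,
      " parameters; ", if (x$valid) "valid" else "INVALID", "\n", sep = "")
  invisible(x)
}

.sbml_strip <- function(doc) {
  # work namespace-free for simpler XPath
  xml2::xml_ns_strip(doc)
  doc
}

#' Structural consistency validation of an SBML file
#'
#' Checks document structure, id uniqueness, reference resolution
#' (species to compartments, reactions and kinetic-law symbols to declared
#' ids), nonnegative parameter values and initial concentrations, and positive
#' compartment sizes.
#'
#' @param path SBML file path.
#' @param report Optional path for a JSON validation report.
#' @return A list with `valid` (logical) and `errors` (character vector).
#' @export
validate_sbml <- function(path, report = NULL) {
  errors <- character(0)
  doc <- tryCatch(.sbml_strip(xml2::read_xml(path)),
                  error = function(e) {
                    errors <<- c(errors, paste("parse failure:",
                                               conditionMessage(e)))
                    NULL
                  })
  if (!is.null(doc)) {
    if (xml2::xml_name(doc) != "sbml")
      errors <- c(errors, "root element is not <sbml>")
    model <- xml2::xml_find_first(doc, "./model")
    if (inherits(model, "xml_missing")) {
      errors <- c(errors, "no <model> element")
    } else {
      comp <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
      cids <- xml2::xml_attr(comp, "id")
      sizes <- as.numeric(xml2::xml_attr(comp, "size"))
      if (length(cids) == 0) errors <- c(errors, "no compartments")
      if (anyDuplicated(cids)) errors <- c(errors, "duplicate compartment ids")
      if (any(is.na(sizes)) || any(sizes <= 0))
        errors <- c(errors, "compartment sizes must be positive numbers")
      spn <- xml2::xml_find_all(model, "./listOfSpecies/species")
      sids <- xml2::xml_attr(spn, "id")
      if (anyDuplicated(sids)) errors <- c(errors, "duplicate species ids")
      bad <- setdiff(xml2::xml_attr(spn, "compartment"), cids)
      if (length(bad) > 0)
        errors <- c(errors, paste("species reference unknown compartment(s):",
                                  paste(bad, collapse = ", ")))
      conc <- as.numeric(xml2::xml_attr(spn, "initialConcentration"))
      if (any(is.na(conc)) || any(conc < 0))
        errors <- c(errors, "initial concentrations must be nonnegative numbers")
      par <- xml2::xml_find_all(model, "./listOfParameters/parameter")
      pids <- xml2::xml_attr(par, "id")
      pval <- as.numeric(xml2::xml_attr(par, "value"))
      if (anyDuplicated(pids)) errors <- c(errors, "duplicate parameter ids")
      if (any(is.na(pval)) || any(pval < 0))
        errors <- c(errors, "parameter values must be nonnegative numbers")
      known <- c(cids, sids, pids)
      for (rn in xml2::xml_find_all(model, "./listOfReactions/reaction")) {
        rid <- xml2::xml_attr(rn, "id")
        refs <- xml2::xml_attr(
          xml2::xml_find_all(rn, ".//speciesReference | .//modifierSpeciesReference"),
          "species")
        if (!all(refs %in% sids))
          errors <- c(errors, paste0("reaction ", rid,
                                     " references unknown species"))
        cis <- xml2::xml_text(xml2::xml_find_all(rn, "./kineticLaw//ci"))
        unres <- setdiff(trimws(cis), known)
        if (length(unres) > 0)
          errors <- c(errors, paste0("reaction ", rid,
                                     " kinetic law references unknown symbol(s): ",
                                     paste(unres, collapse = ", ")))
      }
    }
  }
  out <- list(valid = length(errors) == 0, errors = errors)
  if (!is.null(report))
    jsonlite::write_json(out, report, auto_unbox = TRUE)
  out
}

#' Import a model system from SBML
#'
#' Reconstructs a `tgf_model` from a document written by [export_sbml()] (or
#' any SBML L2/L3 file restricted to the same mass-action rate-law family:
#' each kinetic law a product of one compartment size, one rate-constant
#' parameter and species concentrations). The rebuilt system passes the same
#' conservation checks as a freshly built one.
#'
#' @param path SBML file path.
#' @return A `tgf_model`.
#' @export
import_sbml <- function(path) {
  val <- validate_sbml(path)
  if (!val$valid)
    stop("invalid SBML document: ", paste(val$errors, collapse = "; "),
         call. = FALSE)
  doc <- .sbml_strip(xml2::read_xml(path))
  model <- xml2::xml_find_first(doc, "./model")
  mid <- xml2::xml_attr(model, "id")
  mech <- sub("^tgfsmad_", "", sub("_depletion$", "", mid))
  if (!mech %in% c("BASE", "REPRESSOR", "COMPETITION", "INTEGRATED"))
    stop("cannot identify the model variant from model id '", mid, "'",
         call. = FALSE)
  variant <- model_variant(mech, ligand_depletion = grepl("_depletion$", mid))

  comp <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  compartments <- data.frame(
    name = xml2::xml_attr(comp, "id"),
    volume = as.numeric(xml2::xml_attr(comp, "size")),
    stringsAsFactors = FALSE)

  spn <- xml2::xml_find_all(model, "./listOfSpecies/species")
  boundary <- xml2::xml_attr(spn, "boundaryCondition") == "true"
  species <- data.frame(
    name = xml2::xml_attr(spn, "id")[!boundary],
    compartment = xml2::xml_attr(spn, "compartment")[!boundary],
    stringsAsFactors = FALSE)
  y0 <- stats::setNames(
    as.numeric(xml2::xml_attr(spn, "initialConcentration"))[!boundary],
    species$name)
  boundary_ids <- xml2::xml_attr(spn, "id")[boundary]

  par <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(par, "value")),
                           xml2::xml_attr(par, "id"))
  manifest <- .param_manifest()$name
  params <- tryCatch(new_parameters(pvals[names(pvals) %in% manifest]),
                     error = function(e)
                       stop("invalid parameter block: ", conditionMessage(e),
                            call. = FALSE))
  params <- validate_parameters(params, variant$mechanism)

  rx <- list()
  for (rn in xml2::xml_find_all(model, "./listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rn, "id")
    get_refs <- function(xp) {
      nodes <- xml2::xml_find_all(rn, xp)
      st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(st, xml2::xml_attr(nodes, "species"))
    }
    reactants <- get_refs("./listOfReactants/speciesReference")
    products <- get_refs("./listOfProducts/speciesReference")

    math <- xml2::xml_find_first(rn, "./kineticLaw/math")
    if (inherits(math, "xml_missing"))
      stop("reaction ", rid, ": no kinetic law", call. = FALSE)
    bad_ops <- xml2::xml_find_all(
      math, ".//*[not(self::apply or self::times or self::ci)]")
    if (length(bad_ops) > 0 ||
        length(xml2::xml_find_all(math, ".//apply")) > 1)
      stop("reaction ", rid, ": rate law outside the supported mass-action ",
           "family", call. = FALSE)
    cis <- trimws(xml2::xml_text(xml2::xml_find_all(math, ".//ci")))
    comp_ci <- cis[cis %in% compartments$name]
    k_ci <- cis[cis %in% names(pvals)]
    sp_ci <- cis[cis %in% c(species$name, boundary_ids)]
    if (length(comp_ci) != 1 || length(k_ci) != 1 ||
        length(comp_ci) + length(k_ci) + length(sp_ci) != length(cis))
      stop("reaction ", rid, ": rate law outside the supported mass-action ",
           "family", call. = FALSE)

    ligand_driven <- any(sp_ci %in% boundary_ids)
    kin_species <- sp_ci[!sp_ci %in% boundary_ids]
    kinetics <- if (length(kin_species) > 0) {
      tab <- table(kin_species)
      stats::setNames(as.numeric(tab), names(tab))
    } else numeric(0)

    stoich <- stats::setNames(numeric(0), character(0))
    for (nm in names(reactants))
      stoich[nm] <- (if (nm %in% names(stoich)) stoich[nm] else 0) - reactants[[nm]]
    for (nm in names(products))
      stoich[nm] <- (if (nm %in% names(stoich)) stoich[nm] else 0) + products[[nm]]
    stoich <- stoich[!names(stoich) %in% boundary_ids]

    order_total <- sum(kinetics)
    comps <- unique(species$compartment[species$name %in% names(stoich)])
    rate_law <- if (order_total == 0) "synthesis"
      else if (all(stoich <= 0) && length(kinetics) == 1) "degradation"
      else if (order_total == 1 && length(comps) > 1) "transport"
      else if (order_total == 1) "mass_action_uni"
      else "mass_action_bi"

    rx[[length(rx) + 1]] <- .reaction(rid, k_ci, kinetics, stoich, comp_ci,
                                      rate_law, ligand_driven)
  }

  .assemble_system(variant, species, y0, rx, params, compartments)
}
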