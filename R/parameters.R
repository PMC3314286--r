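# Kinetic parameter sets for the merged receptor-trafficking + Smad-shuttling
# model. Everything is expressed in nM and seconds. Receptor synthesis rates
# come from the trafficking literature in molecules/cell/min and are converted
# at definition time through the 2.27e-12 L cell volume.

.param_manifest <- function() {
  m <- rbind(
    c("p_RI",              "nM/s",      "constitutive synthesis of type I receptor"),
    c("p_RII",             "nM/s",      "constitutive synthesis of type II receptor"),
    c("k_a",               "1/(nM^2 s)","ligand + RI + RII association into the surface signaling complex"),
    c("k_cd",              "1/s",       "constitutive receptor degradation"),
    c("k_lid",             "1/s",       "ligand-induced degradation of the surface complex"),
    c("k_i",               "1/s",       "receptor internalization (surface -> endosome)"),
    c("k_r",               "1/s",       "receptor recycling (endosome -> surface); ligand is lost on recycling"),
    c("k_phos",            "1/(nM s)",  "Smad2 phosphorylation by the endosomal ligand-receptor complex"),
    c("k_dephos",          "1/(nM s)",  "nuclear dephosphorylation of monomeric phospho-Smad2 by PPase"),
    c("k_on",              "1/(nM s)",  "phospho-Smad2 + Smad4 (and pSmad2 homomeric) complex formation"),
    c("k_off",             "1/s",       "Smad complex dissociation"),
    c("k_in_S2",           "1/s",       "nuclear import of monomeric Smad2 / phospho-Smad2"),
    c("k_ex_S2",           "1/s",       "nuclear export of monomeric Smad2 / phospho-Smad2"),
    c("k_in_S4",           "1/s",       "nuclear import of Smad4"),
    c("k_ex_S4",           "1/s",       "nuclear export of Smad4"),
    c("CIF",               "1",         "complex import factor: fold-acceleration of complex nuclear import"),
    c("k_on_pS24nTIF1g",   "1/(nM s)",  "TIF1g binding to nuclear phospho-Smad2/Smad4 complexes"),
    c("k_off_pS24nTIF1g",  "1/s",       "dissociation of the ternary pS24nTIF1g complex back to pS24n + TIF1g"),
    c("k_off_pS2nTIF1g",   "1/s",       "dissociation of nuclear phospho-Smad2/TIF1g complexes"),
    c("k_on_pS2nTIF1g",    "1/(nM s)",  "TIF1g + nuclear phospho-Smad2 association (competition mechanism)"),
    c("k_on_S4nTIF1g",     "1/(nM s)",  "TIF1g + nuclear Smad4 association (competition mechanism)"),
    c("k_off_S4nTIF1g",    "1/s",       "TIF1g/Smad4 complex dissociation (competition mechanism)"),
    c("k_ub",              "1/s",       "Smad4 mono-ubiquitination within the ternary complex, releasing pS2nTIF1g + Smad4ub"),
    c("k_in_S4ub",         "1/s",       "nuclear export of ubiquitinated Smad4 (2x Smad4 nuclear import by default)"),
    c("k_dub",             "1/(nM s)",  "deubiquitination of cytoplasmic Smad4ub by FAM/USP9x")
  )
  data.frame(name = m[, 1], unit = m[, 2], description = m[, 3],
             stringsAsFactors = FALSE)
}

#' Default kinetic parameter set
#'
#' Rate constants for the merged model, in nM and seconds. Receptor-trafficking
#' constants follow the published trafficking model (internalization 1/3 per
#' min, recycling 1/33 per min, constitutive degradation 1/36 per min,
#' ligand-induced degradation 1/4 per min, synthesis 8 molecules per min
#' converted to nM/s in the 2.27e-12 L cell volume). Smad shuttling constants
#' follow the published shuttling model (complex association 1.8e-3 per nM per
#' s, dissociation 1.6e-2 per s, PPase-mediated dephosphorylation 6.57e-3 per
#' nM per s, complex import factor 5.7). Conventions tied to the TIF1g
#' mechanisms: ternary-complex formation/dissociation constants equal the
#' phospho-Smad2/Smad4 constants; ubiquitination and deubiquitination kinetics
#' mirror phosphorylation and dephosphorylation; nuclear export of
#' ubiquitinated Smad4 (`k_in_S4ub`) is twice the Smad4 nuclear import
#' constant, reflecting the weaker nuclear retention of Smad4ub.
#'
#' @return A named numeric vector of class `tgf_parameters` with a `units`
#'   attribute.
#' @export
default_parameters <- function() {
  k_in_S4 <- 2.6e-3
  k_dephos <- 6.57e-3
  v <- c(
    p_RI   = molecules_to_concentration(8) / 60,
    p_RII  = molecules_to_concentration(8) / 60,
    k_a    = 0.15,
    k_cd   = 1 / 36 / 60,
    k_lid  = 1 / 4 / 60,
    k_i    = 1 / 3 / 60,
    k_r    = 1 / 33 / 60,
    k_phos = 4.0e-3,
    k_dephos = k_dephos,
    k_on   = 1.8e-3,
    k_off  = 1.6e-2,
    k_in_S2 = 2.6e-3,
    k_ex_S2 = 5.6e-3,
    k_in_S4 = k_in_S4,
    k_ex_S4 = 2.6e-3,
    CIF    = 5.7,
    k_on_pS24nTIF1g  = 1.8e-3,
    k_off_pS24nTIF1g = 1.6e-2,
    k_off_pS2nTIF1g  = 1.6e-2,
    k_on_pS2nTIF1g   = 1.8e-3,
    k_on_S4nTIF1g    = 1.8e-3,
    k_off_S4nTIF1g   = 1.6e-2,
    k_ub     = k_dephos * 1,      # ubiquitination ~ dephosphorylation at 1 nM enzyme
    k_in_S4ub = 2 * k_in_S4,      # 2-fold the Smad4 nuclear import constant
    k_dub    = k_dephos
  )
  new_parameters(v)
}

new_parameters <- function(values) {
  man <- .param_manifest()
  unknown <- setdiff(names(values), man$name)
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("parameter values must be finite and nonnegative", call. = FALSE)
  structure(values,
            units = stats::setNames(man$unit, man$name)[names(values)],
            class = "tgf_parameters")
}

#' @export
print.tgf_parameters <- function(x, ...) {
  df <- data.frame(value = as.numeric(x), unit = attr(x, "units"),
                   row.names = names(x))
  cat("Kinetic parameter set (", length(x), " constants)\n", sep = "")
  print(df, ...)
  invisible(x)
}

# Symbols each mechanism requires, beyond the shared trafficking/shuttling core.
.core_symbols <- c("p_RI", "p_RII", "k_a", "k_cd", "k_lid", "k_i", "k_r",
                   "k_phos", "k_dephos", "k_on", "k_off",
                   "k_in_S2", "k_ex_S2", "k_in_S4", "k_ex_S4", "CIF")

required_symbols <- function(mechanism) {
  extra <- switch(mechanism,
    BASE        = character(0),
    REPRESSOR   = c("k_on_pS24nTIF1g", "k_in_S4ub", "k_dub"),
    COMPETITION = c("k_on_pS2nTIF1g", "k_off_pS2nTIF1g",
                    "k_on_S4nTIF1g", "k_off_S4nTIF1g"),
    INTEGRATED  = c("k_on_pS24nTIF1g", "k_off_pS24nTIF1g", "k_off_pS2nTIF1g",
                    "k_ub", "k_in_S4ub", "k_dub"),
    stop("unknown variant mechanism: ", mechanism, call. = FALSE))
  c(.core_symbols, extra)
}

validate_parameters <- function(params, mechanism) {
  if (!inherits(params, "tgf_parameters"))
    params <- new_parameters(params)
  missing <- setdiff(required_symbols(mechanism), names(params))
  if (length(missing) > 0)
    stop("missing parameter symbol(s) for ", mechanism, " variant: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(params)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named constants replaced. Unknown
#' symbols are an error (typo protection).
#'
#' @param params A `tgf_parameters` object.
#' @param ... Named replacements, e.g. `k_in_S4ub = 1e-3`.
#' @return The modified parameter set.
#' @export
set_parameters <- function(params, ...) {
  repl <- c(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  params[names(repl)] <- repl
  new_parameters(stats::setNames(as.numeric(params), names(params)))
}

#' Read a parameter configuration file
#'
#' Flat `key: value` text (YAML subset). Values may carry a unit suffix after
#' whitespace, which must match the manifest unit for that symbol. Unknown keys
#' are rejected.
#'
#' @param path File path.
#' @param base Parameter set to override; defaults to [default_parameters()].
#' @return A `tgf_parameters` object.
#' @export
read_parameters <- function(path, base = default_parameters()) {
  raw <- yaml::read_yaml(path)
  man <- .param_manifest()
  vals <- numeric(0)
  for (key in names(raw)) {
    if (!key %in% man$name)
      stop("unknown parameter key in ", path, ": ", key, call. = FALSE)
    entry <- raw[[key]]
    if (is.character(entry)) {
      parts <- strsplit(trimws(entry), "\\s+")[[1]]
      val <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(val)) stop("unparseable value for ", key, call. = FALSE)
      if (length(parts) > 1) {
        unit <- paste(parts[-1], collapse = " ")
        expected <- man$unit[man$name == key]
        if (!identical(unit, expected))
          stop("unit mismatch for ", key, ": got '", unit,
               "', expected '", expected, "'", call. = FALSE)
      }
    } else {
      val <- as.numeric(entry)
    }
    vals[key] <- val
  }
  do.call(set_parameters, c(list(base), as.list(vals)))
}

#' Write a parameter set to a configuration file
#'
#' @param params A `tgf_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  units <- attr(params, "units")
  lines <- sprintf("%s: %.17g %s", names(params), as.numeric(params), units)
  writeLines(lines, path)
  invisible(path)
}
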