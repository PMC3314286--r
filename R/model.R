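# Construction of the merged receptor-trafficking + Smad-shuttling reaction
# network and its TIF1g variants. The two source modules are joined through
# the endosomal ligand-receptor complex (LRe), which is the kinase seen by
# cytoplasmic Smad2. All concentrations are nM, all times seconds. Transport
# reactions are evaluated in the volume of their source compartment and
# rescaled per species so that amounts (concentration x volume) are conserved.

#' Default compartment table
#'
#' Five compartments. Receptor pools (plasma membrane, endosome) are referenced
#' to the 2.27e-12 L cell volume used for the molecules-to-nM conversion of the
#' trafficking module; the cytoplasm uses the same volume and the nucleus
#' 1.0e-12 L, following the shuttling source model. The extracellular volume
#' only matters when ligand depletion is enabled (it sets how much ligand a
#' single cell can drain) and defaults to 1e-11 L of medium per cell.
#'
#' @return A data.frame with columns `name` and `volume` (liters).
#' @export
default_compartments <- function() {
  data.frame(
    name = c("extracellular", "plasma_membrane", "endosome", "cytoplasm", "nucleus"),
    volume = c(1e-11, default_cell_volume(), default_cell_volume(),
               default_cell_volume(), 1.0e-12),
    stringsAsFactors = FALSE
  )
}

#' Describe a model variant
#'
#' @param mechanism One of `"INTEGRATED"` (transient ternary complex +
#'   ubiquitination + FAM recycling), `"REPRESSOR"` (TIF1g catalytically
#'   converts nuclear pSmad2/Smad4 complexes into Smad4ub + pSmad2, the
#'   complex intermediate elided like the PPase treatment), `"COMPETITION"`
#'   (TIF1g reversibly sequesters nuclear phospho-Smad2 and Smad4, no
#'   ubiquitination), or `"BASE"` (no TIF1g reactions at all).
#' @param ligand_depletion If `TRUE`, extracellular TGF-beta is a state
#'   variable consumed by receptor-complex formation instead of a clamped
#'   input.
#' @param fam_included Whether the Smad4ub/FAM recycling arm is present;
#'   defaults to the mechanism's convention and cannot be enabled for
#'   `COMPETITION`/`BASE`.
#' @return A `tgf_variant` object.
#' @export
model_variant <- function(mechanism = c("INTEGRATED", "REPRESSOR", "COMPETITION", "BASE"),
                          ligand_depletion = FALSE,
                          fam_included = NULL) {
  mechanism <- match.arg(mechanism)
  default_fam <- mechanism %in% c("INTEGRATED", "REPRESSOR")
  if (is.null(fam_included)) fam_included <- default_fam
  if (fam_included && !default_fam)
    stop("the ", mechanism, " variant has no Smad4ub/FAM reactions", call. = FALSE)
  structure(list(mechanism = mechanism,
                 ligand_depletion = isTRUE(ligand_depletion),
                 fam_included = fam_included),
            class = "tgf_variant")
}

as_variant <- function(x) {
  if (inherits(x, "tgf_variant")) return(x)
  if (is.character(x) && length(x) == 1) return(model_variant(x))
  stop("unknown variant specification", call. = FALSE)
}

#' @export
print.tgf_variant <- function(x, ...) {
  cat("Model variant:", x$mechanism,
      if (x$ligand_depletion) "(ligand depletion)" else "",
      if (x$fam_included) "(FAM recycling)" else "", "\n")
  invisible(x)
}

.species_table <- function(variant) {
  sp <- function(name, compartment) data.frame(name = name, compartment = compartment,
                                               stringsAsFactors = FALSE)
  tab <- rbind(
    sp("RI",    "plasma_membrane"),
    sp("RII",   "plasma_membrane"),
    sp("LRC",   "plasma_membrane"),
    sp("RIe",   "endosome"),
    sp("RIIe",  "endosome"),
    sp("LRe",   "endosome"),
    sp("S2c",   "cytoplasm"),
    sp("pS2c",  "cytoplasm"),
    sp("S4c",   "cytoplasm"),
    sp("pS24c", "cytoplasm"),
    sp("pS22c", "cytoplasm"),
    sp("S2n",   "nucleus"),
    sp("pS2n",  "nucleus"),
    sp("S4n",   "nucleus"),
    sp("pS24n", "nucleus"),
    sp("pS22n", "nucleus"),
    sp("PPase", "nucleus")
  )
  if (variant$mechanism != "BASE") tab <- rbind(tab, sp("TIF1g_n", "nucleus"))
  if (variant$mechanism == "INTEGRATED")
    tab <- rbind(tab, sp("pS24nTIF1g", "nucleus"), sp("pS2nTIF1g", "nucleus"))
  if (variant$mechanism == "COMPETITION")
    tab <- rbind(tab, sp("pS2nTIF1g", "nucleus"), sp("S4nTIF1g", "nucleus"))
  if (variant$fam_included)
    tab <- rbind(tab, sp("S4ubn", "nucleus"), sp("S4ubc", "cytoplasm"), sp("FAM", "cytoplasm"))
  if (variant$ligand_depletion) tab <- rbind(tab, sp("TGFb", "extracellular"))
  tab
}

# Conservation groups: per-species copy numbers of each conserved moiety.
# Complexes count once per constituent; homomeric pS22 counts Smad2 twice.
.conservation_groups <- function(species_names) {
  count_in <- function(counts) counts[names(counts) %in% species_names]
  groups <- list(
    Smad2 = c(S2c = 1, S2n = 1, pS2c = 1, pS2n = 1, pS24c = 1, pS24n = 1,
              pS22c = 2, pS22n = 2, pS24nTIF1g = 1, pS2nTIF1g = 1),
    Smad4 = c(S4c = 1, S4n = 1, pS24c = 1, pS24n = 1, pS24nTIF1g = 1,
              S4ubn = 1, S4ubc = 1, S4nTIF1g = 1),
    TIF1g = c(TIF1g_n = 1, pS24nTIF1g = 1, pS2nTIF1g = 1, S4nTIF1g = 1),
    FAM   = c(FAM = 1),
    PPase = c(PPase = 1)
  )
  groups <- lapply(groups, count_in)
  groups[vapply(groups, length, 1L) > 0]
}

# A reaction: flux = k * L^lig * prod(state[kinetics]^order), evaluated in the
# volume of `compartment`; `stoich` is the net stoichiometry applied to each
# species after volume rescaling.
.reaction <- function(id, k_name, kinetics, stoich, compartment,
                      rate_law, ligand_driven = FALSE) {
  list(id = id, k_name = k_name, kinetics = kinetics, stoich = stoich,
       compartment = compartment, rate_law = rate_law,
       ligand_driven = ligand_driven)
}

.reaction_table <- function(variant) {
  rx <- list()
  add <- function(...) rx[[length(rx) + 1L]] <<- .reaction(...)

  lig_kin <- if (variant$ligand_depletion) c(TGFb = 1) else numeric(0)
  lig_sto <- if (variant$ligand_depletion) c(TGFb = -1) else numeric(0)

  ## --- receptor trafficking -------------------------------------------------
  add("synth_RI",  "p_RI",  numeric(0), c(RI = 1),  "plasma_membrane", "synthesis")
  add("synth_RII", "p_RII", numeric(0), c(RII = 1), "plasma_membrane", "synthesis")
  add("lr_assoc",  "k_a",   c(RI = 1, RII = 1, lig_kin),
      c(RI = -1, RII = -1, LRC = 1, lig_sto), "plasma_membrane",
      "mass_action_bi", ligand_driven = !variant$ligand_depletion)
  add("deg_RI",   "k_cd",  c(RI = 1),  c(RI = -1),  "plasma_membrane", "degradation")
  add("deg_RII",  "k_cd",  c(RII = 1), c(RII = -1), "plasma_membrane", "degradation")
  add("deg_LRC",  "k_cd",  c(LRC = 1), c(LRC = -1), "plasma_membrane", "degradation")
  add("lid_LRC",  "k_lid", c(LRC = 1), c(LRC = -1), "plasma_membrane", "degradation")
  add("int_RI",   "k_i",   c(RI = 1),  c(RI = -1, RIe = 1),  "plasma_membrane", "transport")
  add("int_RII",  "k_i",   c(RII = 1), c(RII = -1, RIIe = 1), "plasma_membrane", "transport")
  add("int_LRC",  "k_i",   c(LRC = 1), c(LRC = -1, LRe = 1), "plasma_membrane", "transport")
  add("rec_RI",   "k_r",   c(RIe = 1),  c(RIe = -1, RI = 1),  "endosome", "transport")
  add("rec_RII",  "k_r",   c(RIIe = 1), c(RIIe = -1, RII = 1), "endosome", "transport")
  # recycling of the internalized complex returns free receptors; the ligand
  # molecule is degraded in the endosome and never returned to the medium
  add("rec_LRe",  "k_r",   c(LRe = 1), c(LRe = -1, RI = 1, RII = 1), "endosome", "transport")

  ## --- Smad phosphorylation cycle ------------------------------------------
  add("phos_S2",   "k_phos",   c(LRe = 1, S2c = 1), c(S2c = -1, pS2c = 1),
      "cytoplasm", "mass_action_bi")
  add("dephos_S2", "k_dephos", c(PPase = 1, pS2n = 1), c(pS2n = -1, S2n = 1),
      "nucleus", "mass_action_bi")

  ## --- Smad complexes (hetero + homo, both compartments) -------------------
  add("hetero_c_on",  "k_on",  c(pS2c = 1, S4c = 1), c(pS2c = -1, S4c = -1, pS24c = 1),
      "cytoplasm", "mass_action_bi")
  add("hetero_c_off", "k_off", c(pS24c = 1), c(pS24c = -1, pS2c = 1, S4c = 1),
      "cytoplasm", "mass_action_uni")
  add("hetero_n_on",  "k_on",  c(pS2n = 1, S4n = 1), c(pS2n = -1, S4n = -1, pS24n = 1),
      "nucleus", "mass_action_bi")
  add("hetero_n_off", "k_off", c(pS24n = 1), c(pS24n = -1, pS2n = 1, S4n = 1),
      "nucleus", "mass_action_uni")
  add("homo_c_on",  "k_on",  c(pS2c = 2), c(pS2c = -2, pS22c = 1),
      "cytoplasm", "mass_action_bi")
  add("homo_c_off", "k_off", c(pS22c = 1), c(pS22c = -1, pS2c = 2),
      "cytoplasm", "mass_action_uni")
  add("homo_n_on",  "k_on",  c(pS2n = 2), c(pS2n = -2, pS22n = 1),
      "nucleus", "mass_action_bi")
  add("homo_n_off", "k_off", c(pS22n = 1), c(pS22n = -1, pS2n = 2),
      "nucleus", "mass_action_uni")

  ## --- nucleocytoplasmic shuttling ------------------------------------------
  add("imp_S2",   "k_in_S2", c(S2c = 1),  c(S2c = -1, S2n = 1),  "cytoplasm", "transport")
  add("exp_S2",   "k_ex_S2", c(S2n = 1),  c(S2n = -1, S2c = 1),  "nucleus", "transport")
  add("imp_pS2",  "k_in_S2", c(pS2c = 1), c(pS2c = -1, pS2n = 1), "cytoplasm", "transport")
  add("exp_pS2",  "k_ex_S2", c(pS2n = 1), c(pS2n = -1, pS2c = 1), "nucleus", "transport")
  add("imp_S4",   "k_in_S4", c(S4c = 1),  c(S4c = -1, S4n = 1),  "cytoplasm", "transport")
  add("exp_S4",   "k_ex_S4", c(S4n = 1),  c(S4n = -1, S4c = 1),  "nucleus", "transport")
  # complexes are imported CIF-fold faster than monomers and are not exported
  add("imp_pS24", "k_in_complex", c(pS24c = 1), c(pS24c = -1, pS24n = 1),
      "cytoplasm", "transport")
  add("imp_pS22", "k_in_complex", c(pS22c = 1), c(pS22c = -1, pS22n = 1),
      "cytoplasm", "transport")

  ## --- TIF1g mechanisms -----------------------------------------------------
  mech <- variant$mechanism
  if (mech == "REPRESSOR") {
    # transient TIF1g binding elided (fast kinetics, like the PPase step):
    # one catalytic encounter ubiquitinates Smad4 and dissolves the complex
    add("ubiq_cat", "k_on_pS24nTIF1g", c(TIF1g_n = 1, pS24n = 1),
        c(pS24n = -1, pS2n = 1, S4ubn = 1), "nucleus", "mass_action_bi")
  } else if (mech == "COMPETITION") {
    add("pS2T_on",  "k_on_pS2nTIF1g",  c(TIF1g_n = 1, pS2n = 1),
        c(TIF1g_n = -1, pS2n = -1, pS2nTIF1g = 1), "nucleus", "mass_action_bi")
    add("pS2T_off", "k_off_pS2nTIF1g", c(pS2nTIF1g = 1),
        c(pS2nTIF1g = -1, TIF1g_n = 1, pS2n = 1), "nucleus", "mass_action_uni")
    add("S4T_on",   "k_on_S4nTIF1g",   c(TIF1g_n = 1, S4n = 1),
        c(TIF1g_n = -1, S4n = -1, S4nTIF1g = 1), "nucleus", "mass_action_bi")
    add("S4T_off",  "k_off_S4nTIF1g",  c(S4nTIF1g = 1),
        c(S4nTIF1g = -1, TIF1g_n = 1, S4n = 1), "nucleus", "mass_action_uni")
  } else if (mech == "INTEGRATED") {
    add("tern_on",  "k_on_pS24nTIF1g",  c(TIF1g_n = 1, pS24n = 1),
        c(TIF1g_n = -1, pS24n = -1, pS24nTIF1g = 1), "nucleus", "mass_action_bi")
    add("tern_off", "k_off_pS24nTIF1g", c(pS24nTIF1g = 1),
        c(pS24nTIF1g = -1, TIF1g_n = 1, pS24n = 1), "nucleus", "mass_action_uni")
    # ubiquitination inside the ternary complex releases both products;
    # pS2nTIF1g is generated only by this dissolution, never by direct binding
    add("ubiq_tern", "k_ub", c(pS24nTIF1g = 1),
        c(pS24nTIF1g = -1, pS2nTIF1g = 1, S4ubn = 1), "nucleus", "mass_action_uni")
    add("pS2T_off", "k_off_pS2nTIF1g", c(pS2nTIF1g = 1),
        c(pS2nTIF1g = -1, TIF1g_n = 1, pS2n = 1), "nucleus", "mass_action_uni")
  }
  if (variant$fam_included) {
    add("exp_S4ub", "k_in_S4ub", c(S4ubn = 1), c(S4ubn = -1, S4ubc = 1),
        "nucleus", "transport")
    add("dub_S4ub", "k_dub", c(FAM = 1, S4ubc = 1), c(S4ubc = -1, S4c = 1),
        "cytoplasm", "mass_action_bi")
  }
  rx
}

#' Default initial concentrations
#'
#' All Smads start in the cytoplasm (pre-equilibration redistributes them):
#' 60.6 nM total Smad2 and 50 nM total Smad4, the latter matching the
#' default initialization the TIF1g scans are expressed against. The nuclear
#' phosphatase is fixed at 1 nM and FAM defaults to 1 nM. Receptors start at
#' their ligand-free steady state. TIF1g defaults to 0 and is the main
#' experimental dial.
#'
#' @param variant A `tgf_variant` or mechanism string.
#' @param params Parameter set (used for the receptor steady state).
#' @return Named numeric vector of initial concentrations (nM).
#' @export
default_initial_state <- function(variant = "INTEGRATED", params = default_parameters()) {
  variant <- as_variant(variant)
  tab <- .species_table(variant)
  init <- stats::setNames(numeric(nrow(tab)), tab$name)
  # ligand-free receptor steady state: d(R)/dt = p - kcd*R (recycling nets out)
  init["RI"]  <- params[["p_RI"]] / params[["k_cd"]]
  init["RII"] <- params[["p_RII"]] / params[["k_cd"]]
  init["RIe"]  <- params[["k_i"]] * init["RI"] / params[["k_r"]]
  init["RIIe"] <- params[["k_i"]] * init["RII"] / params[["k_r"]]
  init["S2c"] <- 60.6
  init["S4c"] <- 50
  init["PPase"] <- 1
  if ("FAM" %in% tab$name) init["FAM"] <- 1
  init
}

#' Build a TGF-beta/Smad model system
#'
#' Assembles the merged receptor-trafficking + Smad-shuttling reaction network
#' for one TIF1g mechanism into an evaluable system with conservation
#' structure. Conservation of the Smad2, Smad4, TIF1g, FAM and PPase moieties
#' (none of which is synthesized or degraded; receptors are exempt) is checked
#' against the stoichiometric matrix at build time.
#'
#' @param variant A `tgf_variant` from [model_variant()], or a mechanism
#'   string.
#' @param params Parameter set from [default_parameters()] /
#'   [set_parameters()].
#' @param init Named numeric vector of initial-concentration overrides (nM),
#'   e.g. `c(TIF1g_n = 25)`. Unknown species are an error.
#' @param compartments Compartment table, defaults to
#'   [default_compartments()].
#' @return A `tgf_model` object.
#' @examples
#' m <- build_model("INTEGRATED", init = c(TIF1g_n = 10))
#' m
#' @export
build_model <- function(variant = "INTEGRATED", params = default_parameters(),
                        init = NULL, compartments = default_compartments()) {
  variant <- as_variant(variant)
  params <- validate_parameters(params, variant$mechanism)

  stopifnot(all(compartments$volume > 0),
            !anyDuplicated(compartments$name))
  species <- .species_table(variant)
  if (!all(species$compartment %in% compartments$name))
    stop("species reference unknown compartments", call. = FALSE)

  y0 <- default_initial_state(variant, params)
  if (!is.null(init)) {
    bad <- setdiff(names(init), species$name)
    if (length(bad) > 0)
      stop("unknown species in init: ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(init < 0))
      stop("negative initial value for: ",
           paste(names(init)[init < 0], collapse = ", "), call. = FALSE)
    y0[names(init)] <- init
  }

  rx <- .reaction_table(variant)
  .assemble_system(variant, species, y0, rx, params, compartments)
}

# shared assembly: resolves rate constants, builds the (volume-rescaled)
# stoichiometric matrices and verifies moiety conservation. Used by both
# build_model() and the SBML importer.
.assemble_system <- function(variant, species, y0, rx, params, compartments) {
  # resolve rate constants (derived symbol: complex import = CIF * k_in_S2)
  kvals <- vapply(rx, function(r) {
    if (r$k_name == "k_in_complex") return(params[["CIF"]] * params[["k_in_S2"]])
    if (!r$k_name %in% names(params))
      stop("missing parameter symbol: ", r$k_name, call. = FALSE)
    params[[r$k_name]]
  }, numeric(1))

  nsp <- nrow(species)
  nrx <- length(rx)
  spidx <- stats::setNames(seq_len(nsp), species$name)
  vols <- stats::setNames(compartments$volume, compartments$name)
  spvol <- vols[species$compartment]

  S <- matrix(0, nsp, nrx, dimnames = list(species$name, vapply(rx, `[[`, "", "id")))
  M <- S  # volume-rescaled version used by the rhs
  for (j in seq_len(nrx)) {
    st <- rx[[j]]$stoich
    st <- st[st != 0]
    vr <- vols[[rx[[j]]$compartment]]
    for (nm in names(st)) {
      S[spidx[[nm]], j] <- S[spidx[[nm]], j] + st[[nm]]
      M[spidx[[nm]], j] <- M[spidx[[nm]], j] + st[[nm]] * vr / spvol[[spidx[[nm]]]]
    }
  }

  groups <- .conservation_groups(species$name)
  for (g in names(groups)) {
    w <- stats::setNames(numeric(nsp), species$name)
    w[names(groups[[g]])] <- groups[[g]]
    resid <- drop(w %*% S)
    if (max(abs(resid)) > 1e-12)
      stop("conservation violated for group ", g, " by reaction(s): ",
           paste(colnames(S)[abs(resid) > 1e-12], collapse = ", "), call. = FALSE)
  }

  kin_idx <- lapply(rx, function(r) unname(spidx[names(r$kinetics)]))
  kin_pow <- lapply(rx, function(r) unname(r$kinetics))

  structure(list(
    variant = variant,
    species = transform(species, initial = unname(y0)),
    reactions = rx,
    params = params,
    compartments = compartments,
    conservation = groups,
    smat = S, mmat = M,
    k = kvals, kin_idx = kin_idx, kin_pow = kin_pow,
    ligand_driven = vapply(rx, `[[`, TRUE, "ligand_driven")
  ), class = "tgf_model")
}

#' @export
print.tgf_model <- function(x, ...) {
  cat("TGF-beta/Smad model, variant", x$variant$mechanism,
      if (x$variant$ligand_depletion) "(ligand depletion)", "\n")
  cat("  ", nrow(x$species), "species,", length(x$reactions), "reactions,",
      length(x$conservation), "conserved moieties\n")
  invisible(x)
}

#' Species of a model system
#'
#' @param system A `tgf_model`.
#' @return A tidy data.frame (name, compartment, initial concentration in nM).
#' @export
model_species <- function(system) {
  stopifnot(inherits(system, "tgf_model"))
  system$species
}

#' Reaction listing of a model system
#'
#' @param system A `tgf_model`.
#' @return A tidy data.frame (id, rate law, rate constant symbol and value,
#'   reactants, products) suitable for CSV export.
#' @export
model_reactions <- function(system) {
  stopifnot(inherits(system, "tgf_model"))
  fmt_side <- function(st, sign) {
    st <- st[sign(st) == sign & st != 0]
    if (length(st) == 0) return("")
    paste(ifelse(abs(st) == 1, names(st), paste0(abs(st), " ", names(st))),
          collapse = " + ")
  }
  do.call(rbind, lapply(seq_along(system$reactions), function(j) {
    r <- system$reactions[[j]]
    data.frame(id = r$id, rate_law = r$rate_law, k_name = r$k_name,
               k_value = system$k[[j]], compartment = r$compartment,
               reactants = fmt_side(r$stoich, -1),
               products = fmt_side(r$stoich, +1),
               stringsAsFactors = FALSE)
  }))
}

.check_state <- function(system, state) {
  if (length(state) != nrow(system$species))
    stop("state length ", length(state), " does not match species count ",
         nrow(system$species), call. = FALSE)
  if (any(!is.finite(state)))
    stop("NaN/Inf in state", call. = FALSE)
  invisible(TRUE)
}

#' Per-reaction fluxes at a state
#'
#' @param system A `tgf_model`.
#' @param state Nonnegative state vector (nM), in species order.
#' @param t Time (unused by the autonomous rate laws; kept for signature
#'   symmetry).
#' @param ligand Extracellular TGF-beta (nM) for models without ligand
#'   depletion; ignored when the ligand is a state variable.
#' @return Named numeric vector of fluxes (nM/s in each reaction's
#'   compartment).
#' @export
reaction_fluxes <- function(system, state, t = 0, ligand = 0) {
  .check_state(system, state)
  state <- pmax(state, 0)
  n <- length(system$reactions)
  flux <- numeric(n)
  for (j in seq_len(n)) {
    f <- system$k[[j]]
    idx <- system$kin_idx[[j]]
    if (length(idx) > 0) {
      pw <- system$kin_pow[[j]]
      f <- f * prod(state[idx] ^ pw)
    }
    if (system$ligand_driven[[j]]) f <- f * ligand
    flux[j] <- f
  }
  stats::setNames(flux, colnames(system$smat))
}

#' Time derivative of the model state
#'
#' Evaluates the stoichiometry-weighted sum of all reaction fluxes. Entries
#' marginally below zero (integrator undershoot) are clamped to zero for
#' evaluation; undershoot beyond -1e-6 nM aborts, as it signals a solver
#' rather than a model problem.
#'
#' @inheritParams reaction_fluxes
#' @return Named derivative vector (nM/s).
#' @export
model_rhs <- function(system, state, t = 0, ligand = 0) {
  .check_state(system, state)
  if (any(state < -1e-6))
    stop("state has gone negative beyond tolerance (min ",
         format(min(state)), " nM)", call. = FALSE)
  flux <- reaction_fluxes(system, state, t, ligand)
  stats::setNames(drop(system$mmat %*% flux), system$species$name)
}

#' Conserved moiety totals
#'
#' Volume-weighted totals of the Smad2, Smad4, TIF1g, FAM and PPase pools,
#' counting each complex once per constituent (the ternary complex contributes
#' to all of Smad2, Smad4 and TIF1g; the homomeric pS22 complexes count Smad2
#' twice). Totals are reported as cytoplasm-equivalent concentrations
#' (amount / cytoplasmic volume, nM), so a model initialized with 50 nM
#' cytoplasmic Smad4 reports a Smad4 total of 50 nM at every time.
#'
#' @param system A `tgf_model`.
#' @param state State vector (nM).
#' @return Named numeric vector of totals (nM, cytoplasm-equivalent).
#' @export
conserved_totals <- function(system, state) {
  .check_state(system, state)
  vols <- stats::setNames(system$compartments$volume, system$compartments$name)
  spvol <- vols[system$species$compartment]
  vcyt <- vols[["cytoplasm"]]
  out <- vapply(system$conservation, function(grp) {
    idx <- match(names(grp), system$species$name)
    sum(grp * state[idx] * spvol[idx]) / vcyt
  }, numeric(1))
  out
}
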