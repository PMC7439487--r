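# Network realization
#
# Dynamic species (uM): six ACP-carrying species that form a closed, conserved
# pool, plus four phospholipid intermediates:
#   holo_acp, malonyl_acp, c14_oh_acp, c14_acp, c16_acp, c18_acp,
#   lpa, pa, cdp_dag, ps
# Boundary (fixed) species: acetyl_coa, g3p, c16_1_acp, ppgpp.
#
# Reactions (all irreversible one- or two-substrate Michaelis-Menten):
#   ACC          acetyl-CoA + holo-ACP -> malonyl-ACP    (lumped ACC + FabD;
#                competitively inhibited by C16:0-ACP and C18:0-ACP)
#   ELONG_C14OH  malonyl-ACP -> C14:0-OH-ACP             (lumped early cycles)
#   FABZ         C14:0-OH-ACP -> C14:0-ACP               (lumped FabZ/FabI)
#   LPXC         C14:0-OH-ACP -> LPS sink + holo-ACP     (lumped LpxA/LpxC)
#   ELONG_C16    C14:0-ACP + malonyl-ACP -> C16:0-ACP + holo-ACP
#   ELONG_C18    C16:0-ACP + malonyl-ACP -> C18:0-ACP + holo-ACP
#   PLSB_C16     C16:0-ACP + G3P -> LPA + holo-ACP       (ppGpp-inhibited)
#   PLSB_C18     C18:0-ACP + G3P -> LPA + holo-ACP       (ppGpp-inhibited)
#   PLSC         LPA (+ fixed C16:1-ACP) -> PA
#   CDSA         PA -> CDP-DAG
#   PSSA         CDP-DAG -> PS
#   PSD          PS -> PE sink
#
# PE flux is the PSD rate; LPS flux is the LPXC rate.  The two PlsB reactions
# share one Vmax scale, so scanning "PLSB" scales both.

ACP_SPECIES <- c("holo_acp", "malonyl_acp", "c14_oh_acp",
                 "c14_acp", "c16_acp", "c18_acp")

PL_SPECIES <- c("lpa", "pa", "cdp_dag", "ps")

DYNAMIC_SPECIES <- c(ACP_SPECIES, PL_SPECIES)

REACTIONS <- c("ACC", "ELONG_C14OH", "FABZ", "LPXC", "ELONG_C16", "ELONG_C18",
               "PLSB_C16", "PLSB_C18", "PLSC", "CDSA", "PSSA", "PSD")

FIXED_SPECIES <- c("acetyl_coa", "g3p", "c16_1_acp", "ppgpp")

#' Fixed boundary concentrations
#'
#' Concentrations held constant throughout any simulation: the fatty-acid
#' precursor acetyl-CoA, the PlsB acceptor substrate G3P (saturating), the
#' PlsC acyl donor C16:1-ACP, and the alarmone ppGpp (0 at steady state;
#' raised only in perturbation simulations).
#'
#' @param acetyl_coa,g3p,c16_1_acp,ppgpp Concentrations in uM, all >= 0.
#' @return A named list of class `fixed_inputs`.
#' @export
fixed_inputs <- function(acetyl_coa = 500, g3p = 1000, c16_1_acp = 1,
                         ppgpp = 0) {
  x <- list(acetyl_coa = acetyl_coa, g3p = g3p,
            c16_1_acp = c16_1_acp, ppgpp = ppgpp)
  bad <- names(x)[!vapply(x, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v) && v >= 0, logical(1))]
  if (length(bad)) {
    stop("fixed inputs must be single nonnegative numbers; bad: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(x, class = "fixed_inputs")
}

#' Default calibrated kinetic parameter set
#'
#' Vmax in uM/min, Km and Ki in uM.  The set is constructed from an anchor:
#' the baseline concentrations of [baseline_state()] are an exact steady
#' state carrying a PE flux of 10 uM/min and an LPS flux of 3 uM/min.
#' Each Km is fixed by choosing that reaction's substrate saturation at the
#' anchor (so every Km is of the order of the substrate's baseline
#' concentration), and each Vmax then follows as flux / saturation.  The two
#' free regulatory knobs - the PlsB acyl-ACP saturation (0.13) and the total
#' ACC feedback load from C16:0-/C18:0-ACP (I/Ki summing to 5) - are
#' calibrated (see `inst/scripts/calibrate.R`) so that a 4-fold increase in
#' either ACC or PlsB Vmax roughly doubles steady-state PE and LPS flux,
#' while leaving the downstream PL enzymes without flux control.
#'
#' @return Named list (one element per reaction) of kinetics blocks with
#'   fields `vmax`, `km_a`, optionally `km_b`/`ki_ppgpp`, and an
#'   `inhibitors` data frame (`species`, `ki`).
#' @export
default_kinetics <- function() {
  st <- baseline_state()
  fx <- fixed_inputs()
  flux <- c(ACC = 26, ELONG_C14OH = 13, FABZ = 10, LPXC = 3, ELONG_C16 = 10,
            ELONG_C18 = 3, PLSB_C16 = 7, PLSB_C18 = 3, PLSC = 10, CDSA = 10,
            PSSA = 10, PSD = 10)
  km_of <- function(s, th) unname(s) * (1 - th) / th  # Km giving occupancy th
  # calibrated regulatory knobs
  th_plsb <- 0.13   # PlsB saturation in its acyl-ACP substrate
  load <- 5         # total ACC competitive-inhibition load, split evenly
  th_acc_b <- 0.9   # ACC saturation in holo-ACP
  th_mid <- 0.15    # elongation-enzyme saturations (headroom for scans)
  occ_acoa <- fx$acetyl_coa / (fx$acetyl_coa * (1 + load) + fx$acetyl_coa)
  g3p_occ <- fx$g3p / (100 + fx$g3p)
  v <- function(rxn, occ) unname(flux[rxn]) / occ
  list(
    ACC = list(vmax = v("ACC", occ_acoa * th_acc_b), km_a = fx$acetyl_coa,
               km_b = km_of(st["holo_acp"], th_acc_b),
               inhibitors = data.frame(
                 species = c("c16_acp", "c18_acp"),
                 ki = unname(c(st["c16_acp"], st["c18_acp"]) / (load / 2)))),
    ELONG_C14OH = list(vmax = v("ELONG_C14OH", th_mid),
                       km_a = km_of(st["malonyl_acp"], th_mid)),
    FABZ = list(vmax = v("FABZ", 0.2), km_a = km_of(st["c14_oh_acp"], 0.2)),
    LPXC = list(vmax = v("LPXC", 0.2), km_a = km_of(st["c14_oh_acp"], 0.2)),
    ELONG_C16 = list(vmax = v("ELONG_C16", th_mid * 0.5),
                     km_a = km_of(st["c14_acp"], th_mid),
                     km_b = unname(st["malonyl_acp"])),
    ELONG_C18 = list(vmax = v("ELONG_C18", th_mid * 0.5),
                     km_a = km_of(st["c16_acp"], th_mid),
                     km_b = unname(st["malonyl_acp"])),
    PLSB_C16 = list(vmax = v("PLSB_C16", th_plsb * g3p_occ),
                    km_a = km_of(st["c16_acp"], th_plsb), km_b = 100,
                    ki_ppgpp = 50),
    PLSB_C18 = list(vmax = v("PLSB_C18", th_plsb * g3p_occ),
                    km_a = km_of(st["c18_acp"], th_plsb), km_b = 100,
                    ki_ppgpp = 50),
    PLSC = list(vmax = v("PLSC", 0.2 * 0.5), km_a = km_of(st["lpa"], 0.2),
                km_b = 1),
    CDSA = list(vmax = v("CDSA", 0.2), km_a = km_of(st["pa"], 0.2)),
    PSSA = list(vmax = v("PSSA", 0.2), km_a = km_of(st["cdp_dag"], 0.2)),
    PSD = list(vmax = v("PSD", 0.2), km_a = km_of(st["ps"], 0.2))
  )
}

#' Construct and validate a pathway model
#'
#' Assembles the fatty-acid / phospholipid / LPS reaction network: the
#' stoichiometry matrix (species x reactions), the kinetics of each reaction,
#' the fixed boundary concentrations and the conserved total ACP pool.
#' The stoichiometry closes the ACP pool by construction: every reaction's
#' net ACP-species change is zero, which the constructor verifies.
#'
#' @param kinetics Kinetics list as produced by [default_kinetics()].
#' @param fixed Fixed boundary concentrations, see [fixed_inputs()].
#' @param acp_total Conserved total of the six ACP-carrying species (uM).
#' @return An object of class `pathway_model`.
#' @export
pathway_model <- function(kinetics = default_kinetics(),
                          fixed = fixed_inputs(),
                          acp_total = 30) {
  if (!inherits(fixed, "fixed_inputs")) fixed <- do.call(fixed_inputs, fixed)
  if (!is.numeric(acp_total) || length(acp_total) != 1 || acp_total <= 0) {
    stop("acp_total must be a single positive number (uM)", call. = FALSE)
  }
  .validate_kinetics(kinetics)
  S <- .stoichiometry()
  # ACP conservation by construction: net ACP change of every column is 0
  acp_cols <- colSums(S[ACP_SPECIES, , drop = FALSE])
  stopifnot(all(acp_cols == 0))
  structure(
    list(species = DYNAMIC_SPECIES, reactions = REACTIONS,
         stoichiometry = S, kinetics = kinetics, fixed = fixed,
         acp_total = acp_total),
    class = "pathway_model"
  )
}

.stoichiometry <- function() {
  S <- matrix(0L, nrow = length(DYNAMIC_SPECIES), ncol = length(REACTIONS),
              dimnames = list(DYNAMIC_SPECIES, REACTIONS))
  add <- function(rxn, ...) {
    d <- c(...)
    S[names(d), rxn] <<- S[names(d), rxn] + as.integer(d)
  }
  add("ACC",         holo_acp = -1, malonyl_acp = +1)
  add("ELONG_C14OH", malonyl_acp = -1, c14_oh_acp = +1)
  add("FABZ",        c14_oh_acp = -1, c14_acp = +1)
  add("LPXC",        c14_oh_acp = -1, holo_acp = +1)     # LPS sink leaves pool
  add("ELONG_C16",   c14_acp = -1, malonyl_acp = -1, c16_acp = +1,
                     holo_acp = +1)
  add("ELONG_C18",   c16_acp = -1, malonyl_acp = -1, c18_acp = +1,
                     holo_acp = +1)
  add("PLSB_C16",    c16_acp = -1, holo_acp = +1, lpa = +1)
  add("PLSB_C18",    c18_acp = -1, holo_acp = +1, lpa = +1)
  add("PLSC",        lpa = -1, pa = +1)   # C16:1-ACP donor is boundary
  add("CDSA",        pa = -1, cdp_dag = +1)
  add("PSSA",        cdp_dag = -1, ps = +1)
  add("PSD",         ps = -1)             # PE sink
  S
}

.validate_kinetics <- function(kinetics) {
  missing_rxn <- setdiff(REACTIONS, names(kinetics))
  if (length(missing_rxn)) {
    stop("kinetics missing for reaction(s): ",
         paste(missing_rxn, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(kinetics), REACTIONS)
  if (length(unknown)) {
    stop("unknown reaction id(s) in kinetics: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  two_sub <- c("ACC", "ELONG_C16", "ELONG_C18", "PLSB_C16", "PLSB_C18", "PLSC")
  for (rxn in REACTIONS) {
    k <- kinetics[[rxn]]
    for (fld in c("vmax", "km_a")) {
      v <- k[[fld]]
      if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) ||
          v <= 0) {
        stop("reaction ", rxn, ": ", fld, " must be a single positive number",
             call. = FALSE)
      }
    }
    if (rxn %in% two_sub &&
        (is.null(k$km_b) || !is.numeric(k$km_b) || k$km_b <= 0)) {
      stop("reaction ", rxn, ": km_b must be a single positive number",
           call. = FALSE)
    }
    if (!is.null(k$inhibitors)) {
      if (rxn != "ACC") {
        stop("only ACC carries acyl-ACP inhibitors (found on ", rxn, ")",
             call. = FALSE)
      }
      inh <- k$inhibitors
      if (!all(c("species", "ki") %in% names(inh)) ||
          any(inh$ki <= 0) || !all(inh$species %in% DYNAMIC_SPECIES)) {
        stop("ACC inhibitors must name dynamic species with positive ki",
             call. = FALSE)
      }
    }
    if (!is.null(k$ki_ppgpp)) {
      if (!grepl("^PLSB", rxn)) {
        stop("only PLSB reactions carry a ppGpp inhibition constant (found on ",
             rxn, ")", call. = FALSE)
      }
      if (!is.numeric(k$ki_ppgpp) || k$ki_ppgpp <= 0) {
        stop("reaction ", rxn, ": ki_ppgpp must be positive", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Per-reaction rates at a given state
#'
#' Evaluates every reaction's Michaelis-Menten rate law at the supplied
#' dynamic-species concentrations.  PlsB rates carry the noncompetitive
#' ppGpp factor `1 / (1 + ppGpp / Ki_ppGpp)` whenever the model's fixed
#' ppGpp concentration is positive.
#'
#' @param state Named numeric vector over [dynamic_species()]
#'   (uM, nonnegative).
#' @param model A [pathway_model()].
#' @return Named numeric vector of rates (uM/min), one per reaction,
#'   all nonnegative for nonnegative states.
#' @export
reaction_rates <- function(state, model) {
  stopifnot(inherits(model, "pathway_model"))
  state <- .as_state(state)
  if (any(state < 0)) {
    stop("state concentrations must be nonnegative", call. = FALSE)
  }
  .rates(state, model)
}

# unchecked hot path
.rates <- function(state, model) {
  k <- model$kinetics
  fx <- model$fixed
  s <- pmax(state, 0)  # solver may undershoot by ~1e-12; rates use the floor
  inh <- k$ACC$inhibitors
  i_conc <- s[inh$species]
  i_ki <- inh$ki
  ppgpp_fac <- if (fx$ppgpp > 0) {
    1 / (1 + fx$ppgpp / k$PLSB_C16$ki_ppgpp)
  } else 1
  ppgpp_fac18 <- if (fx$ppgpp > 0) {
    1 / (1 + fx$ppgpp / k$PLSB_C18$ki_ppgpp)
  } else 1
  v <- c(
    ACC = .mm(k$ACC$vmax, fx$acetyl_coa, k$ACC$km_a, i_conc, i_ki) *
      s[["holo_acp"]] / (k$ACC$km_b + s[["holo_acp"]]),
    ELONG_C14OH = .mm(k$ELONG_C14OH$vmax, s[["malonyl_acp"]],
                      k$ELONG_C14OH$km_a),
    FABZ = .mm(k$FABZ$vmax, s[["c14_oh_acp"]], k$FABZ$km_a),
    LPXC = .mm(k$LPXC$vmax, s[["c14_oh_acp"]], k$LPXC$km_a),
    ELONG_C16 = .mm(k$ELONG_C16$vmax, s[["c14_acp"]], k$ELONG_C16$km_a) *
      s[["malonyl_acp"]] / (k$ELONG_C16$km_b + s[["malonyl_acp"]]),
    ELONG_C18 = .mm(k$ELONG_C18$vmax, s[["c16_acp"]], k$ELONG_C18$km_a) *
      s[["malonyl_acp"]] / (k$ELONG_C18$km_b + s[["malonyl_acp"]]),
    PLSB_C16 = .mm(k$PLSB_C16$vmax, s[["c16_acp"]], k$PLSB_C16$km_a) *
      fx$g3p / (k$PLSB_C16$km_b + fx$g3p) * ppgpp_fac,
    PLSB_C18 = .mm(k$PLSB_C18$vmax, s[["c18_acp"]], k$PLSB_C18$km_a) *
      fx$g3p / (k$PLSB_C18$km_b + fx$g3p) * ppgpp_fac18,
    PLSC = .mm(k$PLSC$vmax, s[["lpa"]], k$PLSC$km_a) *
      fx$c16_1_acp / (k$PLSC$km_b + fx$c16_1_acp),
    CDSA = .mm(k$CDSA$vmax, s[["pa"]], k$CDSA$km_a),
    PSSA = .mm(k$PSSA$vmax, s[["cdp_dag"]], k$PSSA$km_a),
    PSD = .mm(k$PSD$vmax, s[["ps"]], k$PSD$km_a)
  )
  names(v) <- REACTIONS
  v
}

#' Time derivatives of the dynamic species
#'
#' Mass balances: `stoichiometry %*% reaction_rates`.  The derivative of the
#' summed ACP pool is identically zero because every column of the
#' stoichiometry matrix is ACP-neutral.
#'
#' @inheritParams reaction_rates
#' @return Named numeric vector of d(concentration)/dt (uM/min) per species.
#' @export
time_derivatives <- function(state, model) {
  stopifnot(inherits(model, "pathway_model"))
  state <- .as_state(state)
  drop(model$stoichiometry %*% .rates(state, model))
}

#' Total concentration of the conserved ACP pool
#'
#' Sum of the six ACP-carrying species: holo-ACP, malonyl-ACP, C14:0-OH-ACP,
#' C14:0-ACP, C16:0-ACP and C18:0-ACP.  Conserved along every trajectory.
#'
#' @param state Named numeric vector of dynamic-species concentrations (uM).
#' @return Total ACP (uM).
#' @export
total_acp <- function(state) {
  state <- .as_state(state)
  sum(state[ACP_SPECIES])
}

.as_state <- function(state) {
  if (is.data.frame(state)) {
    state <- stats::setNames(state$concentration, state$species)
  }
  if (is.null(names(state))) {
    if (length(state) != length(DYNAMIC_SPECIES)) {
      stop("unnamed state must have length ", length(DYNAMIC_SPECIES),
           call. = FALSE)
    }
    names(state) <- DYNAMIC_SPECIES
  }
  missing_sp <- setdiff(DYNAMIC_SPECIES, names(state))
  if (length(missing_sp)) {
    stop("state missing species: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  state[DYNAMIC_SPECIES]
}

#' Baseline dynamic state of the default model
#'
#' The concentration vector at which the default parameter set was calibrated;
#' it is (to solver tolerance) the steady state of `pathway_model()`.
#'
#' @return Named numeric vector over the dynamic species (uM).
#' @export
baseline_state <- function() {
  c(holo_acp = 20, malonyl_acp = 5, c14_oh_acp = 1, c14_acp = 1,
    c16_acp = 2, c18_acp = 1, lpa = 0.5, pa = 1, cdp_dag = 0.5, ps = 0.5)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("<pathway_model> fatty-acid / PL / LPS network\n")
  cat("  species:  ", length(x$species), " dynamic (",
      length(ACP_SPECIES), " in conserved ACP pool, total ",
      x$acp_total, " uM)\n", sep = "")
  cat("  reactions:", length(x$reactions), "\n")
  fx <- unlist(x$fixed)
  cat("  fixed:    ", paste(names(fx), "=", fx, collapse = ", "), "uM\n")
  invisible(x)
}

# scale a scan target (enzyme Vmax or fixed input) by a multiplier.
# target "PLSB" scales both acyl-chain variants through the shared scale.
.apply_factor <- function(model, target, factor) {
  stopifnot(factor > 0)
  if (target %in% names(model$fixed)) {
    model$fixed[[target]] <- model$fixed[[target]] * factor
    return(model)
  }
  rxns <- if (identical(target, "PLSB")) c("PLSB_C16", "PLSB_C18") else target
  unknown <- setdiff(rxns, REACTIONS)
  if (length(unknown)) {
    stop("unknown scan target: ", target, call. = FALSE)
  }
  for (r in rxns) model$kinetics[[r]]$vmax <- model$kinetics[[r]]$vmax * factor
  model
}
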