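# Drug mechanisms as model/condition transformations.
#
# Four mechanisms: AXT050 binds alpha5beta1 integrin and depletes the
# Met-integrin heterodimer (mass-action competitive binding); cabozantinib
# binds Met with first-order kinetics, and bound Met cannot engage HGF or
# integrin; rilotumumab depletes free HGF under an excess-antibody
# equilibrium; sorafenib and the calibration-time node inhibitors reduce
# the signal leaving their target node by a multiplicative factor.

.NODE_DRUGS <- c(Met = "meti", PDK1 = "pdk1i", MEK = "meki",
                 PI3K = "pi3ki", ERK = "erki")
.NODE_STRENGTH <- c(Met = "s_Meti", PDK1 = "s_PDK1i", MEK = "s_MEKi",
                    PI3K = "s_PI3Ki", ERK = "s_ERKi", Raf = "s_Sor")

#' Apply AXT050 peptide to a condition
#'
#' AXT050 enters the network as a clamped extracellular species that binds
#' free surface integrin; sequestration of integrin shifts the Met pool away
#' from the protected Met-integrin route.  At dose 0 the condition is
#' unchanged.
#'
#' @param cond a [condition()].
#' @param dose peptide concentration in nM.
#' @param pre_incubation minutes of peptide exposure before HGF
#'   (default 90, the wet-lab protocol the model emulates).
#' @return the modified condition.
#' @export
apply_axt050 <- function(cond, dose, pre_incubation = 90) {
  stopifnot(dose >= 0)
  if (dose == 0) return(cond)
  cond$drugs <- c(cond$drugs, axt050 = dose)
  cond$pre_incubation <- c(cond$pre_incubation, axt050 = pre_incubation)
  cond
}

#' Apply cabozantinib to a condition
#'
#' @param cond a [condition()].
#' @param dose drug concentration in nM.
#' @param pre_incubation minutes before HGF (default 30).
#' @return the modified condition.
#' @export
apply_cabozantinib <- function(cond, dose, pre_incubation = 30) {
  stopifnot(dose >= 0)
  if (dose == 0) return(cond)
  cond$drugs <- c(cond$drugs, cabozantinib = dose)
  cond$pre_incubation <- c(cond$pre_incubation, cabozantinib = pre_incubation)
  cond
}

#' Free HGF under rilotumumab ligand depletion
#'
#' With antibody in excess over ligand, the equilibrium free-ligand
#' concentration is `hgf_total * kd / (kd + dose)`.
#'
#' @param dose antibody concentration in nM.
#' @param hgf_total total HGF in nM.
#' @param kd antibody-ligand dissociation constant in nM.
#' @return free HGF concentration in nM.
#' @export
apply_rilotumumab <- function(dose, hgf_total, kd) {
  if (kd <= 0) stop("kd must be > 0")
  stopifnot(dose >= 0, hgf_total >= 0)
  hgf_total * kd / (kd + dose)
}

#' Apply rilotumumab to a condition
#' @param cond a [condition()].
#' @param dose antibody concentration in nM.
#' @return the modified condition (depletion is resolved at simulation time
#'   from the model's antibody Kd).
#' @export
apply_rilotumumab_condition <- function(cond, dose) {
  stopifnot(dose >= 0)
  if (dose == 0) return(cond)
  cond$drugs <- c(cond$drugs, rilotumumab = dose)
  cond$pre_incubation <- c(cond$pre_incubation, rilotumumab = 0)
  cond
}

#' Apply a node-output inhibitor
#'
#' Multiplies every rate law carrying signal out of the node by
#' `1 - strength` (for the calibration-time inhibitors of Met, PDK1, MEK,
#' PI3K, and ERK, which are modeled as strength-scaled blockade at their
#' calibration doses) or by `1 - strength * dose/(dose + K_inh_Sor)` for
#' sorafenib acting on Raf, whose dose-occupancy mapping makes
#' dose-response curves generable.  Strength 0 restores the model.
#'
#' @param model a `pathway_model`.
#' @param node one of "Met", "PDK1", "MEK", "PI3K", "ERK", "Raf".
#' @param strength inhibition strength in [0, 1].
#' @param dose for node "Raf" (sorafenib), the dose in nM; for other nodes
#'   any dose > 0 switches the inhibitor on.
#' @return list with the modified `model` and the `condition` drug entry to
#'   merge (`drugs` element, named dose vector).
#' @export
apply_node_inhibitor <- function(model, node, strength = NULL, dose = 1) {
  if (!node %in% names(.NODE_STRENGTH))
    stop("unknown node '", node, "'; valid: ",
         paste(names(.NODE_STRENGTH), collapse = ", "))
  stopifnot(dose >= 0)
  if (!is.null(strength)) {
    if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
    model <- set_params(model, setNames(strength, .NODE_STRENGTH[[node]]))
  }
  drugs <- if (node == "Raf") c(sorafenib = dose) else
    setNames(as.numeric(dose > 0), .NODE_DRUGS[[node]])
  list(model = model, drugs = drugs)
}

#' Add a node inhibitor to a condition
#' @param cond a [condition()].
#' @param node target node name (see [apply_node_inhibitor()]).
#' @param dose dose in nM for "Raf" (sorafenib); 0/1 switch otherwise.
#' @param pre_incubation minutes before HGF (default 30).
#' @return the modified condition.
#' @export
with_node_inhibitor <- function(cond, node, dose = 1, pre_incubation = 30) {
  if (!node %in% names(.NODE_STRENGTH)) stop("unknown node '", node, "'")
  dn <- if (node == "Raf") "sorafenib" else .NODE_DRUGS[[node]]
  cond$drugs <- c(cond$drugs, setNames(dose, dn))
  cond$pre_incubation <- c(cond$pre_incubation, setNames(pre_incubation, dn))
  cond
}

#' Baseline vs integrin-knockout trajectories
#'
#' The knockout disables Met-integrin association (association rate 0)
#' while preserving the total number of Met receptors at HGF onset: the Met
#' subsystem is linear in its synthesis rate once association is off, so
#' the synthesis rate is rescaled to match the baseline basal Met pool.
#'
#' @param model a `pathway_model`.
#' @param cond a [condition()].
#' @return list with `baseline` and `knockout` trajectories and the
#'   knockout model (`model_ko`).
#' @export
integrin_knockout_scenario <- function(model, cond) {
  base <- simulate_condition(model, cond)
  pools <- unlist(model$met_pools)
  tot_ref <- sum(basal_state(model)[pools])
  ko <- set_params(model, c(kon_MetItg = 0))
  tot_ko <- sum(basal_state(ko)[pools])
  if (tot_ko > 0 && abs(tot_ko - tot_ref) / tot_ref > 1e-9) {
    ko <- set_params(ko, c(ksyn_Met = model_params(ko)[["ksyn_Met"]] *
                             tot_ref / tot_ko))
  }
  list(baseline = base, knockout = simulate_condition(ko, cond),
       model_ko = ko)
}

#' Percent inhibition of a readout by a treatment
#'
#' `100 * (1 - readout_drug(t) / readout_ref(t))`.  Negative values mean
#' the treatment increased the readout.
#'
#' @param model a `pathway_model`.
#' @param cond_drug treated condition.
#' @param cond_ref reference condition (same HGF, no drug).
#' @param readout readout name.
#' @param t time in minutes.
#' @return percent inhibition (scalar for scalar `t`).
#' @export
percent_inhibition <- function(model, cond_drug, cond_ref, readout, t) {
  r_ref <- readout_values(simulate_condition(model, cond_ref), readout, t)
  if (any(r_ref <= 0))
    stop("reference readout is <= 0; percent inhibition undefined")
  r_drug <- readout_values(simulate_condition(model, cond_drug), readout, t)
  unname(100 * (1 - r_drug / r_ref))
}
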