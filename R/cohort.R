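# Virtual patients: per-protein tumor/normal fold changes scale the
# calibrated model's protein abundances (conservation totals for the
# intracellular proteins, synthesis rates for the surface receptors);
# reaction rate constants stay untouched.

#' Build a patient-specific model by fold-change scaling
#'
#' @param model calibrated reference `pathway_model`.
#' @param profile named numeric vector of log2 fold changes (tumor vs
#'   matched normal); names must be scalable proteins (see
#'   `model$scalable`).  Proteins absent from the profile are unchanged.
#' @return the scaled `pathway_model`.
#' @export
scale_model <- function(model, profile) {
  if (!length(profile)) return(model)
  valid <- names(model$scalable)
  bad <- setdiff(names(profile), valid)
  if (length(bad))
    stop("unknown protein(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "))
  if (any(!is.finite(profile))) stop("fold changes must be finite")
  for (g in names(profile)) {
    fac <- 2^profile[[g]]
    tgt <- model$scalable[[g]]
    if (is.character(tgt) && length(tgt) == 1 &&
        tgt %in% model$parameters$name) {
      model <- set_params(model, setNames(
        model_params(model)[[tgt]] * fac, tgt))
    } else {
      idx <- model$species$name %in% tgt
      model <- set_initial(model, setNames(
        model$species$initial[idx] * fac, model$species$name[idx]))
    }
  }
  model
}

#' Reference monotherapy doses (top of each drug's studied range)
#' @return named numeric vector of doses in nM.
#' @export
reference_doses <- function() {
  c(axt050 = 50000, sorafenib = 1000, cabozantinib = 1000,
    rilotumumab = 10)
}

#' Cohort monotherapy response
#'
#' Percent inhibition of each readout at 120 min for every patient under
#' each drug at its reference dose.  Per-patient simulation failures are
#' flagged (NA row) and logged.
#'
#' @param model reference `pathway_model`.
#' @param profiles list of patient profiles (named log2 fold-change
#'   vectors) or a matrix (proteins x patients).
#' @param drugs drug names (default all four).
#' @param readouts readout names (default pAkt, pERK).
#' @param doses named dose vector (default [reference_doses()]).
#' @param t evaluation time (minutes).
#' @return data.frame: patient, drug, readout, percent_inhibition.
#' @export
cohort_monotherapy <- function(model, profiles,
                               drugs = names(reference_doses()),
                               readouts = c("pAkt", "pERK"),
                               doses = reference_doses(), t = 120) {
  profiles <- .as_profile_list(profiles)
  if (!length(profiles)) stop("need at least one patient profile")
  if (!length(drugs))
    return(data.frame(patient = character(), drug = character(),
                      readout = character(),
                      percent_inhibition = numeric()))
  base <- condition(hgf = 40, output_times = c(15, t))
  out <- list()
  for (pid in names(profiles)) {
    m <- tryCatch(scale_model(model, profiles[[pid]]),
                  error = function(e) NULL)
    for (dg in drugs) for (rd in readouts) {
      pi <- if (is.null(m)) NA_real_ else tryCatch(
        percent_inhibition(m, .drug_condition(base, dg, doses[[dg]]),
                           base, rd, t),
        error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        patient = pid, drug = dg, readout = rd, percent_inhibition = pi)
    }
  }
  do.call(rbind, out)
}

#' Cohort combination synergy
#'
#' Per-patient MuSyC fits for AXT050 combined with each partner drug, on
#' each readout at 120 min.
#'
#' @param model reference `pathway_model`.
#' @param profiles patient profiles (see [cohort_monotherapy()]).
#' @param partners partner drugs for AXT050.
#' @param readouts readout names.
#' @param n_dose doses per axis (grid is n_dose x n_dose plus zero
#'   anchors).
#' @param t evaluation time (minutes).
#' @return data.frame: patient, drug_pair, readout, log_alpha2, beta_obs
#'   (NA rows flag per-patient fit failures).
#' @export
cohort_synergy <- function(model, profiles,
                           partners = c("sorafenib", "cabozantinib",
                                        "rilotumumab"),
                           readouts = c("pAkt", "pERK"), n_dose = 6,
                           t = 120) {
  profiles <- .as_profile_list(profiles)
  if (!length(profiles)) stop("need at least one patient profile")
  out <- list()
  for (pid in names(profiles)) {
    m <- tryCatch(scale_model(model, profiles[[pid]]),
                  error = function(e) NULL)
    for (dg in partners) {
      surfs <- if (is.null(m)) NULL else tryCatch(
        quantify_synergy(m, "axt050", dg, readout = readouts, t = t,
                         doses1 = default_dose_grid("axt050", n_dose),
                         doses2 = default_dose_grid(dg, n_dose)),
        error = function(e) NULL)
      if (length(readouts) == 1 && !is.null(surfs))
        surfs <- setNames(list(surfs), readouts)
      for (rd in readouts) {
        surf <- surfs[[rd]]
        out[[length(out) + 1L]] <- data.frame(
          patient = pid, drug_pair = paste0("axt050+", dg), readout = rd,
          log_alpha2 = if (is.null(surf)) NA_real_ else surf$log_alpha2,
          beta_obs = if (is.null(surf)) NA_real_ else surf$beta_obs)
      }
    }
  }
  do.call(rbind, out)
}

.as_profile_list <- function(profiles) {
  if (is.matrix(profiles) || is.data.frame(profiles)) {
    m <- as.matrix(profiles)
    out <- lapply(seq_len(ncol(m)), function(j) setNames(m[, j],
                                                         rownames(m)))
    names(out) <- colnames(m) %||% paste0("patient", seq_len(ncol(m)))
    return(out)
  }
  if (is.null(names(profiles)))
    names(profiles) <- paste0("patient", seq_along(profiles))
  profiles
}
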