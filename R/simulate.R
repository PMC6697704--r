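# Condition handling and stiff ODE simulation.
#
# A condition is an experimental scenario: an HGF dose (ng/ml), drug doses
# (nM, or a 0/1 switch for the calibration-time node inhibitors), optional
# per-drug pre-incubation times (minutes before HGF addition), a horizon
# and output times.  Every simulation starts from the same relaxed basal
# state, obtained by pre-simulating the unstimulated model for 1000 min and
# cached on the model object.

.DRUGS <- c("axt050" = "AXT050", "cabozantinib" = "Cabo",
            "rilotumumab" = "Rilo", "sorafenib" = "Sor",
            "meti" = "Meti_s", "pdk1i" = "PDK1i_s", "meki" = "MEKi_s",
            "pi3ki" = "PI3Ki_s", "erki" = "ERKi_s")

#' Define an experimental condition
#'
#' @param hgf HGF dose in ng/ml (default 40, the reference stimulation).
#' @param drugs named numeric vector of drug doses; names among
#'   `axt050`, `cabozantinib`, `rilotumumab`, `sorafenib` (nM) and the
#'   node-inhibitor switches `meti`, `pdk1i`, `meki`, `pi3ki`, `erki` (0/1).
#' @param pre_incubation named numeric vector of minutes each drug is
#'   applied before HGF (default 30 min for any dosed drug).
#' @param t_end simulation horizon in minutes.
#' @param output_times times (minutes) at which readouts are reported.
#' @return an object of class `condition`.
#' @export
condition <- function(hgf = 40, drugs = numeric(), pre_incubation = NULL,
                      t_end = 120, output_times = seq(0, t_end, by = 5)) {
  if (hgf < 0) stop("hgf dose must be >= 0")
  if (length(drugs)) {
    bad <- setdiff(names(drugs), names(.DRUGS))
    if (length(bad)) stop("unknown drug(s): ", paste(bad, collapse = ", "))
    if (any(drugs < 0)) stop("drug doses must be >= 0")
  }
  if (t_end < max(output_times))
    stop("t_end must be >= max(output_times)")
  if (is.null(pre_incubation))
    pre_incubation <- setNames(rep(30, length(drugs)), names(drugs))
  structure(list(hgf = hgf, drugs = drugs,
                 pre_incubation = pre_incubation,
                 t_end = t_end, output_times = sort(output_times)),
            class = "hgf_condition")
}

#' @export
print.hgf_condition <- function(x, ...) {
  cat("condition: HGF", x$hgf, "ng/ml")
  if (length(x$drugs))
    cat(";", paste(names(x$drugs), x$drugs, sep = "=", collapse = ", "))
  cat("; t_end", x$t_end, "min\n")
  invisible(x)
}

.ode <- function(y, times, func, rtol = 1e-8, atol = 1e-6) {
  out <- deSolve::lsoda(y = y, times = times, func = func,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed; last successful time ",
         max(out[, 1], na.rm = TRUE))
  out
}

# relaxed basal state (HGF = 0, no drugs), cached per parameterization
basal_state <- function(model, t_relax = 1000) {
  key <- paste0("basal_", digest_params(model))
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  y0 <- setNames(model$species$initial, model$species$name)
  f <- if (.is_native(model)) make_rhs(model) else make_generic_rhs(model)
  out <- .ode(y0, c(0, t_relax), f)
  y <- out[nrow(out), -1]
  y[names(y0)[grepl("_deg$", names(y0))]] <- 0  # reset cumulative sinks
  model$cache[[key]] <- y
  y
}

# cheap stable hash of parameter values + initial amounts for cache keys
digest_params <- function(model) {
  v <- c(model$parameters$value, model$species$initial)
  paste(format(sum(v * seq_along(v)), digits = 15),
        format(sum(v^2), digits = 15), sep = "_")
}

#' Simulate a model under a condition
#'
#' Integration uses a stiff-capable solver (lsoda, rtol 1e-8, atol 1e-6).
#' The model is first relaxed to its unstimulated basal state; drugs are
#' then applied for their pre-incubation period, after which HGF is added
#' at t = 0 and the system integrated to `t_end`.  Rilotumumab acts by
#' ligand depletion: the free-HGF concentration entering the simulation is
#' the excess-antibody equilibrium value (see [apply_rilotumumab()]).
#'
#' @param model a `pathway_model`.
#' @param cond a [condition()].
#' @param relax pre-relax to the unstimulated basal state first (default
#'   TRUE; disable to integrate straight from the stored initial amounts,
#'   e.g. for imported toy models with a known transient).
#' @return object of class `trajectory`: list with `times`, `state`
#'   (time x species matrix), and `readouts` (time x readout matrix).
#' @export
simulate_condition <- function(model, cond, relax = TRUE) {
  stopifnot(inherits(cond, "hgf_condition"))
  f <- if (.is_native(model)) make_rhs(model) else make_generic_rhs(model)
  y <- if (relax) basal_state(model) else
    setNames(model$species$initial, model$species$name)
  p <- model_params(model)

  f_hgf <- if ("f_HGF" %in% names(p)) p[["f_HGF"]] else 1
  hgf_nM <- cond$hgf * f_hgf
  drugs <- cond$drugs
  if (length(drugs) && !all(.DRUGS[names(drugs)] %in% model$species$name))
    stop("model lacks drug species for: ",
         paste(names(drugs)[!.DRUGS[names(drugs)] %in%
                              model$species$name], collapse = ", "))
  if (length(drugs) && "rilotumumab" %in% names(drugs)) {
    hgf_free <- apply_rilotumumab(drugs[["rilotumumab"]], hgf_nM,
                                  p[["Kd_Rilo"]])
    y["Rilo"] <- drugs[["rilotumumab"]]
    y["Rilo_HGF"] <- hgf_nM - hgf_free
    hgf_nM <- hgf_free
    drugs <- drugs[setdiff(names(drugs), "rilotumumab")]
  }

  # pre-incubation: apply drugs in order of decreasing lead time
  if (length(drugs)) {
    pre <- cond$pre_incubation[names(drugs)]
    pre[is.na(pre)] <- 0
    for (tp in sort(unique(pre), decreasing = TRUE)) {
      for (dn in names(drugs)[pre == tp]) y[.DRUGS[[dn]]] <- drugs[[dn]]
      nxt <- if (any(pre < tp)) max(pre[pre < tp]) else 0
      if (tp > nxt) y <- .ode(y, c(0, tp - nxt), f)[2, -1]
    }
  }

  if ("HGF" %in% model$species$name) y["HGF"] <- hgf_nM
  times <- union(0, cond$output_times)
  out <- .ode(y, times, f)
  keep <- out[, 1] %in% cond$output_times
  state <- out[keep, -1, drop = FALSE]
  rownames(state) <- NULL
  ro <- vapply(model$readouts,
               function(sp) rowSums(state[, sp, drop = FALSE]),
               numeric(nrow(state)))
  if (is.null(dim(ro)))
    ro <- matrix(ro, nrow = 1, dimnames = list(NULL, names(model$readouts)))
  structure(list(times = cond$output_times, state = state, readouts = ro,
                 condition = cond), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$times), "timepoints,",
      ncol(x$state), "species\n")
  invisible(x)
}

#' Extract a readout time course from a trajectory
#' @param traj a `trajectory`.
#' @param readout readout name (see model readouts).
#' @param t optional times (minutes); defaults to all output times.
#' @return numeric vector of readout values.
#' @export
readout_values <- function(traj, readout, t = NULL) {
  if (!readout %in% colnames(traj$readouts))
    stop("unknown readout: ", readout)
  v <- traj$readouts[, readout]
  if (is.null(t)) return(setNames(v, traj$times))
  idx <- match(t, traj$times)
  if (anyNA(idx)) {
    # linear interpolation for off-grid times
    return(setNames(approx(traj$times, v, xout = t)$y, t))
  }
  setNames(v[idx], t)
}

#' Fraction of (non-degraded) Met receptor in the internalized pool
#' @param traj a `trajectory` of the reference model.
#' @param model the model the trajectory came from.
#' @param t time(s) in minutes.
#' @return internalized fraction(s) in [0, 1].
#' @export
met_internalized_fraction <- function(traj, model, t) {
  idx <- match(t, traj$times)
  if (anyNA(idx)) stop("time(s) not in trajectory output times")
  surf <- rowSums(traj$state[idx, model$met_pools$surface, drop = FALSE])
  int  <- rowSums(traj$state[idx, model$met_pools$internal, drop = FALSE])
  setNames(int / (surf + int), t)
}

#' Share of total phospho-Met that is internalized
#' @inheritParams met_internalized_fraction
#' @export
pmet_internal_share <- function(traj, t) {
  int <- readout_values(traj, "pMet_internal", t)
  tot <- readout_values(traj, "pMet_total", t)
  int / tot
}

#' Conservation-group residual along a trajectory
#'
#' Maximum over time of the relative deviation of each conservation group's
#' total from its initial value.
#'
#' @param traj a `trajectory`.
#' @param model the model.
#' @return named numeric vector of relative residuals per group.
#' @export
conservation_residual <- function(traj, model) {
  vapply(model$groups, function(sp) {
    tot <- rowSums(traj$state[, sp, drop = FALSE])
    max(abs(tot - tot[1])) / tot[1]
  }, 0)
}
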