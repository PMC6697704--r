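# Uncertainty quantification by parametric Monte-Carlo resampling of the
# calibration data, plus local-sensitivity sign-consistency classification
# of practical identifiability.

#' Resample calibration datasets from a log-normal noise model
#'
#' Each observation is redrawn log-normally with median equal to the
#' observed mean and coefficient of variation `cv` (sdlog =
#' sqrt(log(1 + cv^2))), emulating a stated measurement error (default
#' 10%).
#'
#' @param datasets list of [experiment_dataset()]s (means must be > 0).
#' @param n number of replicate dataset collections (the study used 201).
#' @param cv coefficient of variation of the noise (default 0.10).
#' @param seed RNG seed.
#' @return list of n replicate dataset lists.
#' @export
resample_datasets <- function(datasets, n = 201, cv = 0.10, seed = 1) {
  stopifnot(cv > 0, n >= 1)
  for (ds in datasets)
    if (any(ds$means <= 0))
      stop("non-positive mean in dataset '", ds$id,
           "': log-normal resampling undefined")
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  lapply(seq_len(n), function(i) {
    lapply(datasets, function(ds) {
      ds$means <- rlnorm(length(ds$means), meanlog = log(ds$means),
                         sdlog = sdlog)
      ds
    })
  })
}

#' Refit the model to every resampled replicate
#'
#' One pattern-search refit per replicate, started at the base fit and
#' bounded to plus/minus one order of magnitude around it.  Failed refits
#' are logged and excluded.
#'
#' @param replicates output of [resample_datasets()].
#' @param model a `pathway_model`.
#' @param base_fit named vector of base-fit parameter values (the refitted
#'   subset).
#' @param max_eval pattern-search budget per replicate.
#' @param step0,tol pattern-search mesh controls.
#' @return object of class `resample_ensemble`: `params` (replicate x
#'   parameter matrix), `costs`, `n_failed`, `base_fit`.
#' @export
refit_ensemble <- function(replicates, model, base_fit, max_eval = 60,
                           step0 = 0.25, tol = 0.02) {
  lower <- base_fit / 10
  upper <- base_fit * 10
  rows <- vector("list", length(replicates))
  costs <- rep(NA_real_, length(replicates))
  n_failed <- 0L
  for (i in seq_along(replicates)) {
    fit <- tryCatch(
      pattern_search(function(x)
        calibration_objective(x, model, replicates[[i]]),
        base_fit, lower, upper, step0 = step0, tol = tol,
        max_eval = max_eval),
      error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    rows[[i]] <- fit$par
    costs[i] <- fit$value
  }
  keep <- !vapply(rows, is.null, TRUE)
  structure(list(params = do.call(rbind, rows[keep]),
                 costs = costs[keep], n_failed = n_failed,
                 base_fit = base_fit), class = "resample_ensemble")
}

#' @export
print.resample_ensemble <- function(x, ...) {
  cat("resample ensemble:", nrow(x$params), "refits (",
      x$n_failed, "failed ),", ncol(x$params), "parameters\n")
  invisible(x)
}

#' Pointwise confidence band of a readout across an ensemble
#'
#' Simulates the condition under every ensemble member and returns the
#' pointwise 2.5/50/97.5 percentiles (a pointwise, not simultaneous, 95%
#' band).
#'
#' @param ensemble a `resample_ensemble` (or a replicate x parameter
#'   matrix).
#' @param model a `pathway_model`.
#' @param readout readout name.
#' @param cond a [condition()].
#' @return data.frame `time`, `lower`, `median`, `upper`.
#' @export
confidence_band <- function(ensemble, model, readout, cond) {
  pm <- if (inherits(ensemble, "resample_ensemble")) ensemble$params else
    ensemble
  stopifnot(nrow(pm) >= 1)
  sims <- apply(pm, 1, function(x) {
    readout_values(simulate_condition(set_params(model, x), cond), readout)
  })
  qs <- apply(sims, 1, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  data.frame(time = cond$output_times, lower = qs[1, ], median = qs[2, ],
             upper = qs[3, ])
}

#' Local log-sensitivities of model outputs to parameters
#'
#' Central finite differences of log(output) with respect to log(param)
#' (relative step 1%), for the stated outputs at the stated times.
#'
#' @param model a `pathway_model`.
#' @param params named vector of parameter values at which to evaluate
#'   (default: current model values for all free parameters).
#' @param outputs readout names (default: the six phospho-readouts).
#' @param times evaluation times in minutes.
#' @param cond stimulation condition.
#' @param rel_step relative finite-difference step.
#' @return matrix parameters x outputs (columns readout@time).
#' @export
local_sensitivities <- function(model, params = NULL,
                                outputs = c("pMet_total", "pAkt", "pMEK",
                                            "pERK", "pRSK", "ppRSK"),
                                times = c(15, 120),
                                cond = condition(hgf = 40,
                                                 output_times = c(15, 120)),
                                rel_step = 0.01) {
  if (rel_step <= .Machine$double.eps)
    stop("finite-difference step underflow")
  if (is.null(params)) {
    free <- model$parameters$free
    params <- setNames(model$parameters$value[free],
                       model$parameters$name[free])
  }
  cols <- as.vector(outer(outputs, times, paste, sep = "@"))
  get_out <- function(m) {
    tr <- simulate_condition(m, cond)
    vapply(cols, function(cn) {
      parts <- strsplit(cn, "@", fixed = TRUE)[[1]]
      readout_values(tr, parts[1], as.numeric(parts[2]))
    }, 0)
  }
  sens <- matrix(NA_real_, length(params), length(cols),
                 dimnames = list(names(params), cols))
  for (j in seq_along(params)) {
    nm <- names(params)[j]
    up <- params[j] * (1 + rel_step)
    dn <- params[j] * (1 - rel_step)
    o_up <- get_out(set_params(model, setNames(up, nm)))
    o_dn <- get_out(set_params(model, setNames(dn, nm)))
    sens[j, ] <- (log(pmax(o_up, 1e-300)) - log(pmax(o_dn, 1e-300))) /
      (log(up) - log(dn))
  }
  sens
}

#' Classify practical identifiability by sign consistency
#'
#' A parameter is practically identifiable when, for at least one output,
#' at least 95% of its ensemble sensitivity distribution keeps one sign.
#' Sensitivities below `eps` in magnitude carry no sign; a parameter whose
#' sensitivities are all negligible is not identifiable.
#'
#' @param sens_list list of sensitivity matrices (one per ensemble
#'   member), as returned by [local_sensitivities()].
#' @param level required sign-consistent fraction (default 0.95).
#' @param eps magnitude below which a sensitivity is treated as signless.
#' @return object of class `identifiability_report`: data.frame with
#'   `parameter`, `identifiable`, `best_output`, `consistency`.
#' @export
classify_identifiability <- function(sens_list, level = 0.95,
                                     eps = 1e-6) {
  stopifnot(length(sens_list) >= 2)
  pnames <- rownames(sens_list[[1]])
  onames <- colnames(sens_list[[1]])
  res <- lapply(pnames, function(pn) {
    cons <- vapply(onames, function(on) {
      v <- vapply(sens_list, function(s) s[pn, on], 0)
      v <- v[is.finite(v)]
      signs <- sign(v) * (abs(v) > eps)
      if (all(signs == 0)) return(0)
      max(mean(signs > 0), mean(signs < 0))
    }, 0)
    best <- which.max(cons)
    data.frame(parameter = pn, identifiable = cons[best] >= level,
               best_output = onames[best], consistency = cons[best],
               row.names = NULL)
  })
  structure(do.call(rbind, res), class = c("identifiability_report",
                                           "data.frame"))
}
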