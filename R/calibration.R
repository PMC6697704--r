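# Calibration: normalized multi-condition objective and a derivative-free
# generalized pattern search in log10 parameter space.

#' Construct a calibration dataset
#'
#' @param cond a [condition()] describing the experiment.
#' @param readout readout name.
#' @param times observation times (minutes).
#' @param means normalized observed means.
#' @param sds normalized observed SDs (must be > 0 if supplied).
#' @param id optional dataset label.
#' @return object of class `experiment_dataset`.
#' @export
experiment_dataset <- function(cond, readout, times, means, sds = NULL,
                               id = NULL) {
  stopifnot(length(times) == length(means))
  if (!is.null(sds)) {
    stopifnot(length(sds) == length(means))
    if (any(sds <= 0)) stop("sds must be > 0")
  }
  structure(list(condition = cond, readout = readout, times = times,
                 means = means, sds = sds,
                 id = id %||% paste0(readout, "@", cond$hgf)),
            class = "experiment_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simulate all datasets once per parameter vector; returns normalized
# simulated values aligned with each dataset.  Normalization: each readout
# is scaled by its maximum over the HGF-only control time course (the
# first dataset with no drugs for that readout), switchable to
# per-condition max.
.simulate_datasets <- function(model, datasets,
                               normalization = c("control_max",
                                                 "condition_max")) {
  normalization <- match.arg(normalization)
  lapply(datasets, function(ds) {
    traj <- simulate_condition(model, ds$condition)
    sim <- readout_values(traj, ds$readout, ds$times)
    if (normalization == "condition_max") return(sim / max(sim))
    ctrl <- .control_max(model, datasets, ds$readout)
    sim / ctrl
  })
}

.control_max <- function(model, datasets, readout) {
  key <- paste0("ctrlmax_", readout, "_", digest_params(model))
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  ctrl_ds <- Filter(function(d)
    d$readout == readout && length(d$condition$drugs) == 0, datasets)
  cond <- if (length(ctrl_ds)) ctrl_ds[[1]]$condition else
    datasets[[1]]$condition
  cond$drugs <- numeric()
  traj <- simulate_condition(model, cond)
  v <- max(readout_values(traj, readout))
  model$cache[[key]] <- v
  v
}

#' Calibration objective: multi-condition RMSE
#'
#' Root-mean-square error between normalized simulated readouts and
#' dataset means, summed across datasets.  Residuals are divided by the
#' dataset SD when `weighted = TRUE` and SDs are available.  Simulation
#' failure under a parameter set returns a large finite penalty (1e6)
#' rather than an error, so the optimizer can continue.
#'
#' @param params named vector of parameter values to apply.
#' @param model base `pathway_model`.
#' @param datasets list of [experiment_dataset()]s.
#' @param weighted divide residuals by dataset SDs when available.
#' @param normalization see Details; `"control_max"` (default) scales each
#'   readout by its maximum over the drug-free control time course.
#' @return non-negative cost (penalty 1e6 on simulation failure).
#' @export
calibration_objective <- function(params, model, datasets, weighted = FALSE,
                                  normalization = "control_max") {
  if (!length(datasets)) stop("datasets must be non-empty")
  m <- set_params(model, params)
  sims <- tryCatch(.simulate_datasets(m, datasets, normalization),
                   error = function(e) NULL)
  if (is.null(sims)) return(1e6)
  cost <- 0
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    res <- sims[[i]] - ds$means
    if (weighted && !is.null(ds$sds)) res <- res / ds$sds
    cost <- cost + sqrt(mean(res^2))
  }
  cost
}

#' Generalized pattern search in log10 space
#'
#' Derivative-free bound-constrained minimization: starting from `x0`, poll
#' each coordinate at +/- the current mesh size (in log10 units), accept
#' the first improving point (fixed coordinate order, deterministic
#' tie-break), double the mesh after a successful sweep and halve it after
#' a failed one, and stop when the mesh falls below `tol` or the evaluation
#' budget is exhausted (normal termination).  The returned point is never
#' worse than `x0`.
#'
#' @param fn objective: `function(x)` with `x` a named vector on the
#'   natural (linear) scale.
#' @param x0 named numeric starting point (within bounds).
#' @param lower,upper named bound vectors on the natural scale.
#' @param step0 initial mesh size in log10 units (default 0.5).
#' @param tol mesh-size termination tolerance in log10 units.
#' @param max_eval maximum number of objective evaluations.
#' @param trace record accepted costs.
#' @return object of class `fit_result`: `par` (best point), `value`,
#'   `evals`, `trace` (accepted costs), `bounds`.
#' @export
pattern_search <- function(fn, x0, lower, upper, step0 = 0.5, tol = 1e-4,
                           max_eval = 2000, trace = TRUE) {
  stopifnot(all(x0 >= lower), all(x0 <= upper), all(lower > 0))
  lx <- log10(x0); ll <- log10(lower); lu <- log10(upper)
  n <- length(lx)
  evals <- 0L
  eval_fn <- function(lx) {
    evals <<- evals + 1L
    v <- fn(setNames(10^lx, names(x0)))
    if (!is.finite(v)) Inf else v
  }
  best <- eval_fn(lx)
  tr <- best
  step <- step0
  while (step > tol && evals < max_eval) {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (s in c(+1, -1)) {
        cand <- lx
        cand[i] <- min(max(cand[i] + s * step, ll[i]), lu[i])
        if (cand[i] == lx[i]) next
        if (evals >= max_eval) break
        v <- eval_fn(cand)
        if (v < best) {
          best <- v; lx <- cand; improved <- TRUE
          if (trace) tr <- c(tr, v)
          break
        }
      }
      if (evals >= max_eval) break
    }
    step <- if (improved) min(step * 2, step0) else step / 2
  }
  structure(list(par = setNames(10^lx, names(x0)), value = best,
                 evals = evals, trace = tr,
                 bounds = list(lower = lower, upper = upper)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit result: cost", format(x$value, digits = 6), "after", x$evals,
      "evaluations;", length(x$par), "parameters\n")
  invisible(x)
}

#' Calibrate free model parameters to datasets
#'
#' Pattern search over the selected free parameters (all free parameters by
#' default) within their bounds.
#'
#' @param model a `pathway_model`.
#' @param datasets list of [experiment_dataset()]s.
#' @param which parameter names to fit (default: all free parameters).
#' @param ... passed to [pattern_search()].
#' @inheritParams calibration_objective
#' @return `fit_result` with fitted parameters.
#' @export
calibrate_model <- function(model, datasets, which = NULL, weighted = FALSE,
                            normalization = "control_max", ...) {
  free <- model$parameters[model$parameters$free, ]
  if (is.null(which)) which <- free$name
  stopifnot(all(which %in% model$parameters$name))
  idx <- match(which, model$parameters$name)
  x0 <- setNames(model$parameters$value[idx], which)
  lower <- setNames(model$parameters$lower[idx], which)
  upper <- setNames(model$parameters$upper[idx], which)
  fn <- function(x) calibration_objective(x, model, datasets,
                                          weighted = weighted,
                                          normalization = normalization)
  pattern_search(fn, x0, lower, upper, ...)
}

#' Fit node-inhibitor strengths to mono-treatment data
#'
#' All globally calibrated parameters stay frozen; only the inhibition
#' strengths of the requested nodes are fitted, enabling the prediction of
#' combination treatments from mono-treatment fits.
#'
#' @param model calibrated `pathway_model` (base parameters frozen).
#' @param mono_datasets list of [experiment_dataset()]s from single-agent
#'   treatments.
#' @param nodes character vector of node names (default: nodes dosed in the
#'   datasets).
#' @param ... passed to [pattern_search()].
#' @return named vector of fitted strengths in [0, 1].
#' @export
fit_inhibitor_strengths <- function(model, mono_datasets, nodes = NULL,
                                    ...) {
  if (is.null(nodes)) {
    dosed <- unique(unlist(lapply(mono_datasets,
                                  function(d) names(d$condition$drugs))))
    nodes <- names(.NODE_DRUGS)[.NODE_DRUGS %in% dosed]
    if ("sorafenib" %in% dosed) nodes <- c(nodes, "Raf")
  }
  pnames <- unname(.NODE_STRENGTH[nodes])
  # strengths live in [0, 1]; optimize on a (0, 1] grid via log10 with a
  # small floor so the search space stays positive
  x0 <- setNames(pmax(model_params(model)[pnames], 1e-3), pnames)
  lower <- setNames(rep(1e-4, length(pnames)), pnames)
  upper <- setNames(rep(1, length(pnames)), pnames)
  fn <- function(x) calibration_objective(x, model, mono_datasets)
  fit <- pattern_search(fn, x0, lower, upper, ...)
  setNames(fit$par, nodes)
}
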