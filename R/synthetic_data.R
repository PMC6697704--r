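# Synthetic-data generators with known ground truth: noisy phospho-protein
# time courses in the calibration schema, virtual-patient cohorts, and
# MuSyC response grids.  All generators are pure functions of their
# arguments and a mandatory seed.

#' Generate noisy time-course datasets from a known truth
#'
#' Simulates each condition under the truth parameters, applies
#' multiplicative log-normal noise (median at the noise-free value,
#' coefficient of variation `cv`) to `n_rep` pseudo-replicates, and
#' returns mean +/- SD datasets in the calibration schema.  With `cv = 0`
#' the means equal the noise-free simulation.
#'
#' @param model a `pathway_model`.
#' @param truth named vector of parameter values defining the ground
#'   truth (applied to the model before simulating).
#' @param conditions named list of [condition()]s.
#' @param readouts readout names observed per condition.
#' @param times observation times (minutes).
#' @param cv noise coefficient of variation (default 0.10).
#' @param n_rep pseudo-replicates per observation (default 3).
#' @param seed RNG seed (mandatory).
#' @param normalization readout scaling convention (see
#'   [calibration_objective()]).
#' @return list of [experiment_dataset()]s; the truth-normalized noise-free
#'   curves are attached as attribute `truth_curves`.
#' @export
generate_timecourses <- function(model, truth = NULL, conditions,
                                 readouts = c("pAkt", "pERK"),
                                 times = c(0, 5, 15, 30, 60, 120),
                                 cv = 0.10, n_rep = 3, seed,
                                 normalization = "control_max") {
  stopifnot(!missing(seed))
  set.seed(seed)
  m <- if (is.null(truth)) model else set_params(model, truth)
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  datasets <- list()
  truth_curves <- list()
  for (cn in names(conditions)) {
    cond <- conditions[[cn]]
    cond$output_times <- sort(unique(c(cond$output_times, times)))
    traj <- simulate_condition(m, cond)
    for (rd in readouts) {
      ref <- if (normalization == "control_max") {
        ctrl <- cond; ctrl$drugs <- numeric()
        max(readout_values(simulate_condition(m, ctrl), rd))
      } else max(readout_values(traj, rd))
      mu <- readout_values(traj, rd, times) / ref
      truth_curves[[paste(cn, rd, sep = ".")]] <- mu
      draws <- matrix(rlnorm(length(mu) * n_rep,
                             meanlog = rep(log(pmax(mu, 1e-12)), n_rep),
                             sdlog = sdlog),
                      nrow = length(mu))
      if (cv == 0) draws <- matrix(rep(mu, n_rep), nrow = length(mu))
      means <- rowMeans(draws)
      sds <- if (n_rep >= 2) apply(draws, 1, sd) else cv * means
      sds[!is.finite(sds) | sds <= 0] <- max(mean(means) * 1e-6, 1e-12)
      datasets[[length(datasets) + 1L]] <- experiment_dataset(
        cond, rd, times, means, sds, id = paste(cn, rd, sep = "."))
    }
  }
  attr(datasets, "truth_curves") <- truth_curves
  datasets
}

#' Standard calibration-style condition suite
#'
#' HGF alone plus MEK inhibitor, PDK1 inhibitor, and both — the treatment
#' design the calibration data emulate, chosen because the paired
#' inhibitors dissect the relative strength of the feedback loops.
#'
#' @param t_end horizon in minutes.
#' @return named list of [condition()]s.
#' @export
calibration_conditions <- function(t_end = 120) {
  times <- c(0, 5, 15, 30, 60, 90, 120)
  base <- condition(hgf = 40, t_end = t_end, output_times = times)
  list(
    hgf   = base,
    meki  = with_node_inhibitor(base, "MEK"),
    pdk1i = with_node_inhibitor(base, "PDK1"),
    both  = with_node_inhibitor(with_node_inhibitor(base, "MEK"), "PDK1"))
}

#' Generate a synthetic virtual-patient cohort
#'
#' Per-protein log2 fold changes drawn independently per patient from
#' Normal(log2fc_mean, log2fc_sd), stored as a proteins x patients matrix
#' (the layout of a tumor/normal paired expression table).
#'
#' @param n number of patients (the study cohort had 50 tumor-normal
#'   pairs).
#' @param proteins protein names (default: all scalable model proteins).
#' @param log2fc_mean,log2fc_sd normal-distribution parameters, recycled
#'   per protein.
#' @param seed RNG seed (mandatory).
#' @return numeric matrix proteins x patients of log2 fold changes.
#' @export
generate_cohort <- function(n = 50, proteins = NULL, log2fc_mean = 0,
                            log2fc_sd = 0.5, seed) {
  stopifnot(!missing(seed), n >= 1)
  if (is.null(proteins)) proteins <- names(.scalable_proteins())
  set.seed(seed)
  mu <- rep_len(log2fc_mean, length(proteins))
  sdv <- rep_len(log2fc_sd, length(proteins))
  m <- matrix(rnorm(length(proteins) * n, mean = rep(mu, n),
                    sd = rep(sdv, n)),
              nrow = length(proteins),
              dimnames = list(proteins, paste0("patient", seq_len(n))))
  m
}

#' Generate a noisy 2-D response grid from known MuSyC parameters
#'
#' Evaluates the MuSyC surface on the dose grid and applies multiplicative
#' log-normal noise; the ground truth is attached as attribute `truth`.
#'
#' @param par named list/vector of MuSyC parameters (E0, E1, E2, E3, h1,
#'   h2, C1, C2, alpha2).
#' @param doses1,doses2 positive dose grids (zero anchors added).
#' @param cv noise coefficient of variation (0 for noise-free).
#' @param seed RNG seed (mandatory).
#' @return data.frame `d1`, `d2`, `effect` with attribute `truth`.
#' @export
generate_musyc_grid <- function(par, doses1, doses2, cv = 0, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  d1 <- sort(unique(c(0, doses1))); d2 <- sort(unique(c(0, doses2)))
  grid <- expand.grid(d1 = d1, d2 = d2)
  mu <- musyc_effect(grid$d1, grid$d2, par)
  grid$effect <- if (cv > 0)
    rlnorm(length(mu), meanlog = log(mu), sdlog = sqrt(log(1 + cv^2)))
  else mu
  attr(grid, "truth") <- as.list(par)
  grid
}
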