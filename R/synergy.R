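# Dose-response characterization and MuSyC two-drug synergy surfaces.
#
# Effects are normalized readouts (fraction of the zero-drug control at a
# fixed time), so E0 = 1 by construction and smaller E means stronger
# inhibition.  The 2-D Hill surface used here is
#
#   E(d1,d2) = [ E0*C1^h1*C2^h2 + E1*d1^h1*C2^h2 + E2*C1^h1*d2^h2
#                + E3*alpha2*d1^h1*d2^h2 ]
#            / [ C1^h1*C2^h2 + d1^h1*C2^h2 + C1^h1*d2^h2
#                + alpha2*d1^h1*d2^h2 ]
#
# which reduces to the single-drug Hill curves on each axis.  alpha2 > 1
# (log10(alpha2) > 0) means each drug potentiates the other's potency;
# beta_obs = (min(E1,E2) - E3) / (E0 - min(E1,E2)) is the gain in maximal
# effect of the combination beyond the stronger single agent, as a
# fraction of that agent's effect range (> 0 means synergistic efficacy).

.drug_condition <- function(base, drug, dose) {
  switch(drug,
         axt050       = apply_axt050(base, dose),
         cabozantinib = apply_cabozantinib(base, dose),
         rilotumumab  = apply_rilotumumab_condition(base, dose),
         sorafenib    = with_node_inhibitor(base, "Raf", dose),
         stop("unknown drug: ", drug))
}

#' Default dose grids per drug (nM), mirroring the studied therapeutic
#' ranges: 1-1000 nM for sorafenib and cabozantinib, 0.01-10 nM for
#' rilotumumab, and up to 50 uM for the AXT050 peptide.
#' @param drug drug name.
#' @param n number of log-spaced doses.
#' @return numeric dose vector (without the zero anchor).
#' @export
default_dose_grid <- function(drug, n = 8) {
  r <- switch(drug,
              sorafenib    = c(1, 1000),
              cabozantinib = c(1, 1000),
              rilotumumab  = c(0.01, 10),
              axt050       = c(100, 50000),
              stop("unknown drug: ", drug))
  10^seq(log10(r[1]), log10(r[2]), length.out = n)
}

#' Single-drug dose-response of a model readout
#'
#' One simulation per dose under the base condition (default 40 ng/ml HGF);
#' effect is the readout at time `t` normalized to the zero-dose value.
#'
#' @param model a `pathway_model`.
#' @param drug one of "axt050", "cabozantinib", "rilotumumab", "sorafenib".
#' @param doses dose vector in nM (zero anchor added automatically).
#' @param readout readout name.
#' @param t evaluation time in minutes (15 or 120 in the study design).
#' @param base base [condition()].
#' @return object of class `dose_response`: data.frame with `dose`,
#'   `value`, `effect` plus attributes.
#' @export
dose_response <- function(model, drug, doses = default_dose_grid(drug),
                          readout = "pAkt", t = 120,
                          base = condition(hgf = 40, output_times = c(15, 120))) {
  doses <- sort(unique(c(0, doses)))
  vals <- vapply(doses, function(d) {
    cond <- if (d == 0) base else .drug_condition(base, drug, d)
    readout_values(simulate_condition(model, cond), readout, t)
  }, 0)
  out <- data.frame(dose = doses, value = vals, effect = vals / vals[1])
  structure(out, drug = drug, readout = readout, t = t,
            class = c("dose_response", "data.frame"))
}

#' Four-parameter Hill fit and IC50
#'
#' Fits `E(d) = E0 + (Emax - E0) * d^h / (C^h + d^h)` by least squares
#' (Levenberg-Marquardt on log10 C and log h).  For an inhibition curve
#' the fitted `C` is the dose of half-maximal inhibition (IC50).
#'
#' @param dr a [dose_response()] or data.frame with `dose` and `effect`.
#' @return object of class `hill_fit`: list with `E0`, `Emax`, `h`, `C`
#'   (= IC50), `residual`.
#' @export
fit_ic50 <- function(dr) {
  o <- order(dr$dose)
  d <- dr$dose[o]; e <- dr$effect[o]
  rng <- max(e) - min(e)
  if (rng < 1e-3)
    stop("dose-response flat: effect range too small for a Hill fit")
  span <- abs(e[length(e)] - e[1])
  if (span < 0.5 * rng)
    stop("dose-response non-monotone: end-to-end effect spans less than ",
         "half its dynamic range")
  e0 <- e[d == 0][1]
  emax0 <- e[length(e)]
  mid <- (e0 + emax0) / 2
  c0 <- d[d > 0][which.min(abs(e[d > 0] - mid))]
  fit <- minpack.lm::nls.lm(
    par = c(E0 = e0, Emax = emax0, lC = log10(c0), lh = 0),
    fn = function(p) {
      hh <- 10^p[["lh"]]; cc <- 10^p[["lC"]]
      pred <- p[["E0"]] + (p[["Emax"]] - p[["E0"]]) * d^hh / (cc^hh + d^hh)
      pred - e
    },
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  structure(list(E0 = p[["E0"]], Emax = p[["Emax"]], h = 10^p[["lh"]],
                 C = 10^p[["lC"]], ic50 = 10^p[["lC"]],
                 residual = sqrt(mean(fit$fvec^2))),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: E0 %.3f -> Emax %.3f, h %.2f, C (IC50) %.3g\n",
              x$E0, x$Emax, x$h, x$C))
  invisible(x)
}

#' Evaluate the MuSyC surface
#' @param d1,d2 dose vectors (recycled).
#' @param p named list/vector with E0, E1, E2, E3, h1, h2, C1, C2, alpha2.
#' @return effect values.
#' @export
musyc_effect <- function(d1, d2, p) {
  p <- as.list(p)
  a <- p$alpha2
  t1 <- d1^p$h1; t2 <- d2^p$h2
  c1 <- p$C1^p$h1; c2 <- p$C2^p$h2
  num <- p$E0 * c1 * c2 + p$E1 * t1 * c2 + p$E2 * c1 * t2 +
    p$E3 * a * t1 * t2
  den <- c1 * c2 + t1 * c2 + c1 * t2 + a * t1 * t2
  num / den
}

#' Efficacy synergy beta_obs of a fitted surface
#'
#' `(min(E1, E2) - E3) / (E0 - min(E1, E2))`: the combination's gain in
#' maximal effect beyond the stronger single drug, relative to that drug's
#' effect range.  Zero when the combination's plateau equals the best
#' single-agent plateau.
#'
#' @param surface a `musyc_surface` or parameter list with E0..E3.
#' @return scalar beta_obs.
#' @export
beta_obs <- function(surface) {
  p <- if (inherits(surface, "musyc_surface")) surface$par else
    as.list(surface)
  emin <- min(p$E1, p$E2)
  (emin - p$E3) / (p$E0 - emin)
}

#' Fit a MuSyC surface to a 2-D dose grid of effects
#'
#' Bounded least squares (Levenberg-Marquardt in transformed coordinates),
#' initialized from the single-drug Hill fits along each axis.  The grid
#' must include both single-drug axes and the (0, 0) corner.
#'
#' @param grid data.frame with columns `d1`, `d2`, `effect`.
#' @param fix_e0 hold E0 at the (0,0) effect (default TRUE; effects are
#'   normalized so this is 1).
#' @return object of class `musyc_surface`: `par` (named list incl.
#'   `alpha2`), `log_alpha2`, `beta_obs`, `residual`.
#' @export
fit_musyc_surface <- function(grid, fix_e0 = TRUE) {
  stopifnot(all(c("d1", "d2", "effect") %in% names(grid)))
  ax1 <- grid[grid$d2 == 0, ]
  ax2 <- grid[grid$d1 == 0, ]
  if (nrow(ax1) < 4 || nrow(ax2) < 4 || !any(grid$d1 == 0 & grid$d2 == 0))
    stop("grid must include both single-drug axes and the zero-zero corner")
  if (length(unique(grid$d1[grid$d1 > 0])) < 2 ||
      length(unique(grid$d2[grid$d2 > 0])) < 2)
    stop("degenerate grid: need at least two positive doses per drug")
  h1f <- tryCatch(fit_ic50(data.frame(dose = ax1$d1, effect = ax1$effect)),
                  error = function(e) NULL)
  h2f <- tryCatch(fit_ic50(data.frame(dose = ax2$d2, effect = ax2$effect)),
                  error = function(e) NULL)
  e0 <- grid$effect[grid$d1 == 0 & grid$d2 == 0][1]
  init <- c(
    E1 = if (!is.null(h1f)) h1f$Emax else min(ax1$effect),
    E2 = if (!is.null(h2f)) h2f$Emax else min(ax2$effect),
    E3 = min(grid$effect),
    lh1 = log10(if (!is.null(h1f)) h1f$h else 1),
    lh2 = log10(if (!is.null(h2f)) h2f$h else 1),
    lC1 = log10(if (!is.null(h1f)) h1f$C else stats::median(ax1$d1[ax1$d1 > 0])),
    lC2 = log10(if (!is.null(h2f)) h2f$C else stats::median(ax2$d2[ax2$d2 > 0])),
    la2 = 0)
  if (!fix_e0) init <- c(init, E0 = e0)
  resid_fn <- function(q) {
    p <- list(E0 = if (fix_e0) e0 else q[["E0"]],
              E1 = q[["E1"]], E2 = q[["E2"]], E3 = q[["E3"]],
              h1 = 10^q[["lh1"]], h2 = 10^q[["lh2"]],
              C1 = 10^q[["lC1"]], C2 = 10^q[["lC2"]],
              alpha2 = 10^q[["la2"]])
    musyc_effect(grid$d1, grid$d2, p) - grid$effect
  }
  fit <- minpack.lm::nls.lm(
    par = init, fn = resid_fn,
    lower = c(E1 = -0.5, E2 = -0.5, E3 = -0.5, lh1 = -1.3, lh2 = -1.3,
              lC1 = init[["lC1"]] - 3, lC2 = init[["lC2"]] - 3, la2 = -3,
              if (!fix_e0) c(E0 = 0)),
    upper = c(E1 = 2, E2 = 2, E3 = 2, lh1 = 1.3, lh2 = 1.3,
              lC1 = init[["lC1"]] + 3, lC2 = init[["lC2"]] + 3, la2 = 3,
              if (!fix_e0) c(E0 = 2)),
    control = minpack.lm::nls.lm.control(maxiter = 400))
  q <- fit$par
  par <- list(E0 = if (fix_e0) e0 else q[["E0"]],
              E1 = q[["E1"]], E2 = q[["E2"]], E3 = q[["E3"]],
              h1 = 10^q[["lh1"]], h2 = 10^q[["lh2"]],
              C1 = 10^q[["lC1"]], C2 = 10^q[["lC2"]],
              alpha2 = 10^q[["la2"]])
  structure(list(par = par, log_alpha2 = log10(par$alpha2),
                 beta_obs = beta_obs(par),
                 residual = sqrt(mean(fit$fvec^2))),
            class = "musyc_surface")
}

#' @export
print.musyc_surface <- function(x, ...) {
  cat(sprintf(paste0("MuSyC surface: log(alpha2) %.3f, beta_obs %.4f ",
                     "(E1 %.3f, E2 %.3f, E3 %.3f; rms %.2e)\n"),
              x$log_alpha2, x$beta_obs, x$par$E1, x$par$E2, x$par$E3,
              x$residual))
  invisible(x)
}

#' Simulate a two-drug response grid from the pathway model
#'
#' Simulates every (d1, d2) pair including zero anchors under the base
#' condition and returns normalized effects, ready for
#' [fit_musyc_surface()].
#'
#' @param model a `pathway_model`.
#' @param drug1,drug2 drug names (convention: drug 1 is AXT050).
#' @param doses1,doses2 positive dose grids (defaults per drug).
#' @param readouts readout name(s); one simulation sweep serves them all.
#' @param t evaluation time in minutes.
#' @param base base [condition()].
#' @return data.frame `d1`, `d2`, and per readout `value_<r>` and
#'   `effect_<r>` columns (plus `effect` for the first readout).
#' @export
simulate_drug_grid <- function(model, drug1, drug2,
                               doses1 = default_dose_grid(drug1),
                               doses2 = default_dose_grid(drug2),
                               readouts = "pAkt", t = 120,
                               base = condition(hgf = 40,
                                                output_times = c(15, 120))) {
  d1 <- sort(unique(c(0, doses1))); d2 <- sort(unique(c(0, doses2)))
  grid <- expand.grid(d1 = d1, d2 = d2)
  vals <- t(mapply(function(a, b) {
    cond <- base
    if (a > 0) cond <- .drug_condition(cond, drug1, a)
    if (b > 0) cond <- .drug_condition(cond, drug2, b)
    tr <- simulate_condition(model, cond)
    vapply(readouts, function(rd) readout_values(tr, rd, t), 0)
  }, grid$d1, grid$d2))
  if (length(readouts) == 1) vals <- matrix(vals, ncol = 1)
  zero <- grid$d1 == 0 & grid$d2 == 0
  for (k in seq_along(readouts)) {
    grid[[paste0("value_", readouts[k])]] <- vals[, k]
    grid[[paste0("effect_", readouts[k])]] <- vals[, k] / vals[zero, k]
  }
  grid$effect <- grid[[paste0("effect_", readouts[1])]]
  grid
}

#' Quantify synergy of a drug pair
#'
#' Runs the 2-D dose grid once and fits one MuSyC surface per readout.
#'
#' @inheritParams simulate_drug_grid
#' @param readout readout name(s).
#' @return a `musyc_surface` for a single readout, or a named list of
#'   surfaces for several (the simulated grid attached as attribute
#'   `grid`).
#' @export
quantify_synergy <- function(model, drug1, drug2, readout = "pAkt",
                             t = 120, ...) {
  grid <- simulate_drug_grid(model, drug1, drug2, readouts = readout,
                             t = t, ...)
  fits <- lapply(readout, function(rd) {
    g <- grid[, c("d1", "d2")]
    g$effect <- grid[[paste0("effect_", rd)]]
    surf <- fit_musyc_surface(g)
    attr(surf, "grid") <- grid
    surf
  })
  if (length(readout) == 1) return(fits[[1]])
  setNames(fits, readout)
}

#' Isobologram contour of a fitted MuSyC surface
#'
#' Dose pairs achieving a stated fractional inhibition.  For each d1 on a
#' grid the matching d2 solves the surface equation in closed form (the
#' surface is a ratio of expressions linear in d2^h2).
#'
#' @param surface a `musyc_surface`.
#' @param level fractional inhibition in (0, 1), relative to E0.
#' @param d1max largest drug-1 dose to scan (default: 100 * C1).
#' @param n number of contour points.
#' @return data.frame `d1`, `d2` (NA where the level is unreachable along
#'   that d1 slice); errors if the level is unreachable everywhere.
#' @export
isobologram <- function(surface, level, d1max = NULL, n = 50) {
  p <- surface$par
  target <- p$E0 * (1 - level)
  if (target < min(p$E1, p$E2, p$E3) || target > p$E0)
    stop("inhibition level ", level, " outside the achievable range")
  if (is.null(d1max)) d1max <- 100 * p$C1
  d1 <- c(0, 10^seq(log10(d1max) - 6, log10(d1max), length.out = n - 1))
  c1 <- p$C1^p$h1; c2 <- p$C2^p$h2
  d2 <- vapply(d1, function(x) {
    t1 <- x^p$h1
    # solve (A + B*u)/(D + F*u) = target for u = d2^h2
    A <- p$E0 * c1 * c2 + p$E1 * t1 * c2
    B <- p$E2 * c1 + p$E3 * p$alpha2 * t1
    D <- c1 * c2 + t1 * c2
    F <- c1 + p$alpha2 * t1
    u <- (A - target * D) / (target * F - B)
    if (!is.finite(u) || u < 0) NA_real_ else u^(1 / p$h2)
  }, 0)
  if (all(is.na(d2))) stop("level unreachable on the scanned dose range")
  data.frame(d1 = d1, d2 = d2)
}
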