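hill_curve <- function(doses, E0 = 1, Emax = 0.1, h = 1.2, C = 50) {
  E0 + (Emax - E0) * doses^h / (C^h + doses^h)
}

test_that("dose-response effects are anchored at the zero dose", {
  m <- ref_model()
  dr <- fixture("dr_sor_perk", function()
    dose_response(m, "sorafenib", doses = 10^seq(0, 3, length.out = 7),
                  readout = "pERK", t = 120))
  expect_equal(dr$effect[dr$dose == 0], 1)
  expect_true(all(diff(dr$dose) > 0))
  # sorafenib nearly abolishes steady-state pERK at the top dose
  expect_lt(min(dr$effect), 0.25)
})

test_that("sorafenib barely moves steady-state pAkt", {
  m <- ref_model()
  dr <- dose_response(m, "sorafenib", doses = c(10, 100, 1000),
                      readout = "pAkt", t = 120)
  expect_lt(max(abs(dr$effect - 1)), 0.10)
})

test_that("Hill fits recover generated parameters within 2%", {
  doses <- c(0, 10^seq(0, 3, length.out = 9))
  df <- data.frame(dose = doses, effect = hill_curve(doses))
  fit <- fit_ic50(df)
  expect_rel_equal(fit$C, 50, 0.02)
  expect_rel_equal(fit$h, 1.2, 0.02)
  expect_rel_equal(fit$Emax, 0.1, 0.02)
  # scale equivariance: doubling all doses doubles the fitted C
  df2 <- data.frame(dose = doses * 2, effect = df$effect)
  expect_rel_equal(fit_ic50(df2)$C, 2 * fit$C, 0.01)
})

test_that("flat or non-monotone curves are rejected with diagnostics", {
  doses <- c(0, 1, 10, 100)
  expect_error(fit_ic50(data.frame(dose = doses,
                                   effect = rep(1, 4))), "flat")
  expect_error(fit_ic50(data.frame(dose = doses,
                                   effect = c(1, 0.2, 0.3, 0.95))),
               "non-monotone")
})

test_that("sorafenib IC50 for pERK lands near 200 nM", {
  m <- ref_model()
  dr <- fixture("dr_sor_perk", function()
    dose_response(m, "sorafenib", doses = 10^seq(0, 3, length.out = 7),
                  readout = "pERK", t = 120))
  fit <- fit_ic50(dr)
  expect_gt(fit$ic50, 200 / 1.5)
  expect_lt(fit$ic50, 200 * 1.5)
})

test_that("MuSyC fits recover a lattice of known surfaces within 5%", {
  doses1 <- 10^seq(0, 3, length.out = 8)
  doses2 <- 10^seq(-1, 2, length.out = 8)
  for (la2 in c(-1, 0, 1)) for (beta in c(0, 0.2, 0.5)) {
    emin <- 0.4                      # stronger single-agent plateau
    e3 <- emin - beta * (1 - emin)
    truth <- list(E0 = 1, E1 = 0.55, E2 = emin, E3 = e3, h1 = 1.1,
                  h2 = 0.9, C1 = 40, C2 = 4, alpha2 = 10^la2)
    g <- generate_musyc_grid(truth, doses1, doses2, cv = 0, seed = 1)
    fit <- fit_musyc_surface(g)
    expect_lt(abs(fit$log_alpha2 - la2), 0.05 * max(abs(la2), 1))
    expect_lt(abs(fit$beta_obs - beta), 0.05 * max(beta, 1))
  }
})

test_that("a null-interaction surface scores zero synergy", {
  truth <- list(E0 = 1, E1 = 0.3, E2 = 0.45, E3 = 0.3, h1 = 1, h2 = 1,
                C1 = 50, C2 = 5, alpha2 = 1)
  g <- generate_musyc_grid(truth, 10^seq(0, 3, length.out = 8),
                           10^seq(-1, 2, length.out = 8), cv = 0, seed = 2)
  fit <- fit_musyc_surface(g)
  expect_lt(abs(fit$log_alpha2), 0.02)
  expect_lt(abs(fit$beta_obs), 0.02)
})

test_that("beta_obs is zero when the combination adds no efficacy", {
  expect_equal(beta_obs(list(E0 = 1, E1 = 0.5, E2 = 0.3, E3 = 0.3)), 0)
  expect_gt(beta_obs(list(E0 = 1, E1 = 0.5, E2 = 0.3, E3 = 0.1)), 0)
})

test_that("synergy metrics are invariant to consistent dose-unit changes", {
  doses1 <- 10^seq(0, 3, length.out = 8)
  doses2 <- 10^seq(-1, 2, length.out = 8)
  truth <- list(E0 = 1, E1 = 0.5, E2 = 0.35, E3 = 0.2, h1 = 1.2, h2 = 0.8,
                C1 = 60, C2 = 3, alpha2 = 10^0.4)
  g <- generate_musyc_grid(truth, doses1, doses2, cv = 0, seed = 3)
  f1 <- fit_musyc_surface(g)
  g2 <- g
  g2$d1 <- g$d1 * 1000               # e.g. uM -> nM relabeling
  f2 <- fit_musyc_surface(g2)
  expect_equal(f2$log_alpha2, f1$log_alpha2, tolerance = 1e-4)
  expect_equal(f2$beta_obs, f1$beta_obs, tolerance = 1e-4)
  expect_rel_equal(f2$par$C1, 1000 * f1$par$C1, 0.001)
})

test_that("isobologram endpoints and additive/synergistic shape are exact", {
  # With full-blockade plateaus and h = 1, a drug alone reaches a
  # fractional inhibition L at dose D(L) = C * L / (1 - L).  In the
  # no-co-occupancy limit (alpha2 -> 0) the contour is the exactly
  # straight Loewe line d1/D1(L) + d2/D2(L) = 1; co-occupancy (larger
  # alpha2) bows it inward.
  mk <- function(a2) {
    p <- list(E0 = 1, E1 = 0, E2 = 0, E3 = 0, h1 = 1, h2 = 1,
              C1 = 50, C2 = 5, alpha2 = a2)
    structure(list(par = p, log_alpha2 = log10(a2),
                   beta_obs = beta_obs(p)), class = "musyc_surface")
  }
  L <- 0.5
  D1 <- 50 * L / (1 - L); D2 <- 5 * L / (1 - L)
  iso0 <- isobologram(mk(1e-12), L, d1max = D1, n = 60)
  expect_rel_equal(iso0$d2[iso0$d1 == 0], D2, 1e-6)
  ok <- !is.na(iso0$d2)
  lhs <- iso0$d1[ok] / D1 + iso0$d2[ok] / D2
  expect_lt(max(abs(lhs - 1)), 1e-6)
  # independent co-binding (alpha2 = 1) and potency synergy (alpha2 = 10)
  # bow the contour progressively below the additive line
  iso1 <- isobologram(mk(1), L, d1max = D1, n = 60)
  iso10 <- isobologram(mk(10), L, d1max = D1, n = 60)
  mid <- which.min(abs(iso0$d1 - D1 / 2))
  expect_lt(iso1$d2[mid], iso0$d2[mid])
  expect_lt(iso10$d2[mid], iso1$d2[mid])
  expect_error(isobologram(mk(1), 1.2), "outside the achievable range")
})
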