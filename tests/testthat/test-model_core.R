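test_that("reference model has the declared structure", {
  m <- ref_model()
  expect_equal(nrow(m$species), 52)
  expect_equal(nrow(m$parameters), 69)
  expect_equal(sum(m$parameters$free), 56)
  expect_false(anyDuplicated(m$species$name) > 0)
  expect_true(all(m$species$initial >= 0))
  # every active signaling species pairs with an inactive partner in the
  # same conservation group
  act <- m$species$name[m$species$role == "signaling_active"]
  for (a in act) {
    g <- Filter(function(g) a %in% g, m$groups)
    expect_length(g, 1)
    partners <- m$species$role[m$species$name %in% setdiff(g[[1]], a)]
    expect_true("signaling_inactive" %in% partners)
  }
})

test_that("conservation groups sum to their stored totals at t = 0", {
  m <- ref_model()
  init <- setNames(m$species$initial, m$species$name)
  for (g in names(m$groups)) {
    expect_equal(sum(init[m$groups[[g]]]),
                 sum(m$species$initial[m$species$name %in% m$groups[[g]]]))
  }
})

test_that("structural validation names the offending entity", {
  m <- ref_model()
  bad <- m
  bad$readouts$pAkt <- "NoSuchSpecies"
  expect_error(validate_model(bad), "NoSuchSpecies")
  bad2 <- m
  bad2$reactions[[1]]$rate <- "k_not_a_param*Met"
  expect_error(validate_model(bad2), "k_not_a_param")
})

test_that("fast and declarative derivative paths agree exactly", {
  m <- ref_model()
  set.seed(42)
  for (i in 1:3) {
    st <- setNames(abs(rnorm(52, 5e4, 3e4)), m$species$name)
    d_fast <- derivatives(m, st, fast = TRUE)
    d_gen <- derivatives(m, st, fast = FALSE)
    expect_equal(d_fast, d_gen, tolerance = 1e-12)
  }
})

test_that("derivatives conserve every intracellular group at any state", {
  m <- ref_model()
  set.seed(7)
  for (i in 1:3) {
    st <- setNames(abs(rnorm(52, 1e4, 8e3)), m$species$name)
    d <- derivatives(m, st)
    for (g in names(m$groups))
      expect_lt(abs(sum(d[m$groups[[g]]])), 1e-8 * max(abs(d)))
  }
})

test_that("internalization flux is linear in its rate constant", {
  m <- ref_model()
  st <- setNames(numeric(52), m$species$name)
  st["pMet"] <- 1000
  d1 <- derivatives(m, st)[["pMet_i"]]
  m2 <- set_params(m, c(kint_pMet = 2 * model_params(m)[["kint_pMet"]]))
  d2 <- derivatives(m2, st)[["pMet_i"]]
  expect_equal(d2, 2 * d1)
})

test_that("derivative evaluation rejects malformed states", {
  m <- ref_model()
  expect_error(derivatives(m, rep(1, 10)), "species count")
  st <- setNames(numeric(52), m$species$name)
  st["Met"] <- -5
  expect_error(derivatives(m, st), "negative")
})

test_that("unstimulated model sits at a steady state", {
  m <- ref_model()
  bs <- hgfmet:::basal_state(m)
  d <- derivatives(m, pmax(bs, 0))
  live <- setdiff(m$species$name, c("Met_deg", "Itg_deg"))
  scale <- pmax(bs[live], 1)
  expect_lt(max(abs(d[live]) / scale), 1e-5)
  tr <- simulate_condition(m, condition(hgf = 0,
                                        output_times = c(0, 60, 120)))
  for (rd in c("pAkt", "pERK")) {
    v <- readout_values(tr, rd)
    expect_lt(max(abs(v - v[1])) / v[1], 0.01)
  }
})

test_that("trajectories conserve groups and stay non-negative", {
  m <- ref_model()
  tr <- ref_traj()
  expect_lt(max(conservation_residual(tr, m)), 1e-6)
  expect_true(all(tr$state >= -1e-6))
  trd <- simulate_condition(
    m, apply_cabozantinib(base_cond(), 100))
  expect_lt(max(conservation_residual(trd, m)), 1e-6)
  expect_true(all(trd$state >= -1e-6))
})

test_that("adaptive solver matches an independent RK4 integration", {
  m <- ref_model()
  y0 <- hgfmet:::basal_state(m)
  y0["HGF"] <- 40 * model_params(m)[["f_HGF"]]
  rk <- rk4_integrate(m, y0, t_end = 30, dt = 0.002)
  tr <- simulate_condition(m, condition(hgf = 40, t_end = 30,
                                        output_times = c(0, 30)))
  for (rd in c("pAkt", "pERK", "pMet_total")) {
    expect_rel_equal(readout_values(tr, rd, 30),
                     state_readout(m, rk, rd), 1e-3)
  }
})

test_that("HGF stimulation reproduces the trafficking anchor dynamics", {
  m <- ref_model()
  tr <- ref_traj()
  fr15 <- met_internalized_fraction(tr, m, 15)
  expect_gt(fr15, 0.35)
  expect_lt(fr15, 0.65)
  share <- pmet_internal_share(tr, 120)
  expect_gt(share, 0.6)
  expect_lt(share, 0.85)
})

test_that("integrin knockout lowers pAkt more than pERK", {
  m <- ref_model()
  ko <- fixture("ko_scenario", function()
    integrin_knockout_scenario(m, base_cond()))
  a0 <- readout_values(ko$baseline, "pAkt", 120)
  a1 <- readout_values(ko$knockout, "pAkt", 120)
  e0 <- readout_values(ko$baseline, "pERK", 120)
  e1 <- readout_values(ko$knockout, "pERK", 120)
  expect_lt(a1, a0)
  expect_lt((e0 - e1) / e0, (a0 - a1) / a0)
})

test_that("knockout is idempotent when association is already absent", {
  m <- set_params(ref_model(), c(kon_MetItg = 0))
  ko <- integrin_knockout_scenario(m, base_cond(times = c(0, 60, 120)))
  expect_equal(ko$baseline$readouts, ko$knockout$readouts,
               tolerance = 1e-8)
})

test_that("equalizing trafficking rates removes the knockout difference", {
  m <- ref_model()
  p <- model_params(m)
  m_eq <- set_params(m, c(
    kint_MetItg = p[["kint_Met"]], kint_pMetItg = p[["kint_pMet"]],
    kdeg_MetItgi = p[["kdeg_Meti"]], krec_MetItgi = p[["krec_Meti"]]))
  ko <- integrin_knockout_scenario(m_eq, base_cond(times = c(0, 120)))
  a0 <- readout_values(ko$baseline, "pAkt", 120)
  a1 <- readout_values(ko$knockout, "pAkt", 120)
  expect_lt(abs(a1 - a0) / a0, 0.01)
})

test_that("percent inhibition behaves as a normalized difference", {
  m <- ref_model()
  cond <- base_cond(times = c(0, 120))
  expect_equal(percent_inhibition(m, cond, cond, "pAkt", 120), 0)
  pi_cabo <- percent_inhibition(
    m, apply_cabozantinib(cond, 5000), cond, "pAkt", 120)
  expect_gt(pi_cabo, 85)
  pi_sor <- percent_inhibition(
    m, with_node_inhibitor(cond, "Raf", 1000), cond, "pAkt", 120)
  expect_lt(pi_sor, 5)
})

test_that("higher HGF doses raise both arms of the pathway", {
  m <- ref_model()
  lo <- simulate_condition(m, condition(hgf = 10,
                                        output_times = c(0, 15, 120)))
  hi <- simulate_condition(m, condition(hgf = 100,
                                        output_times = c(0, 15, 120)))
  for (rd in c("pAkt", "pERK", "pMet_surface", "pMet_internal"))
    expect_gt(readout_values(hi, rd, 120), readout_values(lo, rd, 120))
})
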