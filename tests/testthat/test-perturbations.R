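test_that("zero doses leave the trajectories unchanged", {
  m <- ref_model()
  cond <- base_cond(times = c(0, 30, 120))
  tr0 <- simulate_condition(m, cond)
  expect_identical(apply_axt050(cond, 0), cond)
  expect_identical(apply_cabozantinib(cond, 0), cond)
  expect_identical(apply_rilotumumab_condition(cond, 0), cond)
  ni <- apply_node_inhibitor(m, "MEK", strength = 0)
  cond_ni <- cond
  cond_ni$drugs <- c(cond_ni$drugs, ni$drugs)
  tr_ni <- simulate_condition(ni$model, cond_ni)
  expect_equal(tr_ni$readouts, tr0$readouts, tolerance = 1e-10)
})

test_that("AXT050 dose series inhibits pMet, pAkt and pERK progressively", {
  m <- ref_model()
  doses <- c(0, 1e3, 1e4, 5e4)
  vals <- sapply(doses, function(d) {
    tr <- simulate_condition(m, apply_axt050(base_cond(c(0, 120)), d))
    c(readout_values(tr, "pMet_total", 120),
      readout_values(tr, "pAkt", 120),
      readout_values(tr, "pERK", 120))
  })
  for (i in 1:3) expect_true(all(diff(vals[i, ]) < 0))
})

test_that("saturating AXT050 approaches the no-association limit", {
  m <- ref_model()
  cond <- base_cond(times = c(0, 120))
  # the mechanistic limit of total integrin sequestration is the model
  # with the Met-integrin association switched off (receptor synthesis
  # unchanged, unlike the receptor-preserving knockout scenario)
  m_no <- set_params(m, c(kon_MetItg = 0))
  a_no <- readout_values(simulate_condition(m_no, cond), "pAkt", 120)
  a_base <- readout_values(simulate_condition(m, cond), "pAkt", 120)
  tr <- simulate_condition(m, apply_axt050(cond, 5e6, pre_incubation = 600))
  a_sat <- readout_values(tr, "pAkt", 120)
  expect_lt(abs(a_sat - a_no), 0.25 * abs(a_base - a_no))
})

test_that("cabozantinib occupies half the free receptor at its Kd", {
  # isolate the binding equilibrium from the integrin-ejection route
  m <- set_params(ref_model(), c(kon_MetItg = 0))
  p <- model_params(m)
  kd <- p[["koff_Cabo"]] / p[["kon_Cabo"]]
  tr <- simulate_condition(
    m, condition(hgf = 0, drugs = c(cabozantinib = kd),
                 pre_incubation = c(cabozantinib = 2000),
                 t_end = 10, output_times = c(0, 10)))
  st <- tr$state[1, ]
  occ <- st[["Met_Cabo"]] / (st[["Met"]] + st[["Met_Cabo"]])
  expect_gt(occ, 0.42)
  expect_lt(occ, 0.58)
})

test_that("rilotumumab ligand depletion follows the closed form", {
  expect_equal(apply_rilotumumab(0, 0.5, 0.1), 0.5)
  expect_equal(apply_rilotumumab(0.1, 0.5, 0.1), 0.25)
  expect_equal(apply_rilotumumab(0.4, 0.5, 0.1), 0.1)
  expect_error(apply_rilotumumab(1, 0.5, 0), "kd")
})

test_that("saturating rilotumumab converges to the unstimulated baseline", {
  m <- ref_model()
  tr_inf <- simulate_condition(
    m, apply_rilotumumab_condition(base_cond(c(0, 120)), 1e6))
  tr_0 <- simulate_condition(m, condition(hgf = 0,
                                          output_times = c(0, 120)))
  tr_ref <- simulate_condition(m, base_cond(c(0, 120)))
  for (rd in c("pAkt", "pERK", "pMet_total")) {
    # compare on the scale of the stimulated signal: the unstimulated
    # phospho-receptor level is essentially zero
    gap <- abs(readout_values(tr_inf, rd, 120) -
                 readout_values(tr_0, rd, 120))
    expect_lt(gap, 0.02 * readout_values(tr_ref, rd, 120))
  }
})

test_that("MEK inhibition raises pMEK through feedback release", {
  m <- ref_model()
  t0 <- ref_traj()
  tm <- simulate_condition(m, with_node_inhibitor(base_cond(), "MEK"))
  expect_gt(readout_values(tm, "pMEK", 120),
            readout_values(t0, "pMEK", 120))
  # direct downstream targets fall
  for (rd in c("pERK", "pRSK", "ppRSK"))
    expect_lt(readout_values(tm, rd, 120), readout_values(t0, rd, 120))
})

test_that("PDK1 inhibition cuts pAkt deeper than MEK inhibition", {
  m <- ref_model()
  t0 <- ref_traj()
  tm <- simulate_condition(m, with_node_inhibitor(base_cond(), "MEK"))
  tp <- simulate_condition(m, with_node_inhibitor(base_cond(), "PDK1"))
  a0 <- readout_values(t0, "pAkt", 120)
  expect_lt(readout_values(tp, "pAkt", 120),
            readout_values(tm, "pAkt", 120))
  expect_lt(readout_values(tp, "pAkt", 120), 0.5 * a0)
  # PDK1 inhibition has only a minor effect on pMEK
  expect_rel_equal(readout_values(tp, "pMEK", 120),
                   readout_values(t0, "pMEK", 120), 0.25)
})

test_that("unknown node inhibitor targets are rejected", {
  expect_error(apply_node_inhibitor(ref_model(), "Src"), "unknown node")
  expect_error(with_node_inhibitor(base_cond(), "Src"), "unknown node")
})

test_that("perturbations compose commutatively and reversibly", {
  m <- ref_model()
  cond <- base_cond(times = c(0, 120))
  c12 <- apply_cabozantinib(apply_axt050(cond, 1e4), 100)
  c21 <- apply_axt050(apply_cabozantinib(cond, 100), 1e4)
  t12 <- simulate_condition(m, c12)
  t21 <- simulate_condition(m, c21)
  expect_equal(t12$readouts, t21$readouts, tolerance = 1e-10)
  # apply-then-remove a node inhibitor restores the original model
  s0 <- model_params(m)[["s_MEKi"]]
  m2 <- apply_node_inhibitor(m, "MEK", strength = 0.5)$model
  m3 <- apply_node_inhibitor(m2, "MEK", strength = s0)$model
  expect_equal(model_params(m3), model_params(m))
})

test_that("sorafenib blocks pERK while sparing or raising pAkt", {
  m <- ref_model()
  t0 <- ref_traj()
  ts <- simulate_condition(m, with_node_inhibitor(base_cond(), "Raf", 1000))
  expect_lt(readout_values(ts, "pERK", 120),
            0.25 * readout_values(t0, "pERK", 120))
  expect_gt(readout_values(ts, "pAkt", 120),
            0.95 * readout_values(t0, "pAkt", 120))
})
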