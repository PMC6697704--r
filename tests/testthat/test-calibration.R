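# Calibration machinery: objective self-consistency, pattern-search
# convergence on analytic problems, and parameter recovery on noise-free
# synthetic data.

calib_fixture <- function() {
  fixture("calib_fixture", function() {
    m <- ref_model()
    conds <- list(hgf = condition(hgf = 40,
                                  output_times = c(0, 5, 15, 30, 60, 120)))
    datasets <- generate_timecourses(
      m, conditions = conds, readouts = c("pAkt", "pERK", "pMEK"),
      times = c(5, 15, 30, 60, 120), cv = 0, n_rep = 1, seed = 11,
      normalization = "condition_max")
    list(model = m, datasets = datasets)
  })
}

test_that("objective vanishes for data generated from the same model", {
  fx <- calib_fixture()
  p <- model_params(fx$model)[c("kact_Akt", "kdeact_ERK")]
  cost <- calibration_objective(p, fx$model, fx$datasets,
                                normalization = "condition_max")
  expect_lt(cost, 1e-8)
})

test_that("objective increases when a parameter leaves the truth", {
  fx <- calib_fixture()
  p0 <- model_params(fx$model)["kact_Akt"]
  c0 <- calibration_objective(p0, fx$model, fx$datasets,
                              normalization = "condition_max")
  c1 <- calibration_objective(p0 * 10, fx$model, fx$datasets,
                              normalization = "condition_max")
  expect_gt(c1, c0 + 1e-3)
})

test_that("objective requires non-empty datasets and penalizes failures", {
  fx <- calib_fixture()
  expect_error(calibration_objective(c(kact_Akt = 1), fx$model, list()),
               "non-empty")
  # an absurd parameter that breaks the simulation yields the penalty
  cost <- suppressWarnings(calibration_objective(c(kact_Met = 1e300),
                                                 fx$model, fx$datasets))
  expect_true(is.finite(cost))
})

test_that("pattern search solves a quadratic bowl in 5-D", {
  ctr <- c(a = 2, b = 0.5, c = 30, d = 1, e = 5)
  fn <- function(x) sum((log10(x) - log10(ctr))^2)
  x0 <- ctr * c(8, 0.2, 3, 0.1, 6)
  fit <- pattern_search(fn, x0, ctr / 1000, ctr * 1000,
                        step0 = 0.5, tol = 1e-6, max_eval = 5000)
  expect_lt(max(abs(log10(fit$par) - log10(ctr))), 1e-4)
  expect_lt(fit$value, 1e-7)
})

test_that("pattern search is monotone, deterministic, and stays at optima", {
  ctr <- c(a = 1, b = 10)
  fn <- function(x) sum((log10(x) - log10(ctr))^2)
  fit0 <- pattern_search(fn, ctr, ctr / 10, ctr * 10, max_eval = 100)
  expect_identical(unname(fit0$par), unname(ctr))
  expect_length(fit0$trace, 1)       # zero accepted moves
  x0 <- c(a = 3, b = 2)
  f1 <- pattern_search(fn, x0, ctr / 10, ctr * 10, max_eval = 200)
  f2 <- pattern_search(fn, x0, ctr / 10, ctr * 10, max_eval = 200)
  expect_identical(f1$par, f2$par)
  expect_true(all(diff(f1$trace) <= 0))
  expect_lte(f1$value, fn(x0))
})

test_that("noise-free synthetic data recover known parameters within 10%", {
  m <- ref_model()
  # the two deactivation rates shape the pAkt/pERK decay and are cleanly
  # identifiable from shape-normalized single-condition time courses
  truth <- model_params(m)[c("kdeact_Akt", "kdeact_ERK")]
  conds <- list(hgf = condition(hgf = 40,
                                output_times = c(0, 5, 15, 30, 60, 120)))
  datasets <- generate_timecourses(
    m, conditions = conds, readouts = c("pAkt", "pERK"),
    times = c(5, 15, 30, 60, 120), cv = 0, n_rep = 1, seed = 3,
    normalization = "condition_max")
  x0 <- truth * c(3, 0.4)
  fit <- pattern_search(
    function(x) calibration_objective(x, m, datasets,
                                      normalization = "condition_max"),
    x0, truth / 30, truth * 30, step0 = 0.3, tol = 1e-7, max_eval = 320)
  expect_lt(max(abs(fit$par / truth - 1)), 0.10)
  # recovered objective is no worse than at the truth
  expect_lte(fit$value,
             calibration_objective(truth, m, datasets,
                                   normalization = "condition_max") + 1e-6)
})

test_that("inhibitor strengths are recovered from mono-treatment data", {
  m <- ref_model()
  truth_strength <- 0.8
  m_truth <- set_params(m, c(s_MEKi = truth_strength))
  conds <- list(meki = with_node_inhibitor(
    condition(hgf = 40, output_times = c(0, 15, 60, 120)), "MEK"))
  # normalized against the drug-free control, so the inhibition depth is
  # visible to the objective
  datasets <- generate_timecourses(
    m_truth, conditions = conds, readouts = c("pERK", "pMEK"),
    times = c(15, 60, 120), cv = 0, n_rep = 1, seed = 5)
  st <- fit_inhibitor_strengths(set_params(m, c(s_MEKi = 0.3)), datasets,
                                nodes = "MEK", step0 = 0.3, tol = 1e-3,
                                max_eval = 80)
  expect_lt(abs(st[["MEK"]] - truth_strength), 0.05)
})

test_that("zero-effect mono data drive fitted strengths to zero", {
  m <- ref_model()
  # data generated WITHOUT the inhibitor, fitted WITH the inhibitor on
  conds_off <- list(meki = condition(hgf = 40,
                                     output_times = c(0, 15, 60, 120)))
  datasets <- generate_timecourses(
    m, conditions = conds_off, readouts = c("pERK",  "pMEK"),
    times = c(15, 60, 120), cv = 0, n_rep = 1, seed = 6,
    normalization = "condition_max")
  datasets <- lapply(datasets, function(d) {
    d$condition <- with_node_inhibitor(d$condition, "MEK")
    d
  })
  st <- fit_inhibitor_strengths(m, datasets, nodes = "MEK", step0 = 0.5,
                                tol = 2e-3, max_eval = 80)
  expect_lt(st[["MEK"]], 0.05)
})

test_that("mono-fitted strengths predict the Met+PDK1 combination", {
  m <- ref_model()
  cond0 <- condition(hgf = 40, output_times = c(0, 15, 120))
  combo <- with_node_inhibitor(with_node_inhibitor(cond0, "Met"), "PDK1")
  t0 <- simulate_condition(m, cond0)
  tc <- simulate_condition(m, combo)
  for (tv in c(15, 120))
    expect_lt(readout_values(tc, "pAkt", tv),
              0.6 * readout_values(t0, "pAkt", tv))
})
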