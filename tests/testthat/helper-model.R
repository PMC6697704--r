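# Shared fixtures.  The reference model and its commonly used trajectories
# are built once per test run and cached; model caches make repeat
# simulations of the same parameterization cheap.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

ref_model <- function() fixture("ref_model", build_reference_model)

base_cond <- function(times = c(0, 5, 15, 30, 60, 90, 120)) {
  condition(hgf = 40, output_times = times)
}

ref_traj <- function() fixture("ref_traj", function()
  simulate_condition(ref_model(), base_cond()))

# independent fixed-step fourth-order Runge-Kutta integrator (oracle for
# the adaptive stiff solver); returns the state at `t_end`
rk4_integrate <- function(model, y0, t_end, dt) {
  f <- hgfmet:::make_rhs(model)
  y <- as.numeric(y0)
  n <- round(t_end / dt)
  t <- 0
  for (i in seq_len(n)) {
    k1 <- f(t, y)[[1]]
    k2 <- f(t + dt / 2, y + dt / 2 * k1)[[1]]
    k3 <- f(t + dt / 2, y + dt / 2 * k2)[[1]]
    k4 <- f(t + dt, y + dt * k3)[[1]]
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  setNames(y, names(y0))
}

# evaluate a readout on a raw state vector
state_readout <- function(model, y, readout) {
  sum(y[model$readouts[[readout]]])
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected),
                                         .Machine$double.eps), tol)
}
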