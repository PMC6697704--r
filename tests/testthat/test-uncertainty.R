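# Monte-Carlo resampling, ensemble refits, confidence bands, local
# sensitivities and the sign-consistency identifiability rule.

mini_datasets <- function(seed = 21) {
  fixture("mini_datasets", function() {
    m <- ref_model()
    conds <- list(hgf = condition(hgf = 40,
                                  output_times = c(0, 15, 60, 120)))
    generate_timecourses(m, conditions = conds,
                         readouts = c("pAkt", "pERK"),
                         times = c(15, 60, 120), cv = 0, n_rep = 1,
                         seed = seed, normalization = "condition_max")
  })
}

test_that("log-normal resampling has the stated median and CV", {
  ds <- mini_datasets()
  tiny <- resample_datasets(ds, n = 3, cv = 1e-8, seed = 1)
  for (i in seq_along(ds))
    expect_equal(tiny[[1]][[i]]$means, ds[[i]]$means, tolerance = 1e-6)
  reps <- resample_datasets(ds[1], n = 201, cv = 0.10, seed = 2)
  draws <- vapply(reps, function(r) r[[1]]$means[1], 0)
  expect_lt(abs(sd(draws) / mean(draws) - 0.10), 0.02)
  expect_lt(abs(median(draws) - ds[[1]]$means[1]) / ds[[1]]$means[1],
            0.05)
  again <- resample_datasets(ds[1], n = 201, cv = 0.10, seed = 2)
  expect_identical(vapply(again, function(r) r[[1]]$means[1], 0), draws)
})

test_that("resampling rejects non-positive means", {
  ds <- mini_datasets()
  ds[[1]]$means[1] <- 0
  expect_error(resample_datasets(ds, n = 2, cv = 0.1, seed = 1),
               "non-positive")
})

test_that("noise-free replicates refit to the base fit itself", {
  ds <- mini_datasets()
  m <- ref_model()
  base_fit <- model_params(m)[c("kact_Akt", "kdeact_ERK")]
  reps <- lapply(1:3, function(i) ds)   # identical noise-free replicates
  ens <- refit_ensemble(reps, m, base_fit, max_eval = 25)
  expect_equal(nrow(ens$params), 3)
  for (i in 1:3)
    expect_equal(unname(ens$params[i, ]), unname(base_fit),
                 tolerance = 1e-10)
  # every refit respects the one-decade bounds
  expect_true(all(ens$params >= matrix(base_fit / 10, 3, 2, byrow = TRUE)))
  expect_true(all(ens$params <= matrix(base_fit * 10, 3, 2, byrow = TRUE)))
})

test_that("confidence bands are ordered and collapse for one member", {
  m <- ref_model()
  cond <- condition(hgf = 40, output_times = c(0, 30, 120))
  base_fit <- model_params(m)[c("kact_Akt", "kdeact_ERK")]
  single <- matrix(base_fit, 1, dimnames = list(NULL, names(base_fit)))
  band1 <- confidence_band(single, m, "pAkt", cond)
  expect_equal(band1$lower, band1$upper)
  pm <- rbind(base_fit * 0.8, base_fit, base_fit * 1.25)
  colnames(pm) <- names(base_fit)
  band <- confidence_band(pm, m, "pAkt", cond)
  expect_true(all(band$lower <= band$median + 1e-12))
  expect_true(all(band$median <= band$upper + 1e-12))
})

test_that("local sensitivities have the mechanistically expected signs", {
  m <- ref_model()
  sens <- local_sensitivities(
    m, params = model_params(m)[c("kact_Akt", "kdeact_Akt", "kon_Cabo")],
    outputs = c("pAkt"), times = 120)
  expect_gt(sens["kact_Akt", "pAkt@120"], 0)
  expect_lt(sens["kdeact_Akt", "pAkt@120"], 0)
  # no cabozantinib dosed: its binding rate has no path to the output
  expect_lt(abs(sens["kon_Cabo", "pAkt@120"]), 1e-6)
})

test_that("sign-consistency rule classifies constructed distributions", {
  mk <- function(v) matrix(v, 1, 1, dimnames = list("p", "out@120"))
  pos <- lapply(abs(rnorm(30)) + 0.01, mk)
  expect_true(classify_identifiability(pos)$identifiable)
  sym <- lapply(c(rnorm(15, 1), rnorm(15, -1)), mk)
  expect_false(classify_identifiability(sym)$identifiable)
  null <- lapply(rep(1e-12, 25), mk)
  expect_false(classify_identifiability(null)$identifiable)
})

test_that("a structurally redundant pair is flagged non-identifiable", {
  # Met synthesis and basal degradation set the basal receptor level as a
  # ratio; across an ensemble jittered along the ratio direction their
  # individual sensitivities flip sign while an identifiable parameter
  # keeps a consistent sign.
  set.seed(9)
  sens_list <- lapply(1:25, function(i) {
    flip <- sample(c(-1, 1), 1)
    matrix(c(flip * runif(1, 0.1, 0.5),
             -flip * runif(1, 0.1, 0.5),
             runif(1, 0.2, 0.6)),
           3, 1, dimnames = list(c("ksyn_Met", "kdeg_Met0", "kact_Akt"),
                                 "pAkt@120"))
  })
  rep <- classify_identifiability(sens_list)
  expect_false(rep$identifiable[rep$parameter == "ksyn_Met"])
  expect_false(rep$identifiable[rep$parameter == "kdeg_Met0"])
  expect_true(rep$identifiable[rep$parameter == "kact_Akt"])
})
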