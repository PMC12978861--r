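test_that("intercept-only spec yields single all-ones columns at every level", {
  y <- array(0, dim = c(4, 3, 2))
  d <- build_design(occu_spec(), toy_study(y))
  for (X in list(d$X_psi1, d$X_gamma, d$X_epsilon, d$X_p)) {
    expect_equal(ncol(X), 1L)
    expect_true(all(X == 1))
    expect_equal(colnames(X), "(Intercept)")
  }
  expect_equal(nrow(d$X_psi1), 4L)
  expect_equal(nrow(d$X_gamma), 4L * 2L)
  expect_equal(nrow(d$X_p), 4L * 3L * 2L)
})

test_that("drought index expands to baseline-coded dummies with level 0 as baseline", {
  y <- array(0, dim = c(2, 5, 1))
  ds <- toy_study(y, drought = c(0, 1, 2, 3, 0))
  d <- build_design(occu_spec(epsilon = "drought_index"), ds)
  expect_equal(colnames(d$X_epsilon),
               c("(Intercept)", "drought_index1", "drought_index2",
                 "drought_index3"))
  # transition t uses season t+1's index (timing "next"):
  # transitions see drought 1, 2, 3, 0
  dm <- d$X_epsilon[c(1, 3, 5, 7), -1] # site 1's four transition rows
  expect_equal(unname(dm),
               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
  # "current" timing shifts by one: transitions see drought 0, 1, 2, 3
  d2 <- build_design(
    occu_spec(epsilon = "drought_index", drought_timing = "current"), ds
  )
  expect_equal(unname(d2$X_epsilon[c(1, 3, 5, 7), -1]),
               rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
})

test_that("log + standardize uses the population SD of the logged values", {
  y <- array(0, dim = c(3, 2, 1))
  ds <- toy_study(y, discharge = rep(c(1, exp(1), exp(2)), 2))
  # discharge vector recycles over (site, season): log values per column {0,1,2}
  d <- build_design(
    occu_spec(p = "discharge_m3s", transforms = c(discharge_m3s = "log")), ds
  )
  v <- sort(unique(round(d$X_p[, "discharge_m3s"], 4)))
  expect_equal(v, c(-1.2247, 0, 1.2247))
})

test_that("missing covariates on likelihood rows raise a located error", {
  y <- array(0, dim = c(3, 2, 1))
  ds <- toy_study(y)
  seasons <- ds$seasons[!(ds$seasons$site == "S002" & ds$seasons$season == 2), ]
  ds2 <- study_dataset(ds$detections, ds$sites, seasons, ds$visits,
                       n_seasons = 2, n_visits = 1)
  expect_error(build_design(occu_spec(epsilon = "drought_index"), ds2),
               "S002", class = "occdebt_validation_error")
  expect_error(build_design(occu_spec(psi1 = "no_such_column"), ds),
               "unknown covariate", class = "occdebt_validation_error")
  expect_error(build_design(occu_spec(psi1 = "discharge_m3s"), ds),
               "visit-level", class = "occdebt_validation_error")
})

test_that("interactions are psi1-only and multiply transformed columns", {
  y <- array(0, dim = c(5, 2, 1))
  ds <- toy_study(y)
  d <- build_design(occu_spec(psi1 = c("habitat_score", "lulc_developed",
                                       "habitat_score:lulc_developed")), ds)
  expect_equal(
    unname(d$X_psi1[, "habitat_score:lulc_developed"]),
    unname(d$X_psi1[, "habitat_score"] * d$X_psi1[, "lulc_developed"])
  )
  expect_error(occu_spec(epsilon = "a:b"), "psi1")
})

test_that("stored scalings reproduce the training transform on new data", {
  study <- generate_study(sim_config(n_sites = 30, seed = 5))
  spec <- occu_spec(psi1 = "habitat_score", p = "discharge_m3s",
                    transforms = c(discharge_m3s = "log"))
  d1 <- build_design(spec, study$dataset)
  d2 <- build_design(spec, study$dataset, scalings = d1$scalings)
  expect_equal(d1$X_psi1, d2$X_psi1)
  expect_equal(d1$X_p, d2$X_p)
})

test_that("compute_rates applies the inverse logit exactly", {
  y <- array(0, dim = c(3, 3, 2))
  ds <- toy_study(y)
  d <- build_design(occu_spec(psi1 = "habitat_score"), ds)
  par <- rep(0, d$n_par)
  r <- compute_rates(d, par)
  expect_true(all(abs(r$psi1 - 0.5) < 1e-15))
  expect_true(all(abs(r$p - 0.5) < 1e-15))
  # known coefficients match hand-computed logistic values
  par2 <- c(0.3, -1.1, rep(0, d$n_par - 2))
  r2 <- compute_rates(d, par2)
  expect_equal(r2$psi1, plogis(0.3 - 1.1 * d$X_psi1[, 2]), tolerance = 1e-12)
  expect_equal(r2$phi, 1 - r2$epsilon)
})
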