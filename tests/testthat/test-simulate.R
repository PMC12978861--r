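test_that("simulation is deterministic under the config seed", {
  cfg <- sim_config(n_sites = 40, seed = 31)
  a <- simulate_covariates(cfg)
  b <- simulate_covariates(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$visits, b$visits)
  expect_identical(a$surveyed, b$surveyed)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$dataset$y, s2$dataset$y)
  expect_identical(s1$truth$Z, s2$truth$Z)
})

test_that("covariate distributions respect their bounds and parameters", {
  cfg <- sim_config(
    n_sites = 10000, seed = 2,
    covariates = list(lulc_developed = list(shape1 = 2, shape2 = 5),
                      lulc_herbpasture = list(shape1 = 1, shape2 = 50),
                      lulc_crop = list(shape1 = 1, shape2 = 50),
                      lulc_wetland = list(shape1 = 1, shape2 = 50))
  )
  cov <- simulate_covariates(cfg)
  dev <- cov$sites$lulc_developed
  expect_true(all(dev >= 0 & dev <= 1))
  # beta(2,5) mean 2/7; MC error at n = 10,000 is about 0.0016
  expect_lt(abs(mean(dev) - 2 / 7), 3 * sqrt(2 / 7 * 5 / 7 / 8) / sqrt(10000) + 0.01)
  expect_true(all(cov$sites$habitat_score >= 0 & cov$sites$habitat_score <= 100))
  expect_true(all(cov$sites$tqmean >= 0 & cov$sites$tqmean <= 1))
  expect_error(sim_config(covariates = list(habitat = list(sd = -1))),
               "degenerate")
})

test_that("latent dynamics obey the Markov recursion", {
  # absorbing extinction: occupancy only possible in season 1
  cfg <- sim_config(n_sites = 300, seed = 3,
                    spec = occu_spec(),
                    beta = list(psi1 = 0.5, gamma = -30, epsilon = 30, p = 0))
  cov <- simulate_covariates(cfg)
  Z <- simulate_latent(cfg, cov)
  expect_true(all(Z[, 2:5] == 0))
  expect_gt(mean(Z[, 1]), 0.4)

  # empirical trajectory tracks the recursion within Monte Carlo error
  cfg2 <- sim_config(n_sites = 4000, seed = 4, spec = occu_spec(),
                     beta = list(psi1 = qlogis(0.3), gamma = qlogis(0.25),
                                 epsilon = qlogis(0.25), p = 0))
  cov2 <- simulate_covariates(cfg2)
  Z2 <- simulate_latent(cfg2, cov2)
  psi <- 0.3
  for (t in 1:5) {
    mc_se <- sqrt(psi * (1 - psi) / 4000)
    expect_lt(abs(mean(Z2[, t]) - psi), 3 * mc_se + 1e-9)
    psi <- occupancy_recursion(psi, 0.25, 0.25)
  }
  # gamma = epsilon pulls the chain towards one half
  expect_lt(abs(mean(Z2[, 5]) - 0.5), 0.1)
})

test_that("detections are Bernoulli thinnings of the latent state", {
  cfg <- sim_config(n_sites = 500, seed = 5, spec = occu_spec(),
                    beta = list(psi1 = 0.4, gamma = -1, epsilon = -1, p = 30))
  cov <- simulate_covariates(cfg)
  Z <- simulate_latent(cfg, cov)
  ds <- simulate_detections(Z, cfg, cov)
  # p ~ 1: detections equal the latent state at every surveyed visit
  for (t in 1:5) {
    surv <- cov$surveyed[, t]
    expect_true(all(ds$y[surv, t, ] == Z[surv, t]))
  }
  # unoccupied sites never yield detections (no false positives)
  cfg0 <- sim_config(n_sites = 200, seed = 6, spec = occu_spec(),
                     beta = list(psi1 = -30, gamma = -30, epsilon = 0, p = 0))
  st0 <- generate_study(cfg0)
  expect_true(all(st0$dataset$y == 0, na.rm = TRUE))

  # per-visit detection frequency at occupied site-seasons matches p
  cfgp <- sim_config(n_sites = 2000, seed = 7, spec = occu_spec(),
                     beta = list(psi1 = 2, gamma = 0, epsilon = 0, p = qlogis(0.4)))
  covp <- simulate_covariates(cfgp)
  Zp <- simulate_latent(cfgp, covp)
  dsp <- simulate_detections(Zp, cfgp, covp)
  occ_obs <- !is.na(dsp$y) & array(rep(Zp == 1, 4), dim = dim(dsp$y))
  phat <- mean(dsp$y[occ_obs])
  expect_lt(abs(phat - 0.4), 3 * sqrt(0.4 * 0.6 / sum(occ_obs)))
})

test_that("the realized revisit design matches the configured mass", {
  cfg <- sim_config(n_sites = 1000, seed = 8)
  cov <- simulate_covariates(cfg)
  n_surv <- rowSums(cov$surveyed)
  for (k in 1:5) {
    pk <- cfg$revisit_probs[k]
    mc_se <- sqrt(pk * (1 - pk) / 1000)
    expect_lt(abs(mean(n_surv == k) - pk), 3 * mc_se + 1e-9)
  }
})

test_that("generated studies validate and carry a coherent truth record", {
  study <- generate_study(sim_config(n_sites = 35, seed = 9))
  expect_s3_class(study$dataset, "study_dataset")
  expect_true(all(study$dataset$y %in% c(0, 1) | is.na(study$dataset$y)))
  expect_identical(dim(study$truth$Z), c(35L, 5L))
  expect_named(study$truth$beta)
  expect_equal(length(study$truth$beta), 12L)
  # rates in the truth record agree with the generating coefficients
  expect_true(all(study$truth$rates$psi1 > 0 & study$truth$rates$psi1 < 1))
})
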