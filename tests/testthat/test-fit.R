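make_perfect_detection_study <- function(n = 400, T = 3, seed = 101) {
  set.seed(seed)
  psi1 <- 0.45; gamma <- 0.2; epsilon <- 0.3
  Z <- matrix(0L, n, T)
  Z[, 1] <- rbinom(n, 1, psi1)
  for (t in 2:T) {
    Z[, t] <- rbinom(n, 1, Z[, t - 1] * (1 - epsilon) + (1 - Z[, t - 1]) * gamma)
  }
  y <- array(rep(as.vector(Z), 2), dim = c(n, T, 2)) # p = 1: y == Z
  list(ds = toy_study(y), Z = Z)
}

test_that("with perfect detection the MLEs collapse to observed frequencies", {
  pd <- make_perfect_detection_study()
  fit <- fit_model(occu_spec(), pd$ds)
  Z <- pd$Z
  psi1_hat <- plogis(unname(fit$par[1]))
  expect_equal(psi1_hat, mean(Z[, 1]), tolerance = 1e-4)
  # transition frequencies
  from1 <- Z[, 1:2] == 1
  ext_obs <- sum(Z[, 2:3][from1] == 0) / sum(from1)
  col_obs <- sum(Z[, 2:3][!from1] == 1) / sum(!from1)
  expect_equal(plogis(unname(fit$par["gamma.(Intercept)"])), col_obs,
               tolerance = 1e-3)
  expect_equal(plogis(unname(fit$par["epsilon.(Intercept)"])), ext_obs,
               tolerance = 1e-3)
})

test_that("multi-start refits reach the same optimum", {
  study <- generate_study(sim_config(n_sites = 60, seed = 21))
  spec <- occu_spec(psi1 = "habitat_score", epsilon = "habitat_score",
                    p = "discharge_m3s", transforms = c(discharge_m3s = "log"))
  f0 <- fit_model(spec, study$dataset)
  f1 <- fit_model(spec, study$dataset, multi_start = 5, seed = 99)
  expect_lt(abs(f0$nll - f1$nll), 1e-6)
})

test_that("AICc follows its closed form and limits", {
  fake <- structure(list(nll = 5, K = 2, n_sites = 10), class = "occu_fit")
  expect_equal(aicc(fake), 14 + 12 / 7, tolerance = 1e-12)
  expect_lt(abs(aicc(fake, n_effective = 1e8) - 14), 1e-6)
  expect_gt(aicc(fake), 2 * 5 + 2 * 2) # strictly above AIC at finite n
  expect_error(aicc(fake, n_effective = 3), "exceed")
})

test_that("model ranking applies the delta rule, tie-breaks and exclusions", {
  mk <- function(name, nll, K, n = 100, converged = TRUE) {
    f <- structure(list(nll = nll, K = K, n_sites = n, converged = converged,
                        spec = list(name = name)), class = "occu_fit")
    f$aicc <- aicc(f)
    f
  }
  # choose NLLs so the AICc values are 100, 101.5, 104 at K = 2, n = 100
  base <- 2 * 2 + 2 * 2 * 3 / 97
  fits <- list(mk("a", (100 - base) / 2, 2),
               mk("b", (101.5 - base) / 2, 2),
               mk("c", (104 - base) / 2, 2))
  rk <- rank_models(fits)
  expect_equal(rk$delta_aicc, c(0, 1.5, 4), tolerance = 1e-10)
  expect_equal(rk$supported, c(TRUE, TRUE, FALSE))
  # a second-ranked model at delta 2.33 is not equally supported
  rk2 <- rank_models(list(mk("top", (100 - base) / 2, 2),
                          mk("next_", (102.33 - base) / 2, 2)))
  expect_false(rk2$supported[2])
  # identical AICc: fewer parameters wins, then name
  t1 <- mk("zeta", 50, 2)
  t2 <- mk("alpha", 50, 3)
  t2$aicc <- t1$aicc
  expect_equal(rank_models(list(t1, t2))$model[1], "zeta")
  t3 <- mk("alpha", 50, 2)
  t3$aicc <- t1$aicc
  expect_equal(rank_models(list(t1, t3))$model[1], "alpha")
  expect_warning(rank_models(list(t1, mk("bad", 49, 2, converged = FALSE))),
                 "non-converged")
  expect_error(
    suppressWarnings(rank_models(list(mk("bad", 1, 2, converged = FALSE)))),
    "no converged"
  )
})

test_that("standard errors and Wald columns are coherent", {
  study <- generate_study(sim_config(n_sites = 120, seed = 31))
  spec <- occu_spec(epsilon = "habitat_score", p = "discharge_m3s",
                    transforms = c(discharge_m3s = "log"))
  fit <- fit_model(spec, study$dataset)
  expect_true(fit$converged)
  expect_true(fit$se_available)
  td <- tidy(fit)
  expect_true(all(td$std_error > 0))
  expect_equal(td$conf_high - td$estimate, td$estimate - td$conf_low,
               tolerance = 1e-10)
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
  g <- glance(fit)
  expect_equal(g$aicc, aicc(fit))
})
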