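test_that("occupancy recursion handles the boundary, fixed-point and generic cases", {
  expect_equal(occupancy_recursion(1, 0.7, 0), 1)
  expect_equal(occupancy_recursion(0.5, 0.3, 0.3), 0.5)
  expect_equal(occupancy_recursion(0.4, 0.1, 0.2), 0.38, tolerance = 1e-12)
  expect_error(occupancy_recursion(1.2, 0.1, 0.1), class = "occdebt_domain_error")
})

test_that("turnover equals the two-state joint conditional probability", {
  expect_equal(turnover_probability(0, 0.4, 0.8), 0)
  expect_equal(turnover_probability(0.3, 0, 0.8), 1)
  expect_equal(turnover_probability(0.2, 0.5, 0.7), 0.1 / 0.45, tolerance = 1e-12)
  expect_error(turnover_probability(0, 0, 0.5), class = "occdebt_domain_error")
  # grid check against Pr(Z[t-1]=0, Z[t]=1) / Pr(Z[t]=1) from the explicit joint
  gr <- seq(0.05, 0.95, by = 0.15)
  for (g in gr) for (psi in gr) for (phi in gr) {
    joint01 <- (1 - psi) * g
    joint11 <- psi * phi
    want <- joint01 / (joint01 + joint11)
    expect_lt(abs(turnover_probability(g, psi, phi) - want), 1e-12)
  }
})

test_that("equilibrium occupancy is the recursion fixed point", {
  expect_equal(equilibrium_occupancy(0.2, 0.2), 0.5)
  expect_equal(equilibrium_occupancy(0.3, 0), 1)
  expect_equal(equilibrium_occupancy(0.185, 0.285), 0.185 / 0.470,
               tolerance = 1e-12)
  expect_error(equilibrium_occupancy(0, 0), class = "occdebt_domain_error")
  gr <- seq(0.05, 0.95, by = 0.1)
  for (g in gr) for (e in gr) {
    psi_eq <- equilibrium_occupancy(g, e)
    expect_lt(abs(occupancy_recursion(psi_eq, g, e) - psi_eq), 1e-12)
  }
})

test_that("smoothed occupancy matches enumerated conditional probabilities", {
  smr <- occdebt:::smoothed_from_rates
  for (s in 1:30) {
    inst <- random_instance(2000 + s)
    got <- smr(inst$psi1, inst$gamma, inst$epsilon, inst$p, inst$y)
    want <- oracle_study(inst$psi1, inst$gamma, inst$epsilon, inst$p, inst$y)$smoothed
    expect_lt(max(abs(got - want)), 1e-10)
    # exactly 1 wherever a detection occurred
    det <- apply(inst$y == 1, c(1, 2), any)
    det[is.na(det)] <- FALSE
    expect_true(all(got[det] == 1))
  }
})

test_that("perfect detection pins surveyed no-detection seasons at zero", {
  smr <- occdebt:::smoothed_from_rates
  y <- array(c(0, 1), dim = c(1, 2, 1))
  out <- smr(0.5, matrix(0.3, 1, 1), matrix(0.2, 1, 1),
             array(1 - 1e-12, dim = c(1, 2, 1)), y)
  expect_lt(out[1, 1], 1e-9)
  expect_equal(out[1, 2], 1)
})

test_that("smoothing exceeds the unconditional trajectory at detections and matches it with no data", {
  smr <- occdebt:::smoothed_from_rates
  inst <- random_instance(321)
  traj <- occdebt:::marginal_trajectory(
    list(psi1 = inst$psi1, gamma = inst$gamma, epsilon = inst$epsilon), inst$T
  )
  got <- smr(inst$psi1, inst$gamma, inst$epsilon, inst$p, inst$y)
  det <- apply(inst$y == 1, c(1, 2), any); det[is.na(det)] <- FALSE
  expect_true(all(got[det] >= traj[det] - 1e-12))
  # a site with every visit missing carries no information
  y_empty <- inst$y
  y_empty[1, , ] <- NA
  got2 <- smr(inst$psi1, inst$gamma, inst$epsilon, inst$p, y_empty)
  expect_equal(got2[1, ], traj[1, ], tolerance = 1e-12)
})

test_that("smoothed_occupancy on a fitted model is coherent with its rates", {
  study <- generate_study(sim_config(n_sites = 50, seed = 13))
  fit <- fit_model(occu_spec(p = "discharge_m3s",
                             transforms = c(discharge_m3s = "log")),
                   study$dataset)
  sm <- smoothed_occupancy(fit)
  expect_true(all(sm$psi_fs >= 0 & sm$psi_fs <= 1))
  expect_true(all(sm$psi_fs[sm$detected] == 1))
  r <- predict_rates(fit)
  direct <- occdebt:::smoothed_from_rates(r$psi1, r$gamma, r$epsilon, r$p,
                                          study$dataset$y)
  expect_equal(attr(sm, "matrix"), direct, ignore_attr = TRUE,
               tolerance = 1e-12)
})
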