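summ <- function(y, rates, sm, subpop, scope = "surveyed", mode = "plugin") {
  occdebt:::summarize_subpops(design_lite(y), rates, sm, subpop, scope, mode)
}

test_that("a single-site subpopulation with constant rates reproduces the site-level formulas", {
  T <- 4
  y <- array(0, dim = c(1, T, 2))
  rates <- rates_const(1, T, 2, 0.6, 0.25, 0.15, 0.5)
  sm <- matrix(c(0.55, 0.40, 0.70, 0.30), 1, T)
  out <- summ(y, rates, sm, "A")
  bs <- out$by_season
  expect_equal(bs$psi_fs, as.vector(sm))
  expect_equal(bs$gamma[1:3], rep(0.25, 3))
  expect_equal(bs$equilibrium[1:3], rep(equilibrium_occupancy(0.25, 0.15), 3))
  expect_true(is.na(bs$equilibrium[T])) # final season not reported
  expect_true(is.na(bs$turnover[T]))
  for (t in 2:(T - 1)) {
    expect_equal(bs$turnover[t],
                 turnover_probability(0.25, sm[1, t - 1], 0.85),
                 tolerance = 1e-12)
  }
  ov <- out$overall
  expect_equal(ov$occupancy, mean(sm))
  expect_equal(ov$non_equilibrium, mean(sm) - equilibrium_occupancy(0.25, 0.15))
})

test_that("subpopulation report arithmetic: non-equilibrium is occupancy minus equilibrium", {
  # constant-rate constructions whose means match published-style summary rows
  cases <- list(
    list(psi = 0.66, eq = 0.59, want = 0.07),   # stable, low-turnover unit
    list(psi = 0.25, eq = 0.28, want = -0.03),  # urban unit slightly below
    list(psi = 0.32, eq = 0.38, want = -0.06)   # urban unit below equilibrium
  )
  for (cs in cases) {
    gamma <- 0.12
    epsilon <- gamma * (1 - cs$eq) / cs$eq
    y <- array(0, dim = c(4, 4, 1))
    rates <- rates_const(4, 4, 1, 0.5, gamma, epsilon, 0.4)
    sm <- matrix(cs$psi, 4, 4)
    out <- summ(y, rates, sm, rep("U", 4))
    expect_equal(out$overall$non_equilibrium, cs$want, tolerance = 1e-10)
  }
})

test_that("summaries average only over sites surveyed in the season under the default scope", {
  y <- array(NA_real_, dim = c(2, 3, 1))
  y[1, , 1] <- 0            # site 1 surveyed every season
  y[2, 1, 1] <- 0           # site 2 surveyed only in season 1
  rates <- rates_const(2, 3, 1, 0.5, 0.2, 0.3, 0.5)
  rates$gamma[2, ] <- 0.6   # site 2 differs
  sm <- rbind(c(0.2, 0.4, 0.6), c(0.8, 0.5, 0.5))
  out <- summ(y, rates, sm, c("A", "A"))
  bs <- out$by_season
  expect_equal(bs$psi_fs, c(0.5, 0.4, 0.6))     # season 1 averages both sites
  expect_equal(bs$gamma[1], 0.4)                # (0.2 + 0.6) / 2
  expect_equal(bs$gamma[2], 0.2)                # site 1 only
  out_all <- summ(y, rates, sm, c("A", "A"), scope = "all")
  expect_equal(out_all$by_season$psi_fs, c(0.5, 0.45, 0.55))
})

test_that("subpopulation summaries are invariant to site ordering", {
  study <- generate_study(sim_config(n_sites = 60, seed = 17))
  fit <- fit_model(occu_spec(), study$dataset)
  s1 <- subpopulation_summary(fit, study$dataset)$overall
  perm <- sample(60)
  ds2 <- study_dataset(study$dataset$detections, study$dataset$sites[perm, ],
                       study$dataset$seasons, study$dataset$visits,
                       n_seasons = 5, n_visits = 4)
  fit2 <- fit_model(occu_spec(), ds2)
  s2 <- subpopulation_summary(fit2, ds2)$overall
  expect_equal(dplyr::arrange(s1, subpopulation),
               dplyr::arrange(s2, subpopulation), tolerance = 1e-6)
})

test_that("sitewise turnover mode averages site-level turnover instead of plugging in averages", {
  y <- array(0, dim = c(2, 3, 1))
  rates <- rates_const(2, 3, 1, 0.5, 0.2, 0.3, 0.5)
  rates$gamma[2, ] <- 0.8
  sm <- rbind(c(0.2, 0.5, 0.5), c(0.9, 0.5, 0.5))
  plug <- summ(y, rates, sm, c("A", "A"))$by_season$turnover[2]
  site <- summ(y, rates, sm, c("A", "A"), mode = "sitewise")$by_season$turnover[2]
  tau_i <- turnover_probability(c(0.2, 0.8), c(0.2, 0.9), 0.7)
  expect_equal(site, mean(tau_i), tolerance = 1e-12)
  expect_equal(plug, turnover_probability(0.5, 0.55, 0.7), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(plug, site)))
})

test_that("bootstrap intervals are reproducible from the seed and bracket the estimate", {
  study <- generate_study(sim_config(n_sites = 70, seed = 23))
  fit <- fit_model(occu_spec(), study$dataset)
  b1 <- bootstrap_summaries(fit, study$dataset, n_sim = 8, seed = 5)
  b2 <- bootstrap_summaries(fit, study$dataset, n_sim = 8, seed = 5)
  expect_identical(b1$overall_ci, b2$overall_ci)
  expect_identical(b1$by_season_ci, b2$by_season_ci)
  ok <- !is.na(b1$overall_ci$lower)
  expect_true(all(b1$overall_ci$lower[ok] <= b1$overall_ci$upper[ok]))
})

test_that("bootstrap interval widths shrink as the number of sites grows", {
  width_at <- function(n_sites, seed) {
    cfg <- sim_config(n_sites = n_sites, seed = seed, spec = occu_spec(),
                      beta = list(psi1 = 0, gamma = qlogis(0.3),
                                  epsilon = qlogis(0.25), p = 0.5),
                      revisit_probs = c(0, 0, 0, 0, 1),
                      subpopulations = c(Basin = 1))
    st <- generate_study(cfg)
    fit <- fit_model(occu_spec(), st$dataset, hessian = FALSE)
    b <- bootstrap_summaries(fit, st$dataset, n_sim = 30, seed = seed)
    ci <- b$overall_ci[b$overall_ci$statistic == "turnover", ]
    ci$upper - ci$lower
  }
  expect_lt(width_at(320, 51), width_at(50, 51))
})

test_that("debt classification follows the tier and sign rules", {
  tb <- tibble::tibble(
    subpopulation = c("urban-a", "urban-b", "rural-a", "rural-b", "mid"),
    turnover = c(0.74, 0.57, 0.11, 0.10, 0.35),
    non_equilibrium = c(-0.03, 0.04, 0.07, -0.25, -0.15)
  )
  out <- classify_debt(tb)
  expect_equal(out$risk_label, c(
    "debt being realized",
    "debt accruing, not yet realized",
    "near stable",
    "below equilibrium, low turnover",
    "elevated turnover, below equilibrium"
  ))
  # thresholds are configuration
  out2 <- classify_debt(tb, thresholds = list(turnover = c(0.05, 0.09),
                                              non_equilibrium = 0.1))
  expect_equal(out2$risk_label[3], "debt accruing, not yet realized")
})
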