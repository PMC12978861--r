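#' Configuration of a synthetic multi-season occupancy study
#'
#' Defines the generating process of a synthetic study with the same
#' statistical structure the analysis assumes: a stratified set of sites
#' allocated to management subpopulations, site covariates (habitat
#' quality score, effective land-cover proportions, flow flashiness,
#' drainage area), a basin-wide annual drought path, visit-level
#' log-discharge following an AR(1) within each site-season, a heavily
#' unbalanced revisit design, and true logit-scale coefficient blocks for
#' initial occupancy, colonization, extinction and detection.
#'
#' Defaults emulate the monitoring design of a five-winter,
#' 176-site stream survey with four consecutive daily trap checks per
#' surveyed season and most sites surveyed in only one or two seasons
#' (revisit mass 0.38/0.36/0.20/0.05/0.01 on 1..5 seasons). Default
#' coefficients mirror the sign and ordering structure typical of
#' urbanization-driven extinction risk — extinction decreasing with
#' habitat quality, increasing with developed land cover and with drought
#' severity; detection increasing with log discharge — at magnitudes that
#' keep annual rates away from the boundary.
#'
#' @param n_sites,n_seasons,n_visits Study dimensions.
#' @param subpopulations Named integer vector allocating sites to
#'   subpopulations (scaled proportionally if it does not sum to
#'   `n_sites`).
#' @param beta List of numeric coefficient blocks `psi1`, `gamma`,
#'   `epsilon`, `p` on the logit scale, in design-matrix column order
#'   (intercept first; extinction: intercept, habitat, developed LULC,
#'   drought dummies for the levels the drought path realizes).
#' @param spec The true model structure, an [occu_spec()].
#' @param drought_path Integer vector (length `n_seasons`) of basin-wide
#'   drought indices in `{0,1,2,3}`, or `"random"` to draw one per season
#'   (weights 0.4/0.3/0.2/0.1), or `"site"` to draw site-specific indices.
#' @param revisit_probs Probability mass on 1..`n_seasons` surveyed
#'   seasons per site.
#' @param covariates List of distribution settings; see Details in the
#'   package vignette. Partial lists are merged over the defaults.
#' @param seed Integer seed stored in the config; every simulation
#'   operation derives its random stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 176, n_seasons = 5, n_visits = 4,
                       subpopulations = NULL, beta = NULL, spec = NULL,
                       drought_path = c(0, 1, 0, 2, 3),
                       revisit_probs = c(0.38, 0.36, 0.20, 0.05, 0.01),
                       covariates = list(), seed = 1) {
  if (is.null(subpopulations)) {
    subpopulations <- c(
      "Upper Neuse" = 9, "Middle Neuse" = 16, "Lower Neuse" = 7,
      "Flat/Eno" = 17, "Swift/Middle" = 15, "Little River" = 18,
      "Contentnea" = 19, "Trent" = 8, "Upper Tar" = 13, "Middle Tar" = 15,
      "Lower Tar" = 19, "Sandy/Swift" = 7, "Fishing" = 13
    )
  }
  alloc <- round(subpopulations / sum(subpopulations) * n_sites)
  while (sum(alloc) != n_sites) {
    i <- if (sum(alloc) > n_sites) which.max(alloc) else which.min(alloc)
    alloc[i] <- alloc[i] + sign(n_sites - sum(alloc))
  }
  if (any(alloc < 1)) abort("subpopulation allocation must give every unit >= 1 site")

  spec <- spec %||% occu_spec(
    psi1 = "habitat_score",
    gamma = "lulc_developed",
    epsilon = c("habitat_score", "lulc_developed", "drought_index"),
    p = "discharge_m3s",
    transforms = c(discharge_m3s = "log"),
    name = "top"
  )
  beta <- beta %||% list(
    psi1 = c(-0.14, 0.18),
    gamma = c(-1.50, 0.50),
    epsilon = c(-2.20, -1.29, 0.92, 1.30, 2.00, 2.60),
    p = c(-0.10, 0.45)
  )
  cov_defaults <- list(
    habitat = list(mean = 70.45, sd = 12.32, lower = 0, upper = 100),
    lulc_developed = list(shape1 = 1.5, shape2 = 7),
    lulc_herbpasture = list(shape1 = 2, shape2 = 8),
    lulc_crop = list(shape1 = 2, shape2 = 10),
    lulc_wetland = list(shape1 = 1.5, shape2 = 10),
    tqmean = list(shape1 = 8, shape2 = 12),
    discharge = list(mu_mean = 1.0, mu_sd = 0.9, season_sd = 0.3,
                     ar_rho = 0.6, ar_sd = 0.35),
    drainage = list(meanlog = log(500), sdlog = 0.8)
  )
  covariates <- modifyList(cov_defaults, covariates)
  for (nm in names(covariates)) {
    pars <- unlist(covariates[[nm]])
    if (any(!is.finite(pars)) ||
        (all(c("shape1", "shape2") %in% names(pars)) &&
           any(pars[c("shape1", "shape2")] <= 0)) ||
        ("sd" %in% names(pars) && pars[["sd"]] <= 0)) {
      abort(paste0("degenerate distribution parameters for covariate '", nm, "'"))
    }
  }
  if (length(revisit_probs) != n_seasons || abs(sum(revisit_probs) - 1) > 1e-8) {
    abort("revisit_probs must be a probability mass on 1..n_seasons")
  }
  if (is.numeric(drought_path)) {
    stopifnot(length(drought_path) == n_seasons, all(drought_path %in% 0:3))
  } else {
    drought_path <- match.arg(drought_path, c("random", "site"))
  }
  structure(
    list(n_sites = n_sites, n_seasons = n_seasons, n_visits = n_visits,
         subpopulations = alloc, beta = beta, spec = spec,
         drought_path = drought_path, revisit_probs = revisit_probs,
         covariates = covariates, seed = seed),
    class = "sim_config"
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

rtruncnorm_q <- function(n, mean, sd, lower, upper) {
  # inverse-CDF truncated normal: exact bounds, deterministic under seed
  u <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate the covariate tables and revisit design of a study
#'
#' Draws site covariates, the per-season drought index, visit-level
#' discharge/bait-age covariates for the full site-by-season-by-visit
#' grid (discharge is generated even for unsurveyed site-seasons, as it
#' would be interpolated in a real study), and the unbalanced revisit
#' design. Reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with tibbles `sites`, `seasons`, `visits`, the logical
#'   `surveyed` matrix, and `site_ids`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_sites; T <- config$n_seasons; J <- config$n_visits
  cv <- config$covariates
  site_ids <- sprintf("S%03d", seq_len(n))
  subpop <- rep(names(config$subpopulations), config$subpopulations)
  huc10 <- sprintf("03020%03d0",
                   100 + match(subpop, names(config$subpopulations)))

  habitat <- rtruncnorm_q(n, cv$habitat$mean, cv$habitat$sd,
                          cv$habitat$lower, cv$habitat$upper)
  lulc <- purrr::map(
    c("lulc_developed", "lulc_herbpasture", "lulc_crop", "lulc_wetland"),
    ~ rbeta(n, cv[[.x]]$shape1, cv[[.x]]$shape2)
  )
  names(lulc) <- c("lulc_developed", "lulc_herbpasture", "lulc_crop",
                   "lulc_wetland")
  tot <- Reduce(`+`, lulc)
  over <- tot > 0.95
  if (any(over)) {
    lulc <- purrr::map(lulc, ~ ifelse(over, .x * 0.95 / tot, .x))
  }

  sites <- tibble::tibble(
    site = site_ids, subpopulation = subpop, huc10 = huc10,
    drainage_area_km2 = rlnorm(n, cv$drainage$meanlog, cv$drainage$sdlog),
    habitat_score = habitat,
    substrate_score = clamp(habitat * 0.15 + rnorm(n, 0, 1.5), 0, 15),
    cover_score = clamp(habitat * 0.20 + rnorm(n, 0, 2.0), 0, 20),
    lulc_developed = lulc$lulc_developed,
    lulc_herbpasture = lulc$lulc_herbpasture,
    lulc_crop = lulc$lulc_crop,
    lulc_wetland = lulc$lulc_wetland,
    tqmean = rbeta(n, cv$tqmean$shape1, cv$tqmean$shape2)
  )

  if (is.numeric(config$drought_path)) {
    drought <- matrix(rep(config$drought_path, each = n), n, T)
  } else if (identical(config$drought_path, "random")) {
    path <- sample(0:3, T, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    drought <- matrix(rep(path, each = n), n, T)
  } else {
    drought <- matrix(sample(0:3, n * T, replace = TRUE,
                             prob = c(0.4, 0.3, 0.2, 0.1)), n, T)
  }
  seasons <- tibble::tibble(
    site = rep(site_ids, T),
    season = rep(seq_len(T), each = n),
    drought_index = as.vector(drought)
  )

  dcv <- cv$discharge
  mu_site <- rnorm(n, dcv$mu_mean, dcv$mu_sd)
  shift <- matrix(rnorm(n * T, 0, dcv$season_sd), n, T)
  logq <- array(0, dim = c(n, T, J))
  sd0 <- dcv$ar_sd / sqrt(1 - dcv$ar_rho^2)
  for (t in seq_len(T)) {
    x <- rnorm(n, 0, sd0)
    logq[, t, 1] <- x
    for (j in seq_len(J)[-1]) {
      x <- dcv$ar_rho * x + rnorm(n, 0, dcv$ar_sd)
      logq[, t, j] <- x
    }
  }
  logq <- logq + array(rep(mu_site, T * J), dim = c(n, T, J)) +
    array(rep(as.vector(shift), J), dim = c(n, T, J))
  visits <- tibble::tibble(
    site = rep(site_ids, T * J),
    season = rep(rep(seq_len(T), each = n), J),
    visit = rep(seq_len(J), each = n * T),
    discharge_m3s = exp(as.vector(logq)),
    bait_age_days = rep(seq_len(J), each = n * T)
  )

  n_surv <- sample(seq_len(T), n, replace = TRUE, prob = config$revisit_probs)
  surveyed <- matrix(FALSE, n, T)
  for (i in seq_len(n)) {
    surveyed[i, sample.int(T, n_surv[i])] <- TRUE
  }

  list(sites = sites, seasons = seasons, visits = visits,
       surveyed = surveyed, site_ids = site_ids)
}

# skeleton dataset: observed-visit pattern in place, detections all zero
skeleton_dataset <- function(config, covariates) {
  n <- config$n_sites; T <- config$n_seasons; J <- config$n_visits
  grid <- tidyr::expand_grid(site = covariates$site_ids,
                             season = seq_len(T), visit = seq_len(J))
  surv <- covariates$surveyed[cbind(match(grid$site, covariates$site_ids),
                                    grid$season)]
  grid$y <- ifelse(surv, 0, NA_real_)
  study_dataset(grid, covariates$sites, covariates$seasons, covariates$visits,
                n_seasons = T, n_visits = J)
}

true_rates <- function(config, covariates) {
  skel <- skeleton_dataset(config, covariates)
  design <- build_design(config$spec, skel)
  beta <- unlist(config$beta, use.names = FALSE)
  if (length(beta) != design$n_par) {
    abort(paste0(
      "true coefficient blocks (", length(beta), " values) do not match the ",
      "design implied by the spec and drought path (", design$n_par,
      " columns: ",
      paste(unlist(lapply(list(design$X_psi1, design$X_gamma,
                               design$X_epsilon, design$X_p), colnames)),
            collapse = ", "), ")"
    ))
  }
  list(design = design, skeleton = skel,
       rates = compute_rates(design, beta), beta = beta)
}

#' Simulate the latent occupancy states of a study
#'
#' Draws the site-by-season latent occupancy matrix `Z` under the
#' first-order Markov dynamics implied by the config's true coefficients
#' and the simulated covariates: `Z[i,1] ~ Bernoulli(psi1[i])` and
#' `Z[i,t+1] ~ Bernoulli(Z[i,t] * phi[i,t] + (1 - Z[i,t]) * gamma[i,t])`.
#'
#' @param config A [sim_config()].
#' @param covariates Result of [simulate_covariates()].
#' @return Integer `site x season` matrix `Z` with the generating
#'   `rate_surfaces` and design attached as attributes `"rates"` and
#'   `"design"`.
#' @export
simulate_latent <- function(config, covariates) {
  tr <- true_rates(config, covariates)
  set.seed(config$seed + 1L)
  n <- config$n_sites; T <- config$n_seasons
  Z <- matrix(0L, n, T, dimnames = list(covariates$site_ids, NULL))
  Z[, 1] <- rbinom(n, 1, tr$rates$psi1)
  for (t in seq_len(T)[-1]) {
    pr <- Z[, t - 1] * (1 - tr$rates$epsilon[, t - 1]) +
      (1 - Z[, t - 1]) * tr$rates$gamma[, t - 1]
    Z[, t] <- rbinom(n, 1, pr)
  }
  attr(Z, "rates") <- tr$rates
  attr(Z, "design") <- tr$design
  attr(Z, "skeleton") <- tr$skeleton
  Z
}

#' Simulate detection histories given the latent states
#'
#' Draws `y[i,t,j] ~ Bernoulli(Z[i,t] * p[i,t,j])` at every surveyed
#' visit; unsurveyed site-seasons stay fully missing per the drawn revisit
#' design. The model admits no false positives: unoccupied site-seasons
#' yield all-zero records.
#'
#' @param Z Latent matrix from [simulate_latent()].
#' @param config A [sim_config()].
#' @param covariates Result of [simulate_covariates()].
#' @return A validated [study_dataset()].
#' @export
simulate_detections <- function(Z, config, covariates) {
  rates <- attr(Z, "rates") %||% true_rates(config, covariates)$rates
  set.seed(config$seed + 2L)
  n <- config$n_sites; T <- config$n_seasons; J <- config$n_visits
  surv <- covariates$surveyed
  yv <- rep(NA_real_, n * T * J)
  obs <- which(rep(as.vector(surv), J))
  site_season <- (obs - 1) %% (n * T) + 1
  z_obs <- as.vector(Z)[site_season]
  p_obs <- rates$p[obs]
  yv[obs] <- rbinom(length(obs), 1, z_obs * p_obs)
  grid <- tidyr::expand_grid(site = covariates$site_ids,
                             season = seq_len(T), visit = seq_len(J))
  # expand_grid orders site-major; yv is in array order (site fastest)
  flat <- match(grid$site, covariates$site_ids) + n * (grid$season - 1) +
    n * T * (grid$visit - 1)
  grid$y <- yv[flat]
  study_dataset(grid, covariates$sites, covariates$seasons, covariates$visits,
                n_seasons = T, n_visits = J)
}

#' Generate a complete synthetic study with ground truth
#'
#' Composes [simulate_covariates()], [simulate_latent()] and
#' [simulate_detections()] into a validated dataset plus a
#' `simulation_truth` record of the generating parameters, latent states
#' and realized rate surfaces, for parameter-recovery and coverage
#' testing.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a [study_dataset()]) and `truth` (class
#'   `simulation_truth`: `config`, `beta` — the named true coefficient
#'   vector in design order — `Z`, `rates`, and the design `scalings`).
#' @export
generate_study <- function(config = sim_config()) {
  covariates <- simulate_covariates(config)
  Z <- simulate_latent(config, covariates)
  dataset <- simulate_detections(Z, config, covariates)
  design <- attr(Z, "design")
  beta <- setNames(
    unlist(config$beta, use.names = FALSE),
    c(paste0("psi1.", colnames(design$X_psi1)),
      paste0("gamma.", colnames(design$X_gamma)),
      paste0("epsilon.", colnames(design$X_epsilon)),
      paste0("p.", colnames(design$X_p)))
  )
  truth <- structure(
    list(config = config, beta = beta, Z = unclass(Z),
         rates = attr(Z, "rates"), scalings = design$scalings),
    class = "simulation_truth"
  )
  truth$Z <- matrix(as.integer(Z), nrow(Z), ncol(Z),
                    dimnames = dimnames(Z))
  list(dataset = dataset, truth = truth)
}
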