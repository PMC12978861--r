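# small in-code fixtures

make_sites <- function(n, subpop = rep("A", n), habitat = rep(70, n)) {
  tibble::tibble(
    site = sprintf("S%03d", seq_len(n)),
    subpopulation = subpop,
    huc10 = "0302010101",
    drainage_area_km2 = 500,
    habitat_score = habitat,
    substrate_score = 10, cover_score = 12,
    lulc_developed = seq(0.05, 0.4, length.out = n),
    lulc_herbpasture = 0.2, lulc_crop = 0.1, lulc_wetland = 0.05,
    tqmean = 0.35
  )
}

# dataset from a detection array (n x T x J); NA = missing visit
toy_study <- function(y, subpop = NULL, habitat = NULL,
                      discharge = NULL, drought = NULL) {
  n <- dim(y)[1]; T <- dim(y)[2]; J <- dim(y)[3]
  sites <- make_sites(n, subpop %||% rep("A", n),
                      habitat %||% seq(40, 90, length.out = n))
  grid <- tidyr::expand_grid(site = sites$site, season = seq_len(T),
                             visit = seq_len(J))
  flat <- match(grid$site, sites$site) + n * (grid$season - 1) +
    n * T * (grid$visit - 1)
  grid$y <- as.vector(y)[flat]
  seasons <- tidyr::expand_grid(site = sites$site, season = seq_len(T))
  seasons$drought_index <- if (is.null(drought)) {
    rep(c(0, 1, 2, 3), length.out = T)[seasons$season]
  } else {
    drought[seasons$season]
  }
  visits <- grid[, c("site", "season", "visit")]
  visits$discharge_m3s <- discharge %||% (1 + (flat %% 7)) / 2
  visits$bait_age_days <- visits$visit
  study_dataset(grid, sites, seasons, visits, n_seasons = T, n_visits = J)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal design-shaped list good enough for the internal summary/GOF
# machinery (no model matrices, just the data bookkeeping)
design_lite <- function(y) {
  n <- dim(y)[1]; T <- dim(y)[2]
  yv <- as.vector(y)
  obs_idx <- which(!is.na(yv))
  surveyed <- apply(!is.na(y), c(1, 2), any)
  hasdet <- apply(y == 1, c(1, 2), any)
  hasdet[is.na(hasdet)] <- FALSE
  list(
    n_sites = n, n_seasons = T, n_visits = dim(y)[3],
    site_ids = sprintf("S%03d", seq_len(n)),
    obs_idx = obs_idx, obs_y = yv[obs_idx],
    obs_site_season = (obs_idx - 1) %% (n * T) + 1,
    surveyed = surveyed, hasdet = hasdet
  )
}

rates_const <- function(n, T, J, psi1, gamma, epsilon, p) {
  list(psi1 = rep(psi1, n),
       gamma = matrix(gamma, n, T - 1),
       epsilon = matrix(epsilon, n, T - 1),
       phi = matrix(1 - epsilon, n, T - 1),
       p = array(p, dim = c(n, T, J)),
       site_ids = sprintf("S%03d", seq_len(n)))
}
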