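#' One step of the occupancy recursion
#'
#' The unconditional occupancy probability propagates between seasons as
#' `psi' = psi * (1 - epsilon) + (1 - psi) * gamma`: occupied sites persist
#' with probability `phi = 1 - epsilon` and unoccupied sites are colonized
#' with probability `gamma`. Inputs recycle elementwise.
#'
#' @param psi,gamma,epsilon Probabilities in `[0, 1]`.
#' @return Occupancy probability for the next season, in `[0, 1]`.
#' @export
occupancy_recursion <- function(psi, gamma, epsilon) {
  check_prob(psi, "psi"); check_prob(gamma, "gamma"); check_prob(epsilon, "epsilon")
  psi * (1 - epsilon) + (1 - psi) * gamma
}

check_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(paste0("'", name, "' must lie in [0, 1]"),
          class = "occdebt_domain_error")
  }
  invisible(x)
}

#' Turnover probability
#'
#' The probability that a site occupied in season `t` was unoccupied in
#' season `t - 1`:
#' `tau = gamma * (1 - psi) / (gamma * (1 - psi) + phi * psi)`,
#' the conditional probability `Pr(Z[t-1] = 0 | Z[t] = 1)` under the
#' two-state chain, with `gamma`, `psi`, `phi` taken at season `t - 1`.
#' High turnover means occupancy is being continually re-assembled by
#' colonization rather than maintained by persistence — a warning sign for
#' long-lived, low-dispersal species.
#'
#' @param gamma_prev,psi_prev,phi_prev Colonization, occupancy and
#'   persistence probabilities at the earlier season (recycled elementwise).
#' @return Turnover probability in `[0, 1]`.
#' @export
turnover_probability <- function(gamma_prev, psi_prev, phi_prev) {
  check_prob(gamma_prev, "gamma_prev")
  check_prob(psi_prev, "psi_prev")
  check_prob(phi_prev, "phi_prev")
  num <- gamma_prev * (1 - psi_prev)
  den <- num + phi_prev * psi_prev
  if (any(den <= 0)) {
    abort("turnover undefined: Pr(occupied at t) is zero",
          class = "occdebt_domain_error")
  }
  num / den
}

#' Equilibrium occupancy
#'
#' The occupancy level at which colonization gains balance extinction
#' losses, `psi_eq = gamma / (gamma + epsilon)` — the unique fixed point of
#' [occupancy_recursion()] for constant rates. Occupancy below this level
#' grows towards it; occupancy above it declines towards it.
#'
#' @param gamma,epsilon Colonization and extinction probabilities
#'   (recycled elementwise); `gamma + epsilon` must be positive.
#' @return Equilibrium occupancy in `[0, 1]`.
#' @export
equilibrium_occupancy <- function(gamma, epsilon) {
  check_prob(gamma, "gamma"); check_prob(epsilon, "epsilon")
  if (any(gamma + epsilon <= 0)) {
    abort("equilibrium undefined: gamma + epsilon must be > 0",
          class = "occdebt_domain_error")
  }
  gamma / (gamma + epsilon)
}

# forward-backward smoothing over the latent chain given season emissions;
# returns n x T matrix of Pr(Z[i,t] = 1 | full detection record, rates)
smooth_core <- function(psi1, gamma, epsilon, e1, e0) {
  n <- length(psi1); T <- ncol(e1)
  fw <- forward_pass(psi1, gamma, epsilon, e1, e0, keep = TRUE)
  B0 <- B1 <- matrix(1, n, T)
  if (T >= 2) {
    for (t in (T - 1):1) {
      m1 <- e1[, t + 1] * B1[, t + 1]
      m0 <- e0[, t + 1] * B0[, t + 1]
      g <- gamma[, t]; e <- epsilon[, t]
      b1 <- (1 - e) * m1 + e * m0
      b0 <- g * m1 + (1 - g) * m0
      norm <- pmax(b0 + b1, .Machine$double.xmin)
      B1[, t] <- b1 / norm; B0[, t] <- b0 / norm
    }
  }
  num <- fw$A1 * B1
  den <- num + fw$A0 * B0
  num / pmax(den, .Machine$double.xmin)
}

smooth_matrix <- function(design, rates) {
  lp_obs <- qlogis(rates$p[design$obs_idx])
  e1 <- exp(log_emission_occ(design, lp_obs))
  e0 <- 1 - design$hasdet
  out <- smooth_core(rates$psi1, rates$gamma, rates$epsilon, e1, e0)
  rownames(out) <- design$site_ids
  out
}

# season emissions straight from a p array and detection array (NA = missing)
rates_emissions <- function(p, y) {
  contrib <- y * log(p) + (1 - y) * log(1 - p)
  contrib[is.na(y)] <- 0
  le1 <- apply(contrib, c(1, 2), sum)
  hasdet <- apply(y == 1, c(1, 2), any)
  hasdet[is.na(hasdet)] <- FALSE
  list(e1 = exp(le1), e0 = 1 - hasdet)
}

# likelihood and smoothing driven directly by rate surfaces: the same
# forward(-backward) code paths as the fitted-model interface, entered from
# explicit probability arrays (used heavily in verification)
nll_from_rates <- function(psi1, gamma, epsilon, p, y) {
  em <- rates_emissions(p, y)
  -sum(forward_pass(psi1, gamma, epsilon, em$e1, em$e0)$loglik)
}

smoothed_from_rates <- function(psi1, gamma, epsilon, p, y) {
  em <- rates_emissions(p, y)
  smooth_core(psi1, gamma, epsilon, em$e1, em$e0)
}

#' Finite-sample ("smoothed") occupancy trajectories
#'
#' The probability that each site was occupied in each season, conditional
#' on the site's full detection record and the fitted parameters —
#' computed by forward-backward recursion over the latent chain. Wherever
#' the species was detected the estimate equals exactly 1; where a site
#' was surveyed without detections it lies in `(0, 1]`; at unsurveyed
#' site-seasons it interpolates from the neighbouring seasons.
#'
#' @param fit An `occu_fit`.
#' @param dataset Optional new [study_dataset()] (default: training data).
#' @return A tibble of class `smoothed_occupancy`: `site`, `season`,
#'   `psi_fs`, `surveyed`, `detected`. The underlying `site x season`
#'   matrix is attached as attribute `"matrix"`.
#' @export
smoothed_occupancy <- function(fit, dataset = NULL) {
  stopifnot(inherits(fit, "occu_fit"))
  design <- if (is.null(dataset)) fit$design else
    build_design(fit$spec, dataset, scalings = fit$design$scalings)
  rates <- compute_rates(design, unname(fit$par))
  m <- smooth_matrix(design, rates)
  out <- tibble::tibble(
    site = rep(design$site_ids, design$n_seasons),
    season = rep(seq_len(design$n_seasons), each = design$n_sites),
    psi_fs = as.vector(m),
    surveyed = as.vector(design$surveyed),
    detected = as.vector(design$hasdet)
  )
  attr(out, "matrix") <- m
  class(out) <- c("smoothed_occupancy", class(out))
  out
}
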