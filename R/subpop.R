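# simulate a detection array on a fitted design (same missingness pattern)
# and return a design clone carrying the simulated data
simulate_y_on_design <- function(design, rates) {
  n <- design$n_sites; T <- design$n_seasons
  Z <- matrix(0L, n, T)
  Z[, 1] <- rbinom(n, 1, rates$psi1)
  if (T >= 2) {
    for (t in 2:T) {
      pr <- Z[, t - 1] * (1 - rates$epsilon[, t - 1]) +
        (1 - Z[, t - 1]) * rates$gamma[, t - 1]
      Z[, t] <- rbinom(n, 1, pr)
    }
  }
  p_obs <- rates$p[design$obs_idx]
  z_obs <- Z[cbind((design$obs_site_season - 1) %% n + 1,
                   (design$obs_site_season - 1) %/% n + 1)]
  y_obs <- rbinom(length(p_obs), 1, z_obs * p_obs)

  yv <- rep(NA_real_, n * T * design$n_visits)
  yv[design$obs_idx] <- y_obs
  hasdet <- matrix(FALSE, n, T)
  det_ss <- unique(design$obs_site_season[y_obs == 1])
  hasdet[cbind((det_ss - 1) %% n + 1, (det_ss - 1) %/% n + 1)] <- TRUE

  d2 <- design
  d2$obs_y <- y_obs
  d2$hasdet <- hasdet
  list(design = d2, Z = Z, y = array(yv, dim = c(n, T, design$n_visits)))
}

# core subpopulation summary machinery shared by the user-facing function
# and the bootstrap loop
summarize_subpops <- function(design, rates, sm, subpop, site_scope, turnover_mode) {
  n <- design$n_sites; T <- design$n_seasons
  surveyed <- design$surveyed
  groups <- split(seq_len(n), subpop)

  by_season <- purrr::imap(groups, function(ix, nm) {
    scope_t <- function(t) {
      if (site_scope == "all") ix else ix[surveyed[ix, t]]
    }
    psi_bar <- vapply(1:T, function(t) {
      s <- scope_t(t); if (length(s)) mean(sm[s, t]) else NA_real_
    }, numeric(1))
    g_bar <- e_bar <- rep(NA_real_, T)
    for (t in seq_len(T - 1)) {
      s <- scope_t(t)
      if (length(s)) {
        g_bar[t] <- mean(rates$gamma[s, t])
        e_bar[t] <- mean(rates$epsilon[s, t])
      }
    }
    tau <- eqv <- rep(NA_real_, T)
    for (t in seq_len(T - 1)) {
      if (!is.na(g_bar[t]) && !is.na(e_bar[t]) && g_bar[t] + e_bar[t] > 0) {
        eqv[t] <- g_bar[t] / (g_bar[t] + e_bar[t])
      }
    }
    for (t in 2:min(T - 1, T)) {
      if (T < 3 || t > T - 1) next # final season dynamics not reported
      prev <- t - 1
      if (turnover_mode == "plugin") {
        if (!is.na(g_bar[prev]) && !is.na(psi_bar[prev]) && !is.na(e_bar[prev])) {
          den <- g_bar[prev] * (1 - psi_bar[prev]) +
            (1 - e_bar[prev]) * psi_bar[prev]
          if (den > 0) tau[t] <- g_bar[prev] * (1 - psi_bar[prev]) / den
        }
      } else {
        s <- scope_t(prev)
        if (length(s)) {
          den <- rates$gamma[s, prev] * (1 - sm[s, prev]) +
            (1 - rates$epsilon[s, prev]) * sm[s, prev]
          ok <- den > 0
          if (any(ok)) {
            tau[t] <- mean(rates$gamma[s, prev][ok] * (1 - sm[s, prev][ok]) /
                             den[ok])
          }
        }
      }
    }
    tibble::tibble(
      subpopulation = nm, season = 1:T,
      n_sites_in_scope = vapply(1:T, function(t) length(scope_t(t)), integer(1)),
      psi_fs = psi_bar, gamma = g_bar, epsilon = e_bar,
      turnover = tau, equilibrium = eqv
    )
  }) |> dplyr::bind_rows()

  mn <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  lo <- function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  hi <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  overall <- by_season |>
    dplyr::group_by(.data$subpopulation) |>
    dplyr::summarise(
      occupancy = mn(.data$psi_fs),
      occupancy_min = lo(.data$psi_fs), occupancy_max = hi(.data$psi_fs),
      colonization = mn(.data$gamma),
      extinction = mn(.data$epsilon),
      extinction_min = lo(.data$epsilon), extinction_max = hi(.data$epsilon),
      turnover = mn(.data$turnover),
      turnover_min = lo(.data$turnover), turnover_max = hi(.data$turnover),
      equilibrium = mn(.data$equilibrium),
      equilibrium_min = lo(.data$equilibrium),
      equilibrium_max = hi(.data$equilibrium),
      .groups = "drop"
    ) |>
    dplyr::mutate(non_equilibrium = .data$occupancy - .data$equilibrium) |>
    dplyr::left_join(
      tibble::tibble(subpopulation = names(groups),
                     n_sites = lengths(groups)),
      by = "subpopulation"
    ) |>
    dplyr::relocate("n_sites", .after = "subpopulation")
  list(overall = overall, by_season = by_season)
}

#' Subpopulation summaries of occurrence dynamics
#'
#' Summarizes the fitted occurrence dynamics per management subpopulation
#' and season: mean finite-sample (smoothed) occupancy, mean colonization
#' and extinction probabilities, the turnover probability obtained by
#' plugging the subpopulation averages of the previous season into the
#' turnover expression, the equilibrium occupancy `gamma / (gamma +
#' epsilon)` of the averaged rates, and the non-equilibrium index (mean
#' finite-sample occupancy minus mean equilibrium occupancy). Dynamics
#' (turnover, equilibrium) are not reported for the final season, where
#' they are not identified.
#'
#' @param fit An `occu_fit`.
#' @param dataset The [study_dataset()] carrying the subpopulation labels
#'   (default: the data the model was fitted to must be supplied here).
#' @param smoothed Optional precomputed [smoothed_occupancy()] result.
#' @param site_scope `"surveyed"` (default): season-`t` averages run over
#'   the subpopulation's sites surveyed in season `t`; `"all"` uses every
#'   site of the subpopulation.
#' @param turnover_mode `"plugin"` (default): subpopulation averages are
#'   plugged into the turnover expression; `"sitewise"`: site-level
#'   turnover values are averaged instead. The two differ because turnover
#'   is a nonlinear function of the rates.
#' @return A list of class `subpop_summary` with `overall` (one tibble row
#'   per subpopulation, the layout of a subpopulation report table) and
#'   `by_season` (seasonal detail).
#' @export
subpopulation_summary <- function(fit, dataset, smoothed = NULL,
                                  site_scope = c("surveyed", "all"),
                                  turnover_mode = c("plugin", "sitewise")) {
  stopifnot(inherits(fit, "occu_fit"), inherits(dataset, "study_dataset"))
  site_scope <- match.arg(site_scope)
  turnover_mode <- match.arg(turnover_mode)
  design <- fit$design
  subpop <- as.character(
    dataset$sites$subpopulation[match(design$site_ids,
                                      as.character(dataset$sites$site))]
  )
  rates <- compute_rates(design, unname(fit$par))
  sm <- if (!is.null(smoothed)) attr(smoothed, "matrix") else
    smooth_matrix(design, rates)
  out <- summarize_subpops(design, rates, sm, subpop, site_scope, turnover_mode)
  out$site_scope <- site_scope
  out$turnover_mode <- turnover_mode
  class(out) <- "subpop_summary"
  out
}

#' @export
print.subpop_summary <- function(x, ...) {
  cat("<subpop_summary> (site_scope = ", x$site_scope,
      ", turnover = ", x$turnover_mode, ")\n", sep = "")
  print(x$overall, n = Inf)
  invisible(x)
}

#' @rdname subpopulation_summary
#' @param x A `subpop_summary`.
#' @param ... Unused.
#' @export
tidy.subpop_summary <- function(x, ...) x$overall

#' Parametric-bootstrap confidence intervals for subpopulation summaries
#'
#' Repeatedly simulates detection data from the fitted model on the
#' observed design (identical sites, seasons and missingness pattern),
#' refits the same model spec, and recomputes the subpopulation summaries.
#' Percentile 2.5/97.5 intervals are reported for the mean turnover and
#' mean equilibrium occupancy, per subpopulation (and per season).
#' Replicates whose refit does not converge are dropped and counted; more
#' than 20% failures aborts with a diagnostic.
#'
#' @inheritParams subpopulation_summary
#' @param n_sim Number of bootstrap replicates (>= 2; 500 in a full
#'   analysis, far fewer for quick checks).
#' @param seed Integer seed; results are fully reproducible from it.
#' @param conf_level Interval coverage (default 0.95).
#' @param max_fail_frac Abort threshold for the failed-replicate fraction.
#' @return A list of class `subpop_boot`: `overall_ci` (tibble:
#'   `subpopulation`, `statistic`, `estimate`, `lower`, `upper`),
#'   `by_season_ci`, `n_sim`, `n_failed`, `seed`.
#' @export
bootstrap_summaries <- function(fit, dataset, n_sim = 500, seed = 1,
                                site_scope = c("surveyed", "all"),
                                turnover_mode = c("plugin", "sitewise"),
                                conf_level = 0.95, max_fail_frac = 0.2) {
  stopifnot(inherits(fit, "occu_fit"), n_sim >= 2)
  site_scope <- match.arg(site_scope)
  turnover_mode <- match.arg(turnover_mode)
  base <- subpopulation_summary(fit, dataset, site_scope = site_scope,
                                turnover_mode = turnover_mode)
  design <- fit$design
  subpop <- as.character(
    dataset$sites$subpopulation[match(design$site_ids,
                                      as.character(dataset$sites$site))]
  )
  rates <- compute_rates(design, unname(fit$par))
  set.seed(seed)
  reps <- vector("list", n_sim)
  n_failed <- 0L
  for (r in seq_len(n_sim)) {
    simd <- simulate_y_on_design(design, rates)$design
    refit <- tryCatch(
      fit_model(fit$spec, design = simd, start = unname(fit$par),
                hessian = FALSE),
      error = function(e) NULL
    )
    if (is.null(refit) || !refit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    rr <- compute_rates(simd, unname(refit$par))
    sm <- smooth_matrix(simd, rr)
    reps[[r]] <- summarize_subpops(simd, rr, sm, subpop, site_scope,
                                   turnover_mode)
  }
  if (n_failed / n_sim > max_fail_frac) {
    abort(paste0("bootstrap aborted: ", n_failed, "/", n_sim,
                 " replicates failed to converge"),
          class = "occdebt_bootstrap_error")
  }
  reps <- purrr::compact(reps)
  a <- (1 - conf_level) / 2
  qr <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    quantile(v, c(a, 1 - a), names = FALSE, type = 7)
  }

  ov <- purrr::map_dfr(reps, ~ .x$overall)
  overall_ci <- ov |>
    tidyr::pivot_longer(cols = c("turnover", "equilibrium"),
                        names_to = "statistic", values_to = "value") |>
    dplyr::group_by(.data$subpopulation, .data$statistic) |>
    dplyr::summarise(lower = qr(.data$value)[1], upper = qr(.data$value)[2],
                     n_ok = sum(is.finite(.data$value)), .groups = "drop") |>
    dplyr::left_join(
      base$overall |>
        tidyr::pivot_longer(cols = c("turnover", "equilibrium"),
                            names_to = "statistic", values_to = "estimate") |>
        dplyr::select("subpopulation", "statistic", "estimate"),
      by = c("subpopulation", "statistic")
    ) |>
    dplyr::relocate("estimate", .before = "lower")

  bs <- purrr::map_dfr(reps, ~ .x$by_season)
  by_season_ci <- bs |>
    tidyr::pivot_longer(cols = c("turnover", "equilibrium"),
                        names_to = "statistic", values_to = "value") |>
    dplyr::group_by(.data$subpopulation, .data$season, .data$statistic) |>
    dplyr::summarise(lower = qr(.data$value)[1], upper = qr(.data$value)[2],
                     .groups = "drop")

  structure(
    list(overall_ci = overall_ci, by_season_ci = by_season_ci,
         estimate = base, n_sim = n_sim, n_failed = n_failed, seed = seed,
         conf_level = conf_level),
    class = "subpop_boot"
  )
}

#' @export
print.subpop_boot <- function(x, ...) {
  cat("<subpop_boot> ", x$n_sim, " replicates (", x$n_failed,
      " failed), seed ", x$seed, "\n", sep = "")
  print(x$overall_ci, n = Inf)
  invisible(x)
}

#' Classify extinction-debt risk per subpopulation
#'
#' Applies an interpretable rule to the subpopulation summaries: the mean
#' turnover probability is binned into low / moderate / high tiers, and
#' combined with the sign (and, in the low tier, the magnitude) of the
#' non-equilibrium index. High turnover with occupancy below equilibrium
#' indicates a debt already being realized; high turnover with occupancy
#' at or above equilibrium indicates a debt accruing but not yet realized;
#' low turnover with a near-zero index indicates approximate stability.
#' The continuous values are always carried alongside the label.
#'
#' @param summary A `subpop_summary` (or its `overall` tibble).
#' @param thresholds List with `turnover = c(low_cut, high_cut)` (defaults
#'   0.25 and 0.50) and `non_equilibrium` (the half-width of the
#'   "near-equilibrium" band in the low-turnover tier, default 0.10).
#' @return A tibble of class `debt_assessment`: `subpopulation`,
#'   `turnover`, `non_equilibrium`, `turnover_tier`, `risk_label`, `rule`.
#' @export
classify_debt <- function(summary,
                          thresholds = list(turnover = c(0.25, 0.50),
                                            non_equilibrium = 0.10)) {
  overall <- if (inherits(summary, "subpop_summary")) summary$overall else
    tibble::as_tibble(summary)
  cuts <- thresholds$turnover %||% c(0.25, 0.50)
  band <- thresholds$non_equilibrium %||% 0.10
  row_label <- function(tau, ne) {
    if (is.na(tau) || is.na(ne)) {
      return(c(tier = NA_character_, label = NA_character_, rule = "insufficient data"))
    }
    tier <- if (tau >= cuts[2]) "high" else if (tau >= cuts[1]) "moderate" else "low"
    label <- if (tier == "high") {
      if (ne < 0) "debt being realized" else "debt accruing, not yet realized"
    } else if (tier == "moderate") {
      if (ne < 0) "elevated turnover, below equilibrium"
      else "elevated turnover, above equilibrium"
    } else {
      if (abs(ne) <= band) "near stable"
      else if (ne < 0) "below equilibrium, low turnover"
      else "above equilibrium, stable"
    }
    rule <- sprintf(
      "turnover %.3f in %s tier (cuts %.2f/%.2f); non-equilibrium %+.3f (band %.2f)",
      tau, tier, cuts[1], cuts[2], ne, band
    )
    c(tier = tier, label = label, rule = rule)
  }
  lab <- purrr::map2(overall$turnover, overall$non_equilibrium, row_label)
  out <- tibble::tibble(
    subpopulation = overall$subpopulation,
    turnover = overall$turnover,
    non_equilibrium = overall$non_equilibrium,
    turnover_tier = purrr::map_chr(lab, "tier"),
    risk_label = purrr::map_chr(lab, "label"),
    rule = purrr::map_chr(lab, "rule")
  )
  class(out) <- c("debt_assessment", class(out))
  out
}
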