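# unconditional occupancy trajectory per site (recursion from psi1)
marginal_trajectory <- function(rates, T) {
  n <- length(rates$psi1)
  traj <- matrix(0, n, T)
  traj[, 1] <- rates$psi1
  if (T >= 2) {
    for (t in 2:T) {
      traj[, t] <- traj[, t - 1] * (1 - rates$epsilon[, t - 1]) +
        (1 - traj[, t - 1]) * rates$gamma[, t - 1]
    }
  }
  traj
}

# season-cohort Pearson chi-square given a design with data, rate surfaces
# and a site x season occupancy-probability matrix
chisq_from <- function(design, rates, occ, pool_threshold = 2, quiet = FALSE) {
  n <- design$n_sites; T <- design$n_seasons; J <- design$n_visits
  yv <- rep(NA_real_, n * T * J)
  yv[design$obs_idx] <- design$obs_y
  y <- array(yv, dim = c(n, T, J))
  total <- 0
  for (t in seq_len(T)) {
    idx <- which(design$surveyed[, t])
    if (!length(idx)) next
    yt <- matrix(y[, t, ], n, J)[idx, , drop = FALSE]
    pt <- matrix(rates$p[, t, ], n, J)[idx, , drop = FALSE]
    hist_str <- apply(yt, 1, function(r) {
      paste(ifelse(is.na(r), ".", r), collapse = "")
    })
    if (length(unique(hist_str)) < 2) {
      if (!quiet) {
        warn(paste0("season ", t,
                    ": fewer than 2 distinct histories; contributes 0"))
      }
      next
    }
    pattern <- apply(yt, 1, function(r) paste(as.integer(!is.na(r)), collapse = ""))
    obs_cells <- list(); exp_cells <- list()
    for (m in unique(pattern)) {
      rows <- which(pattern == m)
      obs_j <- which(strsplit(m, "")[[1]] == "1")
      k <- length(obs_j)
      combos <- as.matrix(expand.grid(rep(list(0:1), k)))
      psi_i <- occ[idx[rows], t]
      p_i <- pt[rows, obs_j, drop = FALSE]
      # expected count for each possible detection string within this cohort
      e_vec <- vapply(seq_len(nrow(combos)), function(ci) {
        h <- combos[ci, ]
        pr_given_occ <- exp(
          rowSums(log(t(t(p_i)^h)) + log(t(t(1 - p_i)^(1 - h))))
        )
        sum(psi_i * pr_given_occ + (1 - psi_i) * as.numeric(all(h == 0)))
      }, numeric(1))
      key <- vapply(seq_len(nrow(combos)), function(ci) {
        s <- strsplit(m, "")[[1]]
        s[obs_j] <- as.character(combos[ci, ])
        s[s == "0" & !(seq_along(s) %in% obs_j)] <- "."
        paste(ifelse(seq_along(s) %in% obs_j, s, "."), collapse = "")
      }, character(1))
      o_vec <- vapply(key, function(kk) sum(hist_str[rows] == kk), numeric(1))
      obs_cells[[m]] <- o_vec
      exp_cells[[m]] <- e_vec
    }
    o_all <- unlist(obs_cells); e_all <- unlist(exp_cells)
    keep <- e_all >= pool_threshold
    chi <- sum((o_all[keep] - e_all[keep])^2 / e_all[keep])
    if (any(!keep)) {
      o_r <- sum(o_all[!keep]); e_r <- sum(e_all[!keep])
      if (e_r > 0) chi <- chi + (o_r - e_r)^2 / e_r
    }
    total <- total + chi
  }
  total
}

#' Season-cohort chi-square fit statistic
#'
#' Groups the detection histories of each season (among sites surveyed
#' that season) into cohorts sharing the same missing-visit pattern, and
#' within each cohort compares the observed counts of each possible
#' detection string with the counts expected under the fitted model, by a
#' Pearson chi-square summed over seasons. Cells with expected count below
#' `pool_threshold` are pooled into one season-level remainder cell. The
#' statistic has no reference distribution of its own and is calibrated by
#' [parametric_bootstrap_gof()].
#'
#' @param fit An `occu_fit`.
#' @param dataset Optional dataset (default: training data).
#' @param pool_threshold Minimum expected count for an unpooled cell.
#' @param occupancy Occupancy probability used for the expected counts:
#'   `"smoothed"` (finite-sample, conditional on the site's record;
#'   default) or `"marginal"` (the unconditional trajectory).
#' @return The scalar chi-square statistic.
#' @export
cohort_chisq <- function(fit, dataset = NULL, pool_threshold = 2,
                         occupancy = c("smoothed", "marginal")) {
  stopifnot(inherits(fit, "occu_fit"))
  occupancy <- match.arg(occupancy)
  design <- if (is.null(dataset)) fit$design else
    build_design(fit$spec, dataset, scalings = fit$design$scalings)
  rates <- compute_rates(design, unname(fit$par))
  occ <- if (occupancy == "smoothed") smooth_matrix(design, rates) else
    marginal_trajectory(rates, design$n_seasons)
  chisq_from(design, rates, occ, pool_threshold)
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' Simulates detection data from the fitted model on the observed design,
#' refits, and recomputes the season-cohort chi-square per replicate. The
#' p-value is the fraction of bootstrap statistics at or above the
#' observed one; the overdispersion factor `c-hat` is the observed
#' statistic divided by the bootstrap mean. `c-hat` near 1 and a
#' non-extreme p-value indicate no evidence of overdispersion.
#'
#' @inheritParams cohort_chisq
#' @param n_sim Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; the result is reproducible from it.
#' @param max_fail_frac Abort threshold for the failed-replicate fraction.
#' @return A list of class `occu_gof`: `statistic`, `p_value`, `c_hat`,
#'   `boot_stats`, `n_sim`, `n_failed`, `seed`.
#' @export
parametric_bootstrap_gof <- function(fit, dataset = NULL, n_sim = 100, seed = 1,
                                     pool_threshold = 2,
                                     occupancy = c("smoothed", "marginal"),
                                     max_fail_frac = 0.2) {
  stopifnot(inherits(fit, "occu_fit"), n_sim >= 2)
  occupancy <- match.arg(occupancy)
  design <- if (is.null(dataset)) fit$design else
    build_design(fit$spec, dataset, scalings = fit$design$scalings)
  rates <- compute_rates(design, unname(fit$par))
  occ_of <- function(d, r) {
    if (occupancy == "smoothed") smooth_matrix(d, r) else
      marginal_trajectory(r, d$n_seasons)
  }
  observed <- chisq_from(design, rates, occ_of(design, rates), pool_threshold)

  set.seed(seed)
  boot <- rep(NA_real_, n_sim)
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
    boot[r] <- chisq_from(simd, rr, occ_of(simd, rr), pool_threshold,
                          quiet = TRUE)
  }
  if (n_failed / n_sim > max_fail_frac) {
    abort(paste0("GOF bootstrap aborted: ", n_failed, "/", n_sim,
                 " replicates failed to converge"),
          class = "occdebt_bootstrap_error")
  }
  boot <- boot[is.finite(boot)]
  structure(
    list(
      statistic = observed,
      p_value = mean(boot >= observed),
      c_hat = observed / mean(boot),
      boot_stats = boot, n_sim = n_sim, n_failed = n_failed, seed = seed
    ),
    class = "occu_gof"
  )
}

#' @export
print.occu_gof <- function(x, ...) {
  cat("<occu_gof> parametric bootstrap, ", length(x$boot_stats),
      " usable replicates (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  chi-square = %.3f, p = %.3f, c-hat = %.3f\n",
              x$statistic, x$p_value, x$c_hat))
  invisible(x)
}

#' @rdname glance.occu_fit
#' @export
glance.occu_gof <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 c_hat = x$c_hat, n_sim = as.integer(x$n_sim),
                 n_failed = as.integer(x$n_failed), seed = x$seed)
}
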