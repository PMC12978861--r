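# Forward-pass likelihood for the multi-season occupancy model.
#
# Each site contributes the marginal probability of its detection record
# under a two-state latent Markov chain: initial state (1-psi1, psi1),
# transitions P(1->1) = phi = 1 - epsilon, P(0->1) = gamma, and a
# within-season emission that is Prod_j p^y (1-p)^(1-y) given occupancy and
# the indicator of an all-zero record given absence. Missing visits
# contribute a factor of 1. The pass is normalized each season so the
# computation stays in a numerically safe range at any T.

# season-wise log-emissions given occupancy, from detection-prob linear
# predictors at the observed visits
log_emission_occ <- function(design, lp_obs) {
  contrib <- design$obs_y * plogis(lp_obs, log.p = TRUE) +
    (1 - design$obs_y) * plogis(-lp_obs, log.p = TRUE)
  le1 <- numeric(design$n_sites * design$n_seasons)
  agg <- rowsum(contrib, design$obs_site_season)
  le1[as.integer(rownames(agg))] <- agg
  matrix(le1, design$n_sites, design$n_seasons)
}

forward_pass <- function(psi1, gamma, epsilon, e1, e0, keep = FALSE) {
  n <- length(psi1); T <- ncol(e1)
  a1 <- psi1 * e1[, 1]
  a0 <- (1 - psi1) * e0[, 1]
  norm <- pmax(a0 + a1, .Machine$double.xmin)
  ll <- log(norm)
  a0 <- a0 / norm; a1 <- a1 / norm
  A0 <- A1 <- NULL
  if (keep) {
    A0 <- A1 <- matrix(0, n, T)
    A0[, 1] <- a0; A1[, 1] <- a1
  }
  if (T >= 2) {
    for (t in 2:T) {
      g <- gamma[, t - 1]; e <- epsilon[, t - 1]
      na1 <- (a1 * (1 - e) + a0 * g) * e1[, t]
      na0 <- (a1 * e + a0 * (1 - g)) * e0[, t]
      norm <- pmax(na0 + na1, .Machine$double.xmin)
      ll <- ll + log(norm)
      a0 <- na0 / norm; a1 <- na1 / norm
      if (keep) { A0[, t] <- a0; A1[, t] <- a1 }
    }
  }
  list(loglik = ll, A0 = A0, A1 = A1)
}

# fast closure over a design; returns function(par) -> NLL
make_nll <- function(design) {
  X_p_obs <- design$X_p[design$obs_idx, , drop = FALSE]
  e0 <- 1 - design$hasdet
  force(design)
  function(par) {
    b <- split_par(par, design)
    lp1 <- drop(design$X_psi1 %*% b$psi1)
    lpg <- drop(design$X_gamma %*% b$gamma)
    lpe <- drop(design$X_epsilon %*% b$epsilon)
    lpp <- drop(X_p_obs %*% b$p)
    if (!all(is.finite(lp1)) || !all(is.finite(lpg)) ||
        !all(is.finite(lpe)) || !all(is.finite(lpp))) {
      abort("non-finite linear predictor in likelihood evaluation")
    }
    n <- design$n_sites; T <- design$n_seasons
    psi1 <- plogis(lp1)
    gamma <- matrix(plogis(lpg), n, max(T - 1, 0))
    epsilon <- matrix(plogis(lpe), n, max(T - 1, 0))
    e1 <- exp(log_emission_occ(design, lpp))
    -sum(forward_pass(psi1, gamma, epsilon, e1, e0)$loglik)
  }
}

#' Negative log-likelihood of the multi-season occupancy model
#'
#' Computes the exact marginal negative log-likelihood of the observed
#' detection histories by a forward pass over the latent two-state
#' occupancy chain (never by enumerating latent sequences), in log space
#' with per-season normalization.
#'
#' @param par Coefficient vector on the logit scale, ordered by the
#'   design's block map (psi1, gamma, epsilon, p).
#' @param design An [build_design()] result (carries the observed data).
#' @return The scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(par, design) {
  stopifnot(inherits(design, "occu_design"), length(par) == design$n_par)
  make_nll(design)(par)
}

#' Fit a dynamic occupancy model by maximum likelihood
#'
#' Minimizes the forward-pass negative log-likelihood by quasi-Newton
#' (BFGS) iteration from a deterministic all-zero start, optionally with
#' additional seeded random starts. Standard errors come from the inverse
#' of the numerically differentiated Hessian at the optimum; a singular or
#' non-positive-definite Hessian leaves them `NA` and is flagged.
#'
#' @param spec An [occu_spec()].
#' @param dataset A [study_dataset()] with at least two seasons.
#' @param start Optional start vector (default all zeros).
#' @param multi_start Number of additional random starts (coefficients
#'   drawn `N(0, 0.5)`); the best optimum is kept.
#' @param seed Seed for the random starts.
#' @param maxit,reltol Passed to [stats::optim()] (BFGS).
#' @param grad_tol Convergence check: the fit is flagged converged when the
#'   optimizer reports success and the max absolute component of the
#'   numeric gradient at the optimum is below this value.
#' @param hessian Compute the Hessian/SEs (disable inside bootstrap loops).
#' @param design Optional pre-built design (must match `spec`); used to
#'   avoid rebuilding inside simulation loops.
#' @return An object of class `occu_fit` with elements `par`, `se`, `vcov`,
#'   `nll`, `K`, `n_sites`, `aicc`, `converged`, `se_available`,
#'   `max_abs_gradient`, `spec`, `design`, `optim` (counts/convergence),
#'   and `term_table` (tibble of parameter group / term / estimate / SE).
#' @seealso [aicc()], [rank_models()], [predict_rates()], [tidy.occu_fit()]
#' @export
fit_model <- function(spec, dataset = NULL, start = NULL, multi_start = 0,
                      seed = NULL, maxit = 500, reltol = 1e-10,
                      grad_tol = 1e-2, hessian = TRUE, design = NULL) {
  design <- design %||% build_design(spec, dataset)
  if (design$n_seasons < 2) {
    abort("dynamics estimation requires at least 2 seasons")
  }
  nll_fn <- make_nll(design)
  K <- design$n_par
  starts <- list(start %||% rep(0, K))
  if (multi_start > 0) {
    if (!is.null(seed)) set.seed(seed)
    starts <- c(starts, replicate(multi_start, rnorm(K, 0, 0.5),
                                  simplify = FALSE))
  }
  runs <- lapply(starts, function(s) {
    tryCatch(
      optim(s, nll_fn, method = "BFGS",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
  })
  runs <- purrr::compact(runs)
  if (!length(runs)) abort("all optimizer starts failed", class = "occdebt_fit_error")
  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]

  grad <- tryCatch(pracma::grad(nll_fn, best$par), error = function(e) rep(NA_real_, K))
  max_grad <- max(abs(grad))
  converged <- isTRUE(best$convergence == 0) && is.finite(best$value) &&
    is.finite(max_grad) && max_grad < grad_tol

  se <- rep(NA_real_, K)
  vc <- NULL
  se_available <- FALSE
  if (hessian) {
    H <- tryCatch(pracma::hessian(nll_fn, best$par), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
        se <- sqrt(diag(vc))
        se_available <- TRUE
      }
    }
  }

  term_names <- c(
    paste0("psi1.", colnames(design$X_psi1)),
    paste0("gamma.", colnames(design$X_gamma)),
    paste0("epsilon.", colnames(design$X_epsilon)),
    paste0("p.", colnames(design$X_p))
  )
  groups <- rep(names(design$block_map), lengths(design$block_map))
  term_table <- tibble::tibble(
    group = groups,
    term = sub("^[^.]+\\.", "", term_names),
    estimate = best$par,
    std_error = se
  )

  fit <- structure(
    list(
      spec = design$spec, design = design, par = setNames(best$par, term_names),
      se = setNames(se, term_names), vcov = vc, nll = best$value, K = K,
      n_sites = design$n_sites, converged = converged,
      se_available = se_available, max_abs_gradient = max_grad,
      optim = best[c("convergence", "counts", "message")],
      term_table = term_table
    ),
    class = "occu_fit"
  )
  fit$aicc <- aicc(fit)
  fit
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = 2*NLL + 2K + 2K(K+1)/(n - K - 1)`. The effective sample size
#' defaults to the number of sites, the independent units of the
#' likelihood; this convention is configurable.
#'
#' @param fit An `occu_fit`.
#' @param n_effective Effective sample size (default: number of sites).
#' @return The scalar AICc.
#' @export
aicc <- function(fit, n_effective = NULL) {
  stopifnot(inherits(fit, "occu_fit"))
  n <- n_effective %||% fit$n_sites
  aicc_value(fit$nll, fit$K, n)
}

aicc_value <- function(nll, K, n) {
  if (n <= K + 1) {
    abort(paste0("AICc undefined: effective sample size (", n,
                 ") must exceed K + 1 (", K + 1, ")"))
  }
  2 * nll + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank candidate models by AICc
#'
#' Sorts converged fits by AICc (ties broken by fewer parameters, then
#' model name), computes the AICc difference to the best model, and flags
#' models within the equal-support band.
#'
#' @param fits List of `occu_fit` objects (named, or named via their specs).
#' @param delta_threshold Models with `delta_aicc` at or below this value
#'   are flagged `supported` (default 2.0).
#' @return A tibble: `model`, `K`, `nll`, `aicc`, `delta_aicc`, `supported`.
#'   Non-converged fits are dropped with a warning.
#' @export
rank_models <- function(fits, delta_threshold = 2.0) {
  if (inherits(fits, "occu_fit")) fits <- list(fits)
  nms <- names(fits) %||% purrr::map_chr(fits, ~ .x$spec$name)
  nms[!nzchar(nms)] <- purrr::map_chr(fits[!nzchar(nms)], ~ .x$spec$name)
  conv <- purrr::map_lgl(fits, "converged")
  if (any(!conv)) {
    warn(paste0("excluding non-converged fit(s): ",
                paste(nms[!conv], collapse = ", ")))
  }
  if (!any(conv)) abort("no converged fits to rank", class = "occdebt_fit_error")
  tb <- tibble::tibble(
    model = unname(nms[conv]),
    K = unname(purrr::map_int(fits[conv], ~ as.integer(.x$K))),
    nll = unname(purrr::map_dbl(fits[conv], "nll")),
    aicc = unname(purrr::map_dbl(fits[conv], "aicc"))
  ) |>
    dplyr::arrange(.data$aicc, .data$K, .data$model) |>
    dplyr::mutate(
      delta_aicc = .data$aicc - .data$aicc[1],
      supported = .data$delta_aicc <= delta_threshold
    )
  tb
}

#' Predict probability surfaces from a fitted model
#'
#' Applies the logistic inverse link to the fitted linear predictors,
#' returning initial occupancy, colonization, extinction, persistence and
#' detection probabilities on the probability scale. With a new dataset the
#' stored training scalings are reused and covariate values outside the
#' training range trigger an extrapolation warning.
#'
#' @param fit An `occu_fit`.
#' @param dataset Optional new [study_dataset()]; default: the training data.
#' @return A `rate_surfaces` object (see [compute_rates()]).
#' @export
predict_rates <- function(fit, dataset = NULL) {
  stopifnot(inherits(fit, "occu_fit"))
  design <- fit$design
  if (!is.null(dataset)) {
    new_design <- build_design(fit$spec, dataset, scalings = design$scalings)
    for (blk in c("X_psi1", "X_gamma", "X_epsilon", "X_p")) {
      tr <- suppressWarnings(apply(design[[blk]], 2, range, na.rm = TRUE))
      nw <- new_design[[blk]]
      for (cn in colnames(nw)) {
        if (!cn %in% colnames(design[[blk]])) next
        v <- nw[, cn]
        if (any(v < tr[1, cn] - 1e-12 | v > tr[2, cn] + 1e-12, na.rm = TRUE)) {
          warn(paste0("extrapolation: covariate column '", cn, "' in ", blk,
                      " outside the training range"))
        }
      }
    }
    design <- new_design
  }
  compute_rates(design, unname(fit$par))
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("<occu_fit> ", x$spec$name, "\n", sep = "")
  cat("  K = ", x$K, ", sites = ", x$n_sites,
      ", NLL = ", round(x$nll, 3), ", AICc = ", round(x$aicc, 3), "\n", sep = "")
  cat("  converged: ", x$converged,
      " (max |grad| = ", signif(x$max_abs_gradient, 3), ")\n", sep = "")
  if (!x$se_available) cat("  note: standard errors unavailable (singular Hessian)\n")
  print(tidy(x), n = Inf)
  invisible(x)
}
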