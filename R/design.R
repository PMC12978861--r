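#' Specify a candidate dynamic occupancy model
#'
#' A model spec names the covariates entering each of the four parameter
#' groups of the multi-season occupancy model — initial occupancy `psi1`,
#' colonization `gamma`, extinction `epsilon` and detection `p` — together
#' with per-covariate transformation tags. All four groups use the logit
#' link; every group always contains an intercept.
#'
#' @param psi1,gamma,epsilon,p Character vectors of covariate names
#'   (columns of the study's site / season / visit tables). Empty vector =
#'   intercept only. Interaction terms `"a:b"` are allowed for `psi1` only
#'   (products of the transformed columns); they are rejected for the other
#'   groups, where interaction-rich structures are typically
#'   non-identifiable at realistic sample sizes.
#' @param transforms Named character vector of tags:
#'   `"zscore"` (center/scale; the default for continuous covariates),
#'   `"log"` (natural log, then center/scale), `"identity"` (use as is), or
#'   `"categorical"` (baseline-coded dummies; the default for
#'   `drought_index`, with level 0 as baseline).
#' @param drought_timing For transition parameters (`gamma`, `epsilon`) the
#'   drought index attached to the transition from season `t` to `t+1`:
#'   `"next"` (default) uses season `t+1`'s index — the drought experienced
#'   over the interval the transition spans — `"current"` uses season `t`'s.
#' @param name Label used in ranking tables.
#' @return An object of class `occu_spec`.
#' @seealso [build_design()], [fit_model()]
#' @export
occu_spec <- function(psi1 = character(), gamma = character(),
                      epsilon = character(), p = character(),
                      transforms = character(), drought_timing = c("next", "current"),
                      name = "model") {
  drought_timing <- match.arg(drought_timing)
  transforms <- unlist(transforms)
  if (length(transforms) && is.null(names(transforms))) {
    abort("`transforms` must be a named vector (covariate -> tag)")
  }
  ok_tags <- c("identity", "log", "zscore", "categorical")
  bad <- setdiff(transforms, ok_tags)
  if (length(bad)) abort(paste0("unknown transform tag(s): ", paste(bad, collapse = ", ")))
  for (grp in c("gamma", "epsilon", "p")) {
    terms <- get(grp)
    if (any(grepl(":", terms, fixed = TRUE))) {
      abort(paste0("interaction terms are only supported for psi1 (found in ",
                   grp, ")"))
    }
  }
  structure(
    list(psi1 = psi1, gamma = gamma, epsilon = epsilon, p = p,
         transforms = transforms, drought_timing = drought_timing, name = name),
    class = "occu_spec"
  )
}

#' @export
print.occu_spec <- function(x, ...) {
  f <- function(v) if (length(v)) paste(v, collapse = " + ") else "1"
  cat("<occu_spec> ", x$name, "\n",
      "  psi1:    ~ ", f(x$psi1), "\n",
      "  gamma:   ~ ", f(x$gamma), "\n",
      "  epsilon: ~ ", f(x$epsilon), "\n",
      "  p:       ~ ", f(x$p), "\n", sep = "")
  invisible(x)
}

#' Read a named candidate set of model specs from YAML or JSON
#'
#' The file holds a mapping of model name to a spec with optional keys
#' `psi1`, `gamma`, `epsilon`, `p` (covariate lists), `transforms`
#' (mapping covariate -> tag) and `drought_timing`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return Named list of [occu_spec()] objects.
#' @export
read_model_specs <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  purrr::imap(raw, function(s, nm) {
    occu_spec(
      psi1 = as.character(s$psi1 %||% character()),
      gamma = as.character(s$gamma %||% character()),
      epsilon = as.character(s$epsilon %||% character()),
      p = as.character(s$p %||% character()),
      transforms = unlist(s$transforms %||% character()),
      drought_timing = s$drought_timing %||% "next",
      name = nm
    )
  })
}

# level at which a covariate lives: "site", "season", or "visit"
covariate_level <- function(name, dataset) {
  base <- strsplit(name, ":", fixed = TRUE)[[1]]
  lv <- vapply(base, function(b) {
    if (b %in% names(dataset$sites) && b != "site") "site"
    else if (b %in% c("drought_index")) "season"
    else if (b %in% c("discharge_m3s", "bait_age_days")) "visit"
    else abort(paste0("unknown covariate: '", b, "'"),
               class = "occdebt_validation_error")
  }, character(1))
  if (length(unique(lv)) > 1) {
    abort(paste0("interaction '", name, "' mixes covariate levels"),
          class = "occdebt_validation_error")
  }
  lv[1]
}

transform_tag <- function(name, spec) {
  if (name %in% names(spec$transforms)) return(spec$transforms[[name]])
  if (name == "drought_index") return("categorical")
  "zscore"
}

#' Build design matrices for a model spec on a study
#'
#' Expands a spec into the four design matrices of the likelihood:
#' `X_psi1` (one row per site), `X_gamma` / `X_epsilon` (one row per site
#' and transition, transition-major), and `X_p` (one row per site, season
#' and visit, in array order). Continuous covariates are centered and
#' scaled by the population standard deviation (after log transformation
#' where tagged) using the rows that
#' enter the likelihood; those scalings are stored so fitted coefficients
#' can be back-transformed and new data scored consistently. The drought
#' index expands to baseline-coded dummies with level 0 as baseline.
#'
#' @param spec An [occu_spec()].
#' @param dataset A [study_dataset()].
#' @param scalings Optional scalings from a previous design (to score new
#'   data on the training scale). Default: computed from `dataset`.
#' @return An object of class `occu_design` carrying the matrices, column
#'   names, a parameter block map, stored scalings, and the pieces of the
#'   observed data needed by the likelihood.
#' @export
build_design <- function(spec, dataset, scalings = NULL) {
  stopifnot(inherits(spec, "occu_spec"), inherits(dataset, "study_dataset"))
  n <- dataset$n_sites
  T <- dataset$n_seasons
  J <- dataset$n_visits
  site_order <- match(dataset$site_ids, as.character(dataset$sites$site))

  # season-level covariate values as n x T matrix
  drought_mat <- {
    m <- matrix(NA_real_, n, T)
    s <- dataset$seasons
    m[cbind(match(as.character(s$site), dataset$site_ids), s$season)] <-
      s$drought_index
    m
  }
  # visit-level covariates as flat vectors in array order (i, t, j)
  visit_flat <- function(col) {
    v <- rep(NA_real_, n * T * J)
    vt <- dataset$visits
    flat <- match(as.character(vt$site), dataset$site_ids) +
      n * (vt$season - 1) + n * T * (vt$visit - 1)
    v[flat] <- vt[[col]]
    v
  }

  yv <- as.vector(dataset$y)
  obs_idx <- which(!is.na(yv))

  # raw (untransformed) values of a base covariate on the rows of a block
  raw_values <- function(base, block) {
    lv <- covariate_level(base, dataset)
    if (lv == "site") {
      v <- dataset$sites[[base]][site_order]
      switch(block,
             psi1 = v,
             trans = rep(v, T - 1),
             p = rep(v, T * J))
    } else if (lv == "season") {
      if (block == "psi1") {
        drought_mat[, 1]
      } else if (block == "trans") {
        tt <- if (spec$drought_timing == "next") 2:T else 1:(T - 1)
        as.vector(drought_mat[, tt, drop = FALSE])
      } else {
        as.vector(drought_mat[, rep(1:T, J), drop = FALSE])
      }
    } else { # visit level
      if (block != "p") {
        abort(paste0("visit-level covariate '", base,
                     "' can only enter detection (p)"),
              class = "occdebt_validation_error")
      }
      visit_flat(base)
    }
  }

  scl <- scalings %||% list()
  used_scalings <- list()

  locate_row <- function(r, block) {
    switch(block,
      psi1 = paste0("site ", dataset$site_ids[r]),
      trans = paste0("site ", dataset$site_ids[(r - 1) %% n + 1],
                     ", transition ", (r - 1) %/% n + 1),
      p = paste0("site ", dataset$site_ids[(r - 1) %% n + 1],
                 ", season ", ((r - 1) %/% n) %% T + 1,
                 ", visit ", (r - 1) %/% (n * T) + 1))
  }

  # build one block's matrix from its term list
  build_block <- function(terms, block, key, likelihood_rows) {
    nrow_block <- switch(block, psi1 = n, trans = n * (T - 1), p = n * T * J)
    cols <- list(`(Intercept)` = rep(1, nrow_block))
    col_of_base <- function(base) {
      tag <- transform_tag(base, spec)
      v <- raw_values(base, block)
      if (tag == "categorical") {
        vl <- v[likelihood_rows]
        if (anyNA(vl)) {
          r <- likelihood_rows[which(is.na(vl))[1]]
          abort(paste0("missing value of categorical covariate '", base,
                       "' in ", key, " design at ", locate_row(r, block)),
                class = "occdebt_validation_error")
        }
        levs <- sort(unique(vl))
        levs <- levs[-1] # first level is baseline
        out <- lapply(levs, function(l) as.numeric(v == l))
        names(out) <- paste0(base, levs)
        return(out)
      }
      if (tag == "log") {
        if (any(v[likelihood_rows] <= 0, na.rm = TRUE)) {
          abort(paste0("covariate '", base,
                       "' must be positive for log transform"),
                class = "occdebt_validation_error")
        }
        v <- log(v)
      }
      if (tag %in% c("log", "zscore")) {
        skey <- paste(key, base, sep = ".")
        st <- scl[[skey]]
        if (is.null(st)) {
          vv <- v[likelihood_rows]
          mu <- mean(vv, na.rm = TRUE)
          # population SD: scaling is a fixed data transform, not an estimate
          sg <- sqrt(mean((vv - mu)^2, na.rm = TRUE))
          if (!is.finite(sg) || sg == 0) {
            abort(paste0("covariate '", base, "' is constant on the rows of ",
                         key, "; cannot standardize"),
                  class = "occdebt_validation_error")
          }
          st <- c(center = mu, scale = sg)
        }
        used_scalings[[paste(key, base, sep = ".")]] <<- st
        v <- (v - st[["center"]]) / st[["scale"]]
      }
      setNames(list(v), base)
    }
    for (term in terms) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (length(parts) == 1) {
        cols <- c(cols, col_of_base(term))
      } else {
        vv <- lapply(parts, function(b) col_of_base(b)[[1]])
        cols[[term]] <- Reduce(`*`, vv)
      }
    }
    X <- do.call(cbind, cols)
    colnames(X) <- names(cols)
    # rows that enter the likelihood must be complete
    bad <- likelihood_rows[rowSums(is.na(X[likelihood_rows, , drop = FALSE])) > 0]
    if (length(bad)) {
      abort(paste0("missing covariate value in ", key, " design at ",
                   locate_row(bad[1], block)),
            class = "occdebt_validation_error")
    }
    X
  }

  X_psi1 <- build_block(spec$psi1, "psi1", "psi1", seq_len(n))
  if (T >= 2) {
    X_gamma <- build_block(spec$gamma, "trans", "gamma", seq_len(n * (T - 1)))
    X_epsilon <- build_block(spec$epsilon, "trans", "epsilon", seq_len(n * (T - 1)))
  } else {
    X_gamma <- matrix(numeric(0), 0, 1, dimnames = list(NULL, "(Intercept)"))
    X_epsilon <- X_gamma
  }
  X_p <- build_block(spec$p, "p", "p", obs_idx)

  k <- c(psi1 = ncol(X_psi1), gamma = ncol(X_gamma),
         epsilon = ncol(X_epsilon), p = ncol(X_p))
  ends <- cumsum(k)
  block_map <- purrr::map2(ends - k + 1, ends, seq)
  names(block_map) <- names(k)

  hasdet <- apply(dataset$y == 1, c(1, 2), any)
  hasdet[is.na(hasdet)] <- FALSE
  if (T == 1) hasdet <- matrix(hasdet, ncol = 1)

  structure(
    list(
      spec = spec, X_psi1 = X_psi1, X_gamma = X_gamma, X_epsilon = X_epsilon,
      X_p = X_p, block_map = block_map, n_par = sum(k),
      scalings = used_scalings,
      n_sites = n, n_seasons = T, n_visits = J,
      site_ids = dataset$site_ids,
      obs_idx = obs_idx, obs_y = yv[obs_idx],
      obs_site_season = (obs_idx - 1) %% (n * T) + 1, # flat (site, season) id
      hasdet = hasdet, surveyed = dataset$surveyed
    ),
    class = "occu_design"
  )
}

split_par <- function(par, design) {
  lapply(design$block_map, function(ix) par[ix])
}

#' Compute probability surfaces from coefficients
#'
#' Applies the logistic inverse link to the linear predictors of a design,
#' returning per-site initial occupancy, per-site-and-transition
#' colonization/extinction/persistence, and per-visit detection
#' probability. Detection probabilities are `NA` at visits whose covariates
#' were never observed.
#'
#' @param design An [build_design()] result.
#' @param par Numeric coefficient vector (length `design$n_par`).
#' @return List of class `rate_surfaces`: `psi1` (length n), `gamma`,
#'   `epsilon`, `phi` (n x T-1 matrices; `phi = 1 - epsilon` exactly), `p`
#'   (n x T x J array).
#' @export
compute_rates <- function(design, par) {
  stopifnot(length(par) == design$n_par)
  b <- split_par(par, design)
  n <- design$n_sites; T <- design$n_seasons; J <- design$n_visits
  lin <- function(X, beta) drop(X %*% beta)
  psi1 <- plogis(lin(design$X_psi1, b$psi1))
  if (T >= 2) {
    gamma <- matrix(plogis(lin(design$X_gamma, b$gamma)), n, T - 1)
    epsilon <- matrix(plogis(lin(design$X_epsilon, b$epsilon)), n, T - 1)
  } else {
    gamma <- matrix(numeric(0), n, 0)
    epsilon <- matrix(numeric(0), n, 0)
  }
  lp_p <- rep(NA_real_, n * T * J)
  ok <- rowSums(is.na(design$X_p)) == 0
  lp_p[ok] <- lin(design$X_p[ok, , drop = FALSE], b$p)
  structure(
    list(psi1 = psi1, gamma = gamma, epsilon = epsilon, phi = 1 - epsilon,
         p = array(plogis(lp_p), dim = c(n, T, J)),
         site_ids = design$site_ids),
    class = "rate_surfaces"
  )
}

#' @export
print.rate_surfaces <- function(x, ...) {
  cat("<rate_surfaces>\n")
  cat("  mean psi1:   ", round(mean(x$psi1), 3), "\n")
  if (length(x$gamma)) {
    cat("  mean gamma:  ", round(mean(x$gamma), 3), "\n")
    cat("  mean epsilon:", round(mean(x$epsilon), 3), "\n")
  }
  cat("  mean p:      ", round(mean(x$p, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' @rdname tidy.occu_fit
#' @export
tidy.rate_surfaces <- function(x, ...) {
  n <- length(x$psi1); Tm1 <- ncol(x$gamma)
  dplyr::bind_rows(
    tibble::tibble(parameter = "psi1", site = x$site_ids, season = 1L,
                   visit = NA_integer_, estimate = x$psi1),
    if (Tm1 > 0) tibble::tibble(
      parameter = rep(c("gamma", "epsilon"), each = n * Tm1),
      site = rep(rep(x$site_ids, Tm1), 2),
      season = rep(rep(seq_len(Tm1), each = n), 2),
      visit = NA_integer_,
      estimate = c(as.vector(x$gamma), as.vector(x$epsilon))
    ),
    {
      d <- dim(x$p)
      tibble::tibble(
        parameter = "p",
        site = rep(x$site_ids, d[2] * d[3]),
        season = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
        visit = rep(seq_len(d[3]), each = d[1] * d[2]),
        estimate = as.vector(x$p)
      )
    }
  )
}
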