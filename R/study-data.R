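#' Assemble and validate a multi-season detection/non-detection study
#'
#' Bundles the four tables of a multi-season occupancy study — long-format
#' detection histories, site covariates, site-by-season covariates and
#' visit covariates — into a single validated object. Visits never performed
#' are recorded as `NA` detections; a season with at least one non-missing
#' visit at a site counts as *surveyed* for that site.
#'
#' @param detections Data frame with columns `site`, `season`, `visit`, `y`
#'   (`y` in `{0, 1, NA}`). Rows may be omitted for unperformed visits; any
#'   site-season-visit combination absent from the table is treated as `NA`.
#' @param sites Data frame with one row per site: `site`, `subpopulation`,
#'   `huc10`, `drainage_area_km2`, `habitat_score` (0-100), `substrate_score`,
#'   `cover_score`, `lulc_developed`, `lulc_herbpasture`, `lulc_crop`,
#'   `lulc_wetland` (each in `[0, 1]`), `tqmean` (in `[0, 1]`).
#' @param seasons Data frame with columns `site`, `season`, `drought_index`
#'   (ordinal, in `{0, 1, 2, 3}`).
#' @param visits Data frame with columns `site`, `season`, `visit`,
#'   `discharge_m3s` (> 0 where present), `bait_age_days` (integer 1-4).
#' @param n_seasons,n_visits Study dimensions. Default: inferred as the
#'   maximum season/visit index appearing in `detections` or `visits`.
#'
#' @return An object of class `study_dataset`: a list carrying the four
#'   tables (as tibbles), the site identifier vector, the detection array
#'   `y` (`site x season x visit`) and the logical `surveyed` matrix
#'   (`site x season`).
#'
#' @details Every site must be surveyed in at least one season; dynamics
#'   (colonization/extinction) estimation additionally requires
#'   `n_seasons >= 2`, enforced at fit time rather than here. Validation
#'   failures raise classed errors (`occdebt_validation_error`) whose
#'   messages name the offending table, row and column.
#'
#' @seealso [read_study()], [write_study()], [summarize_design()]
#' @export
study_dataset <- function(detections, sites, seasons, visits,
                          n_seasons = NULL, n_visits = NULL) {
  detections <- tibble::as_tibble(detections)
  sites <- tibble::as_tibble(sites)
  seasons <- tibble::as_tibble(seasons)
  visits <- tibble::as_tibble(visits)

  need_cols(detections, c("site", "season", "visit", "y"), "detections")
  need_cols(sites, c(
    "site", "subpopulation", "huc10", "drainage_area_km2", "habitat_score",
    "substrate_score", "cover_score", "lulc_developed", "lulc_herbpasture",
    "lulc_crop", "lulc_wetland", "tqmean"
  ), "sites")
  need_cols(seasons, c("site", "season", "drought_index"), "seasons")
  need_cols(visits, c("site", "season", "visit", "discharge_m3s", "bait_age_days"),
            "visits")

  site_ids <- as.character(sites$site)
  if (anyDuplicated(site_ids)) {
    validation_error("sites: duplicated site id(s): ",
                     paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  }

  n_seasons <- n_seasons %||% max(detections$season, visits$season, seasons$season, 1)
  n_visits <- n_visits %||% max(detections$visit, visits$visit, 1)
  n_sites <- length(site_ids)

  check_ids(detections$site, site_ids, "detections")
  check_ids(seasons$site, site_ids, "seasons")
  check_ids(visits$site, site_ids, "visits")

  bad_y <- which(!(is.na(detections$y) | detections$y %in% c(0, 1)))
  if (length(bad_y)) {
    validation_error(
      "detections: non-binary value in column 'y' at row ", bad_y[1],
      " (site ", detections$site[bad_y[1]], ", season ",
      detections$season[bad_y[1]], ", visit ", detections$visit[bad_y[1]],
      "): ", detections$y[bad_y[1]]
    )
  }
  check_index(detections$season, n_seasons, "detections", "season")
  check_index(detections$visit, n_visits, "detections", "visit")
  check_index(seasons$season, n_seasons, "seasons", "season")
  check_index(visits$season, n_seasons, "visits", "season")
  check_index(visits$visit, n_visits, "visits", "visit")

  check_range(sites, "habitat_score", 0, 100)
  for (cl in c("lulc_developed", "lulc_herbpasture", "lulc_crop",
               "lulc_wetland", "tqmean")) {
    check_range(sites, cl, 0, 1)
  }
  if (any(is.na(sites$subpopulation) | !nzchar(as.character(sites$subpopulation)))) {
    validation_error("sites: empty subpopulation label at row ",
                     which(is.na(sites$subpopulation) |
                             !nzchar(as.character(sites$subpopulation)))[1])
  }
  bad_d <- which(!is.na(seasons$drought_index) &
                   !(seasons$drought_index %in% 0:3))
  if (length(bad_d)) {
    validation_error("seasons: drought_index outside {0,1,2,3} at row ",
                     bad_d[1], " (value ", seasons$drought_index[bad_d[1]], ")")
  }
  bad_b <- which(!is.na(visits$bait_age_days) &
                   (visits$bait_age_days < 1 | visits$bait_age_days > 4 |
                      visits$bait_age_days != round(visits$bait_age_days)))
  if (length(bad_b)) {
    validation_error("visits: bait_age_days outside integer range [1,4] at row ",
                     bad_b[1], " (value ", visits$bait_age_days[bad_b[1]], ")")
  }
  bad_q <- which(!is.na(visits$discharge_m3s) & visits$discharge_m3s <= 0)
  if (length(bad_q)) {
    validation_error("visits: non-positive discharge_m3s at row ", bad_q[1],
                     " (site ", visits$site[bad_q[1]], ")")
  }

  y <- array(NA_real_, dim = c(n_sites, n_seasons, n_visits),
             dimnames = list(site_ids, NULL, NULL))
  idx <- cbind(match(as.character(detections$site), site_ids),
               detections$season, detections$visit)
  if (anyDuplicated(idx)) {
    d1 <- which(duplicated(idx))[1]
    validation_error("detections: duplicated site/season/visit row (site ",
                     detections$site[d1], ", season ", detections$season[d1],
                     ", visit ", detections$visit[d1], ")")
  }
  y[idx] <- detections$y

  # discharge must be present wherever a detection value was recorded
  qkey <- paste(visits$site, visits$season, visits$visit)
  obs <- detections[!is.na(detections$y), ]
  okey <- paste(obs$site, obs$season, obs$visit)
  qi <- match(okey, qkey)
  missing_q <- is.na(qi) | is.na(visits$discharge_m3s[qi])
  if (any(missing_q)) {
    m1 <- which(missing_q)[1]
    validation_error("visits: discharge_m3s missing for observed visit (site ",
                     obs$site[m1], ", season ", obs$season[m1], ", visit ",
                     obs$visit[m1], ")")
  }

  surveyed <- apply(!is.na(y), c(1, 2), any)
  if (n_seasons == 1) surveyed <- matrix(surveyed, ncol = 1)
  never <- which(rowSums(surveyed) == 0)
  if (length(never)) {
    validation_error("detections: site(s) surveyed in zero seasons: ",
                     paste(site_ids[never], collapse = ", "))
  }

  structure(
    list(
      detections = detections, sites = sites, seasons = seasons,
      visits = visits, site_ids = site_ids, n_sites = n_sites,
      n_seasons = n_seasons, n_visits = n_visits, y = y, surveyed = surveyed
    ),
    class = "study_dataset"
  )
}

validation_error <- function(...) {
  abort(paste0(...), class = "occdebt_validation_error")
}

need_cols <- function(df, cols, name) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    validation_error(name, ": missing column(s): ", paste(miss, collapse = ", "))
  }
}

check_ids <- function(ids, site_ids, name) {
  unknown <- setdiff(unique(as.character(ids)), site_ids)
  if (length(unknown)) {
    validation_error(name, ": unknown site id(s): ",
                     paste(head(unknown, 5), collapse = ", "))
  }
}

check_index <- function(x, upper, name, col) {
  bad <- which(is.na(x) | x < 1 | x > upper | x != round(x))
  if (length(bad)) {
    validation_error(name, ": column '", col, "' outside 1..", upper,
                     " at row ", bad[1], " (value ", x[bad[1]], ")")
  }
}

check_range <- function(df, col, lo, hi) {
  bad <- which(!is.na(df[[col]]) & (df[[col]] < lo | df[[col]] > hi))
  if (length(bad)) {
    validation_error("sites: column '", col, "' outside [", lo, ", ", hi,
                     "] at row ", bad[1], " (site ", df$site[bad[1]],
                     ", value ", df[[col]][bad[1]], ")")
  }
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  cat("  sites:   ", x$n_sites, "\n")
  cat("  seasons: ", x$n_seasons, " (max ", x$n_visits, " visits/season)\n", sep = "")
  cat("  surveyed site-seasons: ", sum(x$surveyed), "\n")
  cat("  detections: ", sum(x$y == 1, na.rm = TRUE), " over ",
      sum(!is.na(x$y)), " visits\n", sep = "")
  invisible(x)
}

#' Read a study from its four CSV files
#'
#' Reads and validates the on-disk representation of a study: long-format
#' detections plus site, site-by-season and visit covariate tables. Empty
#' cells and the token `NA` are both accepted for missing visits.
#'
#' @param detections_path,sites_path,seasons_path,visits_path CSV paths.
#'   See [study_dataset()] for the required columns.
#' @param n_seasons,n_visits Optional explicit dimensions (otherwise inferred).
#' @return A validated [study_dataset()].
#' @export
read_study <- function(detections_path, sites_path, seasons_path, visits_path,
                       n_seasons = NULL, n_visits = NULL) {
  rd <- function(path) {
    readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                    progress = FALSE)
  }
  study_dataset(rd(detections_path), rd(sites_path), rd(seasons_path),
                rd(visits_path), n_seasons = n_seasons, n_visits = n_visits)
}

#' Write a study to its four CSV files
#'
#' Inverse of [read_study()]: writes `detections.csv`, `sites.csv`,
#' `seasons.csv` and `visits.csv` under `dir`. Missing values are written as
#' `NA`. A write/read round trip reproduces the detection array, its
#' missingness pattern and all covariates exactly.
#'
#' @param dataset A [study_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    readr::write_csv(df, file.path(dir, name), na = "NA", progress = FALSE)
  }
  # write the full site x season x visit grid so the missingness pattern is explicit
  grid <- tidyr::expand_grid(
    site = dataset$site_ids,
    season = seq_len(dataset$n_seasons),
    visit = seq_len(dataset$n_visits)
  )
  grid$y <- dataset$y[cbind(match(grid$site, dataset$site_ids),
                            grid$season, grid$visit)]
  wr(grid, "detections.csv")
  wr(dataset$sites, "sites.csv")
  wr(dataset$seasons, "seasons.csv")
  wr(dataset$visits, "visits.csv")
  invisible(dir)
}

#' Summarize the survey design of a study
#'
#' Design bookkeeping in the form used to describe unbalanced
#' detection/non-detection monitoring: how many sites were surveyed in
#' 1, 2, ... seasons, the naive occupancy (share of sites with at least one
#' detection ever, ignoring imperfect detection), trapping effort per
#' surveyed site-season, and the share of presence sites whose habitat
#' score reaches a reporting threshold.
#'
#' @param dataset A [study_dataset()].
#' @param traps,nights Trapping effort per surveyed site-season; the default
#'   10 traps checked over 4 nights gives 40 trap-nights.
#' @param habitat_threshold Habitat-score cutoff used for the
#'   presence-site habitat summary (default 60).
#' @return A list of class `design_summary` with elements
#'   `n_sites`, `n_seasons`, `naive_occupancy` (rounded to 2 decimals),
#'   `naive_occupancy_raw`, `n_presence_sites`, `revisit_distribution`
#'   (tibble: `n_seasons_surveyed`, `n_sites`, `proportion`),
#'   `trap_nights_per_site_season`, `presence_habitat` (tibble with the
#'   count and fraction of presence sites at or above `habitat_threshold`).
#' @export
summarize_design <- function(dataset, traps = 10, nights = 4,
                             habitat_threshold = 60) {
  stopifnot(inherits(dataset, "study_dataset"))
  det_ever <- apply(dataset$y == 1, 1, any, na.rm = TRUE)
  n_presence <- sum(det_ever)
  naive_raw <- n_presence / dataset$n_sites

  n_surv <- rowSums(dataset$surveyed)
  revisit <- tibble::tibble(n_seasons_surveyed = seq_len(dataset$n_seasons)) |>
    dplyr::left_join(
      tibble::tibble(n_seasons_surveyed = as.integer(names(table(n_surv))),
                     n_sites = as.integer(table(n_surv))),
      by = "n_seasons_surveyed"
    ) |>
    dplyr::mutate(
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      proportion = .data$n_sites / dataset$n_sites
    )

  hs <- dataset$sites$habitat_score[match(dataset$site_ids, dataset$sites$site)]
  n_high <- sum(det_ever & !is.na(hs) & hs >= habitat_threshold)
  presence_habitat <- tibble::tibble(
    threshold = habitat_threshold,
    n_presence_sites = n_presence,
    n_at_or_above = n_high,
    fraction = if (n_presence > 0) n_high / n_presence else NA_real_
  )

  structure(
    list(
      n_sites = dataset$n_sites,
      n_seasons = dataset$n_seasons,
      naive_occupancy = round(naive_raw, 2),
      naive_occupancy_raw = naive_raw,
      n_presence_sites = n_presence,
      revisit_distribution = revisit,
      trap_nights_per_site_season = traps * nights,
      presence_habitat = presence_habitat
    ),
    class = "design_summary"
  )
}

#' @export
print.design_summary <- function(x, ...) {
  cat("<design_summary>\n")
  cat("  sites:", x$n_sites, " seasons:", x$n_seasons, "\n")
  cat("  naive occupancy:", x$naive_occupancy,
      sprintf("(%d/%d sites with >=1 detection)\n", x$n_presence_sites, x$n_sites))
  cat("  trap-nights per surveyed site-season:", x$trap_nights_per_site_season, "\n")
  cat("  sites by number of surveyed seasons:\n")
  print(x$revisit_distribution, n = Inf)
  invisible(x)
}
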