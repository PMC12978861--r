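#' Drainage-area-ratio discharge interpolation
#'
#' Estimates daily mean discharge at an ungaged stream site by scaling a
#' reference gage's series with the ratio of drainage areas:
#' `Q_u = (A_u / A_g) * Q_g`. The scaling is linear and elementwise over
#' the daily series.
#'
#' @param q_g Numeric vector of gaged daily mean discharge (m3/s, >= 0).
#' @param a_u Drainage area of the ungaged site (km2, > 0).
#' @param a_g Drainage area of the gaged site (km2, > 0).
#' @return Interpolated discharge series, same length as `q_g`.
#' @export
interpolate_discharge <- function(q_g, a_u, a_g) {
  if (!is.numeric(a_g) || length(a_g) != 1 || a_g <= 0) {
    abort("'a_g' must be a single positive drainage area",
          class = "occdebt_domain_error")
  }
  if (!is.numeric(a_u) || length(a_u) != 1 || a_u <= 0) {
    abort("'a_u' must be a single positive drainage area",
          class = "occdebt_domain_error")
  }
  if (any(q_g < 0, na.rm = TRUE)) {
    abort("'q_g' must be non-negative", class = "occdebt_domain_error")
  }
  (a_u / a_g) * q_g
}

#' Select the reference gage for an ungaged site
#'
#' Among gages sharing the site's HUC10 watershed code and lying within
#' the distance threshold (Euclidean, on user-supplied planar coordinates
#' in meters), returns the nearest gage. Watershed membership dominates raw
#' proximity because the closest gage by distance is not always the most
#' representative of discharge at the ungaged location. Distance ties are
#' broken by the drainage-area ratio closest to 1 (smallest
#' `|log(A_u/A_g)|`), then by gage id.
#'
#' @param site One-row data frame (or list) with `huc10`, `x_m`, `y_m`,
#'   `drainage_area_km2`.
#' @param gages Data frame of candidate gages: `gage_id`, `huc10`, `x_m`,
#'   `y_m`, `drainage_area_km2`.
#' @param max_distance_m Distance threshold in meters (default 50 km).
#' @return The selected gage as a one-row tibble with an added
#'   `distance_m` column.
#' @export
select_reference_gage <- function(site, gages, max_distance_m = 50000) {
  gages <- tibble::as_tibble(gages)
  need_cols(gages, c("gage_id", "huc10", "x_m", "y_m", "drainage_area_km2"),
            "gages")
  cand <- gages |>
    dplyr::filter(.data$huc10 == site$huc10) |>
    dplyr::mutate(
      distance_m = sqrt((.data$x_m - site$x_m)^2 + (.data$y_m - site$y_m)^2),
      area_ratio_dev = abs(log(site$drainage_area_km2 / .data$drainage_area_km2))
    ) |>
    dplyr::filter(.data$distance_m <= max_distance_m) |>
    dplyr::arrange(.data$distance_m, .data$area_ratio_dev, .data$gage_id)
  if (!nrow(cand)) {
    abort(paste0("no gage within ", max_distance_m / 1000,
                 " km in HUC10 ", site$huc10,
                 "; assign a reference gage manually"),
          class = "occdebt_domain_error")
  }
  cand[1, setdiff(names(cand), "area_ratio_dev")]
}

#' TQmean flow flashiness
#'
#' The fraction of the year on which daily mean discharge strictly exceeds
#' the annual mean discharge. Flashy (often urbanized) streams concentrate
#' their flow into brief high peaks, spend most days below the annual
#' mean, and therefore have low TQmean.
#'
#' @param daily Either a numeric vector of 365/366 daily values, or a data
#'   frame with columns `date` and a discharge column (`q_m3s` or `q`)
#'   covering one full calendar year with no gaps.
#' @param strict Use strict exceedance `>` (default). Set `FALSE` for `>=`.
#' @return Fraction in `[0, 1]`.
#' @export
tqmean <- function(daily, strict = TRUE) {
  if (is.data.frame(daily)) {
    qcol <- intersect(c("q_m3s", "q"), names(daily))[1]
    if (is.na(qcol) || !"date" %in% names(daily)) {
      abort("data-frame input needs columns 'date' and 'q_m3s' (or 'q')")
    }
    dates <- as.Date(daily$date)
    yr <- unique(format(dates, "%Y"))
    if (length(yr) != 1) {
      abort("series must cover exactly one calendar year",
            class = "occdebt_domain_error")
    }
    full <- seq(as.Date(paste0(yr, "-01-01")),
                as.Date(paste0(yr, "-12-31")), by = "day")
    missing_days <- setdiff(as.character(full), as.character(dates))
    if (length(missing_days)) {
      abort(paste0("missing day(s) in the series: ",
                   paste(head(missing_days, 5), collapse = ", "),
                   if (length(missing_days) > 5) " ..."),
            class = "occdebt_domain_error")
    }
    q <- daily[[qcol]][order(dates)]
  } else {
    q <- as.numeric(daily)
    if (!length(q) %in% c(365, 366)) {
      abort("numeric input must contain 365 or 366 daily values",
            class = "occdebt_domain_error")
    }
  }
  if (anyNA(q)) {
    abort("series contains missing discharge values",
          class = "occdebt_domain_error")
  }
  m <- mean(q)
  if (strict) mean(q > m) else mean(q >= m)
}

#' Encode a drought-monitor stage as an ordinal index
#'
#' Maps the maximum annual drought stage to the ordinal index used as an
#' extinction-probability covariate: `None` = 0, `D0` (Abnormally Dry) =
#' 1, `D1` (Moderate Drought) = 2, `D2` (Severe Drought) = 3. Stages D3
#' and D4 are outside the supported range and raise an error (a documented
#' extension point).
#'
#' @param max_annual_stage Character vector of stages.
#' @return Integer vector of indices in `{0, 1, 2, 3}`.
#' @export
encode_drought <- function(max_annual_stage) {
  map <- c(None = 0L, D0 = 1L, D1 = 2L, D2 = 3L)
  idx <- map[as.character(max_annual_stage)]
  bad <- which(is.na(idx) & !is.na(max_annual_stage))
  if (length(bad)) {
    abort(paste0("unsupported drought stage '", max_annual_stage[bad[1]],
                 "': supported stages are None, D0, D1, D2"),
          class = "occdebt_domain_error")
  }
  unname(idx)
}
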