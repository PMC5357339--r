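#' Occurrence-record cleaning
#'
#' Three filters applied in a fixed order, mirroring standard practice for
#' aggregated presence records: (1) drop records off the working grid or on
#' nodata ("sea") cells; (2) drop records whose cited elevation differs from
#' the gridded elevation by strictly more than a tolerance (default 100 m) —
#' records with no cited elevation are retained; (3) keep one record per
#' occupied grid cell (first in input order). [clean_occurrences()] chains the
#' three and returns a reconciled cleaning report.
#'
#' @param records data.frame with columns `x`, `y` (km, equal-area plane) and
#'   `cited_elevation_m` (may be `NA`).
#' @param grid a [grid_spec()].
#' @return for the individual filters, `list(records, n_removed)`; see
#'   [clean_occurrences()] for the combined report.
#' @name cleaning
NULL

#' @rdname cleaning
#' @export
drop_offgrid <- function(records, grid) {
  if (nrow(records) == 0) return(list(records = records, n_removed = 0L))
  rc <- cell_of_xy(grid, records$x, records$y)
  inside <- !is.na(rc[, "row"])
  keep <- inside
  keep[inside] <- !grid$nodata_mask[rc[inside, , drop = FALSE]]
  list(records = records[keep, , drop = FALSE],
       n_removed = sum(!keep))
}

#' @param dem elevation matrix on `grid` (m).
#' @param tolerance_m elevation mismatch tolerance (m); removal uses strict
#'   `>` ("exceeded"). Default 100.
#' @rdname cleaning
#' @export
elevation_filter <- function(records, dem, grid, tolerance_m = 100) {
  if (nrow(records) == 0) return(list(records = records, n_removed = 0L))
  rc <- cell_of_xy(grid, records$x, records$y)
  cell_elev <- dem[rc]
  diff <- abs(records$cited_elevation_m - cell_elev)
  # NA cited elevation -> retained; NA dem (nodata cell) -> removed here
  keep <- ifelse(is.na(cell_elev), FALSE,
                 ifelse(is.na(records$cited_elevation_m), TRUE,
                        diff <= tolerance_m))
  list(records = records[keep, , drop = FALSE],
       n_removed = sum(!keep))
}

#' @rdname cleaning
#' @export
dedup_cells <- function(records, grid) {
  if (nrow(records) == 0) return(list(records = records, n_removed = 0L))
  rc <- cell_of_xy(grid, records$x, records$y)
  cell_id <- (rc[, "row"] - 1L) * grid$n_cols + rc[, "col"]
  keep <- !duplicated(cell_id)
  list(records = records[keep, , drop = FALSE],
       n_removed = sum(!keep))
}

#' @rdname cleaning
#' @export
clean_occurrences <- function(records, grid, dem, tolerance_m = 100) {
  s1 <- drop_offgrid(records, grid)
  s2 <- elevation_filter(s1$records, dem, grid, tolerance_m)
  s3 <- dedup_cells(s2$records, grid)
  report <- list(
    n_input = nrow(records),
    n_removed_offgrid = s1$n_removed,
    n_removed_elevation = s2$n_removed,
    n_removed_duplicate = s3$n_removed,
    n_retained = nrow(s3$records)
  )
  stopifnot(report$n_input == report$n_retained + report$n_removed_offgrid +
              report$n_removed_elevation + report$n_removed_duplicate)
  list(records = s3$records, report = report)
}

#' Days per calendar month (non-leap year)
#' @export
DAYS_PER_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

check_monthly <- function(layers, what) {
  if (!is.list(layers) || length(layers) != 12 ||
      any(vapply(layers, is.null, logical(1)))) {
    stop(sprintf("%s must be a list of 12 monthly layers", what))
  }
  invisible(TRUE)
}

#' Growing degree days
#'
#' Annual thermal sum above a base temperature from monthly means:
#' `gdd = sum_m max(0, tmean_m - base_C) * days_m`. The monthly-mean
#' approximation with a 5 degree C base is the standard macroclimate
#' convention.
#'
#' @param tmean list of 12 monthly mean-temperature matrices (degrees C).
#' @param base_C base temperature, default 5.
#' @param days_per_month integer vector of 12 month lengths.
#' @return degree-day matrix (degrees C times day).
#' @export
growing_degree_days <- function(tmean, base_C = 5,
                                days_per_month = DAYS_PER_MONTH) {
  check_monthly(tmean, "tmean")
  gdd <- tmean[[1]] * 0
  for (m in 1:12) gdd <- gdd + pmax(0, tmean[[m]] - base_C) * days_per_month[m]
  gdd
}

#' Absolute minimum temperature of the coldest month
#'
#' Cellwise minimum over the 12 monthly minimum-temperature layers.
#'
#' @param tmin list of 12 monthly minimum-temperature matrices (degrees C).
#' @return matrix (degrees C).
#' @export
absolute_min_temperature <- function(tmin) {
  check_monthly(tmin, "tmin")
  Reduce(pmin, tmin)
}

# mean day length (h) per month from latitude: solar declination at the
# mid-month day of year, hour-angle formula, clamped for polar day/night
month_day_length <- function(latitude, days_per_month = DAYS_PER_MONTH) {
  mid_doy <- cumsum(days_per_month) - days_per_month / 2
  lat_r <- latitude * pi / 180
  lapply(seq_len(12), function(m) {
    decl <- 0.409 * sin(2 * pi * mid_doy[m] / 365 - 1.39)
    cos_w <- pmin(pmax(-tan(lat_r) * tan(decl), -1), 1)
    24 / pi * acos(cos_w)
  })
}

#' Annual water balance (precipitation minus Thornthwaite PET)
#'
#' Potential evapotranspiration follows Thornthwaite's temperature-based
#' formulation: with heat index `I = sum_m (max(0, tmean_m)/5)^1.514` and
#' exponent `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`, monthly
#' PET (mm) is `16 (L_m/12) (N_m/30) (10 max(0, tmean_m)/I)^a`, where `L_m` is
#' the mean day length in hours (from latitude) and `N_m` the days in the
#' month; PET is 0 in months with `tmean <= 0`, and identically 0 where all
#' months are at or below freezing (`I = 0`). The water balance
#' `sum_m (precip_m - PET_m)` can be negative (arid cells).
#'
#' @param precip list of 12 monthly precipitation matrices (mm).
#' @param tmean list of 12 monthly mean-temperature matrices (degrees C).
#' @param latitude latitude matrix (degrees).
#' @param days_per_month integer vector of 12 month lengths.
#' @return water-balance matrix (mm per year).
#' @export
water_balance <- function(precip, tmean, latitude,
                          days_per_month = DAYS_PER_MONTH) {
  check_monthly(precip, "precip")
  check_monthly(tmean, "tmean")
  tpos <- lapply(tmean, function(t) pmax(0, t))
  I <- Reduce(`+`, lapply(tpos, function(t) (t / 5)^1.514))
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  L <- month_day_length(latitude, days_per_month)
  wbal <- precip[[1]] * 0
  for (m in 1:12) {
    pet <- 16 * (L[[m]] / 12) * (days_per_month[m] / 30) *
      ifelse(I > 0, (10 * tpos[[m]] / pmax(I, .Machine$double.eps))^a, 0)
    pet[tpos[[m]] <= 0] <- 0
    wbal <- wbal + precip[[m]] - pet
  }
  wbal
}

#' Derive the three bioclimatic predictor layers
#'
#' @param climate a `monthly_climate` list as returned by
#'   [generate_climate()] (fields `tmean`, `tmin`, `precip`, `latitude`).
#' @param days_per_month integer vector of 12 month lengths.
#' @return list with matrices `gdd`, `tmin_abs`, `wbal`, class
#'   `bioclim_layers`.
#' @export
derive_bioclim <- function(climate, days_per_month = DAYS_PER_MONTH) {
  structure(list(
    gdd = growing_degree_days(climate$tmean, days_per_month = days_per_month),
    tmin_abs = absolute_min_temperature(climate$tmin),
    wbal = water_balance(climate$precip, climate$tmean, climate$latitude,
                         days_per_month = days_per_month)
  ), class = "bioclim_layers")
}
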