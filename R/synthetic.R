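#' Synthetic climate, elevation and occurrence data with known ground truth
#'
#' These generators stand in for downloaded climate grids and aggregated
#' occurrence databases so that every downstream stage — record cleaning,
#' bioclimatic derivation, maximum-entropy fitting, evaluation and risk-area
#' change — can be exercised against a known truth. Fields are built as a
#' deterministic north--south gradient plus seeded Gaussian noise smoothed by
#' a fixed-width moving average, which gives spatial autocorrelation and a
#' climate-like latitudinal structure without any projection machinery: the
#' synthetic world lives natively in an equal-area plane.
#'
#' @name synthetic_data
NULL

# box smoothing with edge-clamped windows via summed-area tables;
# half-width w means a (2w+1)^2 window interior
box_smooth <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  sat <- apply(m, 2, cumsum)
  sat <- t(apply(sat, 1, cumsum))
  sat <- rbind(0, cbind(0, sat))
  r1 <- pmax(seq_len(nr) - w, 1); r2 <- pmin(seq_len(nr) + w, nr)
  c1 <- pmax(seq_len(nc) - w, 1); c2 <- pmin(seq_len(nc) + w, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    a <- sat[r2 + 1, c2[j] + 1] - sat[r1, c2[j] + 1] -
      sat[r2 + 1, c1[j]] + sat[r1, c1[j]]
    out[, j] <- a / ((r2 - r1 + 1) * (c2[j] - c1[j] + 1))
  }
  out
}

# seeded smooth field on (0,1): smoothed Gaussian noise mapped through pnorm
smooth_unit_field <- function(grid, seed, width = 3) {
  with_seed(seed, {
    z <- matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                grid$n_rows, grid$n_cols)
    s <- box_smooth(z, width)
    stats::pnorm(s / stats::sd(s))
  })
}

mask_layer <- function(grid, values) {
  values[grid$nodata_mask] <- NA_real_
  values
}

#' Generate monthly climate fields
#'
#' Builds 12 monthly mean-temperature, minimum-temperature and precipitation
#' layers. Mean temperature is a latitudinal gradient plus smoothed seeded
#' noise, with a sinusoidal seasonal cycle peaking in July; monthly minimum
#' temperature is the mean minus a positive, spatially smooth diurnal offset;
#' precipitation is a positive smooth field with mild seasonality. A future
#' scenario is the current climate plus `warming_offset_C` on both temperature
#' sets and times `precip_factor` on precipitation, so scenario fields with
#' the same seed differ from the current ones only by those two knobs.
#'
#' @param grid a [grid_spec()].
#' @param seed integer seed; identical seeds give bit-identical fields.
#' @param warming_offset_C additive temperature offset (degrees C), default 0.
#' @param precip_factor multiplicative precipitation factor (> 0), default 1.
#' @return list with `tmean`, `tmin`, `precip` (each a list of 12 matrices),
#'   and `latitude` (degrees), class `monthly_climate`.
#' @export
generate_climate <- function(grid, seed, warming_offset_C = 0, precip_factor = 1) {
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec")
  if (precip_factor <= 0) stop("precip_factor must be > 0")
  lat <- matrix(lat_of_row(grid, seq_len(grid$n_rows)), grid$n_rows, grid$n_cols)
  u_t <- smooth_unit_field(grid, derive_seed(seed, 11))
  u_d <- smooth_unit_field(grid, derive_seed(seed, 12))
  u_p <- smooth_unit_field(grid, derive_seed(seed, 13))

  # annual mean: ~12 C at 32N falling to ~-10 C at 60N, plus +-3 C local noise
  t_annual <- 37 - 0.78 * lat + 6 * (u_t - 0.5)
  amp <- 10 + 2 * (u_t - 0.5)              # seasonal amplitude ~9-11 C
  diurnal <- 4 + 4 * u_d                    # positive tmean - tmin offset
  p_base <- 30 + 60 * u_p                   # mm per month

  tmean <- tmin <- precip <- vector("list", 12)
  for (m in 1:12) {
    tm <- t_annual + amp * cos(2 * pi * (m - 7) / 12) + warming_offset_C
    pm <- p_base * (1 + 0.3 * sin(2 * pi * (m - 4) / 12)) * precip_factor
    tmean[[m]] <- mask_layer(grid, tm)
    tmin[[m]] <- mask_layer(grid, tm - diurnal)
    precip[[m]] <- mask_layer(grid, pm)
  }
  structure(list(tmean = tmean, tmin = tmin, precip = precip,
                 latitude = mask_layer(grid, lat)),
            class = "monthly_climate")
}

#' Generate a synthetic elevation model
#'
#' Smooth, non-negative elevation field (0--1500 m), deterministic in the
#' seed; nodata cells carry `NA`.
#'
#' @inheritParams generate_climate
#' @return elevation matrix (m).
#' @export
generate_elevation <- function(grid, seed) {
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec")
  u <- smooth_unit_field(grid, derive_seed(seed, 21))
  mask_layer(grid, 1500 * u^2)
}

#' Ground-truth suitability parameters
#'
#' Coefficients of a logistic ("virtual species") suitability surface applied
#' to standardized bioclimatic predictors: suitability =
#' logistic(intercept + sum linear_v z_v + sum quadratic_v z_v^2).
#'
#' @param intercept scalar intercept.
#' @param linear,quadratic named numeric vectors keyed by predictor name
#'   (`gdd`, `tmin_abs`, `wbal`); missing names count as 0.
#' @return object of class `truth_params`.
#' @export
truth_params <- function(intercept = 0, linear = c(gdd = 2),
                         quadratic = numeric()) {
  if (all(c(linear, quadratic) == 0)) {
    stop("at least one linear or quadratic coefficient must be nonzero")
  }
  structure(list(intercept = intercept, linear = linear, quadratic = quadratic),
            class = "truth_params")
}

#' True suitability surface from bioclimatic layers
#'
#' Standardizes each predictor layer over valid cells (zero mean, unit
#' variance), applies the linear/quadratic coefficients in `params`, and maps
#' through the logistic function. Nodata is preserved.
#'
#' @param bioclim a [bioclim_layers] list (`gdd`, `tmin_abs`, `wbal` matrices).
#' @param params a [truth_params()].
#' @return suitability matrix with values in (0, 1).
#' @export
true_suitability <- function(bioclim, params) {
  layers <- bioclim[c("gdd", "tmin_abs", "wbal")]
  if (all(vapply(layers, function(l) all(is.na(l)), logical(1)))) {
    stop("all predictor layers are nodata")
  }
  eta <- params$intercept
  for (v in names(layers)) {
    l <- layers[[v]]
    mu <- mean(l, na.rm = TRUE)
    sg <- stats::sd(l, na.rm = TRUE)
    z <- if (is.na(sg) || sg == 0) l * 0 else (l - mu) / sg
    bl <- unname(params$linear[v]); bq <- unname(params$quadratic[v])
    if (!is.na(bl) && length(bl)) eta <- eta + bl * z
    if (!is.na(bq) && length(bq)) eta <- eta + bq * z^2
  }
  stats::plogis(eta)
}

#' Sample occurrence records from a truth surface, with injected errors
#'
#' Clean records are drawn from valid cells with probability proportional to
#' the truth suitability, placed uniformly within their cell, and given a
#' cited elevation within +-100 m of the cell's elevation (so they survive the
#' strict 100 m elevation filter). Error records are flagged `is_error`:
#' `offgrid` records sit on nodata cells (or outside the extent when the grid
#' has no nodata), `elev_mismatch` records cite an elevation off by more than
#' 100 m, and `duplicate` records are copies dropped into an already-sampled
#' cell. Error counts are `round(n * rate)`; the remainder are clean.
#'
#' @param truth suitability matrix (values >= 0, not all zero).
#' @param grid a [grid_spec()].
#' @param dem elevation matrix on `grid`.
#' @param n total number of records (>= 1); cells are sampled with
#'   replacement, so `n` may exceed the number of valid cells.
#' @param seed integer seed.
#' @param error_rates list with proportions `offgrid`, `elev_mismatch`,
#'   `duplicate`, each in \[0,1\], summing to <= 1.
#' @param species species label for the output records.
#' @return data.frame with columns `species`, `x`, `y`, `cited_elevation_m`,
#'   `is_error`.
#' @export
sample_occurrences <- function(truth, grid, dem, n, seed,
                               error_rates = list(offgrid = 0,
                                                  elev_mismatch = 0,
                                                  duplicate = 0),
                               species = "synthetic_species") {
  if (n < 1) stop("n must be >= 1")
  rates <- c(offgrid = error_rates$offgrid %||% 0,
             elev_mismatch = error_rates$elev_mismatch %||% 0,
             duplicate = error_rates$duplicate %||% 0)
  if (any(rates < 0 | rates > 1) || sum(rates) > 1) {
    stop("error rates must lie in [0,1] and sum to <= 1")
  }
  w <- truth
  w[grid$nodata_mask] <- NA_real_
  ok <- which(!is.na(w) & w > 0)
  if (length(ok) == 0) stop("truth surface has no positive valid cells")

  n_err <- round(n * rates)
  n_clean <- n - sum(n_err)

  with_seed(seed, {
    half <- grid$cell_size_km / 2
    draw_in_cells <- function(cells) {
      rc <- arrayInd(cells, dim(truth))
      ctr <- cell_center(grid, rc[, 1], rc[, 2])
      data.frame(
        row = rc[, 1], col = rc[, 2],
        x = ctr[, "x"] + stats::runif(length(cells), -half, half),
        y = ctr[, "y"] + stats::runif(length(cells), -half, half)
      )
    }

    recs <- list()
    clean_cells <- integer(0)
    if (n_clean > 0) {
      clean_cells <- sample(ok, n_clean, replace = TRUE, prob = w[ok])
      d <- draw_in_cells(clean_cells)
      recs$clean <- data.frame(
        species = species, x = d$x, y = d$y,
        cited_elevation_m = dem[cbind(d$row, d$col)] +
          stats::runif(n_clean, -100, 100),
        is_error = FALSE
      )
    }
    if (n_err["offgrid"] > 0) {
      k <- n_err["offgrid"]
      sea <- which(grid$nodata_mask)
      if (length(sea) > 0) {
        d <- draw_in_cells(sample(sea, k, replace = TRUE))
        xo <- d$x; yo <- d$y
      } else {
        xo <- grid$origin_x - stats::runif(k, 1, 10) * grid$cell_size_km
        yo <- grid$origin_y + stats::runif(k, 0, grid$n_rows) * grid$cell_size_km
      }
      recs$offgrid <- data.frame(species = species, x = xo, y = yo,
                                 cited_elevation_m = stats::runif(k, 0, 1500),
                                 is_error = TRUE)
    }
    if (n_err["elev_mismatch"] > 0) {
      k <- n_err["elev_mismatch"]
      cells <- sample(ok, k, replace = TRUE, prob = w[ok])
      d <- draw_in_cells(cells)
      off <- (101 + stats::runif(k, 0, 400)) * sample(c(-1, 1), k, replace = TRUE)
      recs$mismatch <- data.frame(
        species = species, x = d$x, y = d$y,
        cited_elevation_m = pmax(dem[cbind(d$row, d$col)] + off, -499),
        is_error = TRUE
      )
    }
    if (n_err["duplicate"] > 0) {
      k <- n_err["duplicate"]
      host <- if (length(clean_cells) > 0) clean_cells else ok
      cells <- sample(host, k, replace = TRUE)
      d <- draw_in_cells(cells)
      recs$dup <- data.frame(
        species = species, x = d$x, y = d$y,
        cited_elevation_m = dem[cbind(d$row, d$col)] +
          stats::runif(k, -100, 100),
        is_error = TRUE
      )
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}
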