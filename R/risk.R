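#' Quartile threshold for high-risk classification
#'
#' The break value is the lower limit of the highest quartile of present-day
#' suitability: the 75th percentile (linear interpolation between order
#' statistics, `quantile type 7`) over valid cells, optionally restricted to a
#' region mask.
#'
#' @param current_map suitability matrix or vector (present-day).
#' @param region_mask optional logical mask (`TRUE` = in region) of the same
#'   shape.
#' @return threshold t in the suitability units of the map.
#' @export
har_threshold <- function(current_map, region_mask = NULL) {
  v <- as.vector(current_map)
  if (!is.null(region_mask)) v <- v[as.vector(region_mask)]
  v <- v[!is.na(v)]
  if (length(v) < 4) stop("need at least 4 valid cells to take a quartile")
  stats::quantile(v, 0.75, type = 7, names = FALSE)
}

#' Binary high-risk classification
#'
#' A cell is high-risk iff its suitability is `>= t` (the break value itself
#' belongs to the top class); nodata stays `NA`.
#'
#' @param map suitability matrix or vector.
#' @param t threshold (finite).
#' @return 0/1 layer of the same shape, `NA` preserved.
#' @export
classify_har <- function(map, t) {
  if (!is.finite(t)) stop("threshold must be finite")
  out <- ifelse(is.na(map), NA_real_, as.numeric(map >= t))
  if (is.matrix(map)) out <- matrix(out, nrow(map), ncol(map))
  out
}

#' Area of a binary layer
#'
#' @param binary 0/1 layer (NA = nodata).
#' @param cell_area_km2 area of one grid cell in km2 (> 0); default 100, a
#'   10 km x 10 km equal-area cell.
#' @return area in km2 (an integer multiple of `cell_area_km2`).
#' @export
area_km2 <- function(binary, cell_area_km2 = 100) {
  if (cell_area_km2 <= 0) stop("cell_area_km2 must be > 0")
  sum(binary == 1, na.rm = TRUE) * cell_area_km2
}

#' Area-change statistics between a current and a future area
#'
#' Reports the absolute change and both printed percent conventions:
#' `percent_increase = (F - C)/C * 100` (an unchanged area scores 0) and
#' `percent_of_current = F/C * 100` (an unchanged area scores 100). Rounding
#' to integer percent is left to the report layer.
#'
#' @param current,future areas in km2; `current` must be > 0 for the percent
#'   fields (otherwise they are `NA`).
#' @return list with `delta_km2`, `percent_increase`, `percent_of_current`.
#' @export
change_stats <- function(current, future) {
  delta <- future - current
  if (current > 0) {
    list(delta_km2 = delta,
         percent_increase = delta / current * 100,
         percent_of_current = future / current * 100)
  } else {
    list(delta_km2 = delta,
         percent_increase = NA_real_,
         percent_of_current = NA_real_)
  }
}

#' High-risk area report across climate scenarios
#'
#' Computes the quartile threshold from the current map only, classifies the
#' current and every scenario map with that same threshold, and tabulates
#' areas and both change conventions per scenario.
#'
#' @param current_map present-day suitability layer.
#' @param scenario_maps named list of future suitability layers on the same
#'   grid shape.
#' @param region_mask optional logical mask restricting the analysis region.
#' @param cell_area_km2 area of one cell (km2), default 100.
#' @return object of class `har_result`: `threshold`, `binary` (named list of
#'   0/1 layers including `current`), `areas_km2` (named), `changes` (named
#'   list of [change_stats()] results), and `table` (one row per scenario).
#' @export
har_report <- function(current_map, scenario_maps = list(),
                       region_mask = NULL, cell_area_km2 = 100) {
  for (s in scenario_maps) {
    if (!identical(dim(s) %||% length(s), dim(current_map) %||% length(current_map))) {
      stop("scenario map shape does not match the current map")
    }
  }
  apply_mask <- function(map) {
    if (is.null(region_mask)) return(map)
    out <- map
    out[!region_mask] <- NA_real_
    out
  }
  cur <- apply_mask(current_map)
  t <- har_threshold(cur)
  bin <- c(list(current = classify_har(cur, t)),
           lapply(scenario_maps, function(s) classify_har(apply_mask(s), t)))
  areas <- vapply(bin, area_km2, numeric(1), cell_area_km2 = cell_area_km2)
  changes <- lapply(names(scenario_maps), function(nm) {
    change_stats(areas[["current"]], areas[[nm]])
  })
  names(changes) <- names(scenario_maps)
  tab <- do.call(rbind, lapply(names(scenario_maps), function(nm) {
    ch <- changes[[nm]]
    data.frame(scenario = nm,
               current_km2 = areas[["current"]],
               future_km2 = areas[[nm]],
               delta_km2 = ch$delta_km2,
               percent_increase = ch$percent_increase,
               percent_of_current = ch$percent_of_current)
  }))
  structure(list(threshold = t, binary = bin, areas_km2 = areas,
                 changes = changes, cell_area_km2 = cell_area_km2,
                 table = tab),
            class = "har_result")
}

#' @export
print.har_result <- function(x, ...) {
  cat(sprintf("har_result: threshold %.4f, current area %s km2\n",
              x$threshold, format(x$areas_km2[["current"]], big.mark = ",")))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}
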