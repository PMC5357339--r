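#' Read occurrence records from CSV
#'
#' Expects Darwin-Core-like columns `species`, `decimalLongitude`,
#' `decimalLatitude`, `elevation` (coordinates in the equal-area plane's km
#' units). Rows whose coordinates do not parse as numbers are skipped and
#' counted; blank or unparseable elevations become missing cited elevations
#' (the record is kept).
#'
#' @param path CSV file path.
#' @return list: `records` (data.frame with `species`, `x`, `y`,
#'   `cited_elevation_m`, and `is_error` when present in the file) and
#'   `report` (`n_rows`, `n_parsed`, `n_skipped`).
#' @export
read_occurrences <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("species", "decimalLongitude", "decimalLatitude", "elevation")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- suppressWarnings(as.numeric(raw$decimalLongitude))
  y <- suppressWarnings(as.numeric(raw$decimalLatitude))
  elev <- suppressWarnings(as.numeric(raw$elevation))
  ok <- is.finite(x) & is.finite(y)
  records <- data.frame(species = raw$species[ok],
                        x = x[ok], y = y[ok],
                        cited_elevation_m = elev[ok])
  if ("is_error" %in% names(raw)) {
    records$is_error <- as.logical(raw$is_error[ok])
  }
  list(records = records,
       report = list(n_rows = nrow(raw), n_parsed = sum(ok),
                     n_skipped = sum(!ok)))
}

#' Write occurrence records as CSV
#'
#' Inverse of [read_occurrences()]: columns `species`, `decimalLongitude`,
#' `decimalLatitude`, `elevation` (and `is_error` if present).
#'
#' @param records data.frame with `species`, `x`, `y`, `cited_elevation_m`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  out <- data.frame(species = records$species,
                    decimalLongitude = records$x,
                    decimalLatitude = records$y,
                    elevation = records$cited_elevation_m)
  if ("is_error" %in% names(records)) out$is_error <- records$is_error
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. The synthetic world is one
#' equal-area grid split into two disjoint sub-extents: a training region
#' (where occurrences are sampled and the model is fitted) and a projection
#' region (where suitability is projected and risk areas are tabulated),
#' standing in for a native and an invaded range. Scenario entries hold an
#' additive warming (degrees C) and a multiplicative precipitation factor
#' applied to the current climate.
#'
#' @param n_rows,n_cols,cell_size_km,origin_x,origin_y grid geometry; see
#'   [grid_spec()].
#' @param nodata_mask optional logical mask of invalid cells.
#' @param training_cols,projection_cols integer column ranges (length-2
#'   vectors) defining the two disjoint regions.
#' @param scenarios named list of `list(warming_offset_C, precip_factor)`.
#'   Defaults hold a moderate (+2.2 C, wetter) and a high-end (+3.7 C, drier)
#'   end-of-century scenario.
#' @param truth a [truth_params()] ground-truth definition.
#' @param n_occurrences number of synthetic records to draw.
#' @param error_rates record-error proportions; see [sample_occurrences()].
#' @param classes_candidates,rm_candidates AICc tuning grid (set each to a
#'   single value to skip searching).
#' @param n_hinge_knots hinge knots per predictor.
#' @param n_replicates,test_fraction replicate fitting controls.
#' @param elevation_tolerance_m cleaning tolerance (m).
#' @param cell_area_km2 cell area for risk tabulation (km2).
#' @param background_max background size cap; all valid training cells are
#'   used when fewer, otherwise a seeded uniform sample this big.
#' @param master_seed integer master seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_rows = 60, n_cols = 100, cell_size_km = 10,
                            origin_x = 0, origin_y = 3600,
                            nodata_mask = NULL,
                            training_cols = c(1, 50),
                            projection_cols = c(51, 100),
                            scenarios = list(
                              rcp60 = list(warming_offset_C = 2.2,
                                           precip_factor = 1.05),
                              rcp85 = list(warming_offset_C = 3.7,
                                           precip_factor = 0.9)),
                            truth = truth_params(
                              intercept = 0,
                              linear = c(gdd = 2, tmin_abs = 0.75, wbal = 0.5),
                              quadratic = c(gdd = -0.25)),
                            n_occurrences = 600,
                            error_rates = list(offgrid = 0.05,
                                               elev_mismatch = 0.05,
                                               duplicate = 0.05),
                            classes_candidates = "LQ",
                            rm_candidates = 1,
                            n_hinge_knots = 10,
                            n_replicates = 15,
                            test_fraction = 0.25,
                            elevation_tolerance_m = 100,
                            cell_area_km2 = 100,
                            background_max = 10000,
                            master_seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  if (max(training_cols) >= min(projection_cols) &&
      max(projection_cols) >= min(training_cols)) {
    if (length(intersect(seq(training_cols[1], training_cols[2]),
                         seq(projection_cols[1], projection_cols[2])))) {
      stop("training and projection regions must be disjoint")
    }
  }
  structure(cfg, class = "pipeline_config")
}

region_mask_cols <- function(grid, col_range) {
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  m[, seq(col_range[1], col_range[2])] <- TRUE
  m & !grid$nodata_mask
}

# predictor data.frame at the valid cells of a mask, plus the cell indices
predictors_at <- function(bioclim, mask) {
  idx <- which(mask & !is.na(bioclim$gdd))
  list(data = data.frame(gdd = bioclim$gdd[idx],
                         tmin_abs = bioclim$tmin_abs[idx],
                         wbal = bioclim$wbal[idx]),
       idx = idx)
}

values_to_layer <- function(grid, idx, values) {
  m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  m[idx] <- values
  m
}

#' Run the full pipeline
#'
#' Chains every stage on synthetic data: generate climate/elevation ->
#' ground-truth suitability -> sample and clean occurrences -> derive
#' bioclimatic predictors -> AICc tuning -> replicate fitting -> evaluation
#' (AUC, jackknife importance, MESS) -> projection to climate scenarios ->
#' high-risk area report. Fully deterministic under the config's master seed.
#' When `outdir` is given, stage artifacts (rasters, CSVs, JSON reports) are
#' written there and digested into the run manifest.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory (created if needed).
#' @return list of class `pipeline_result` with fields `grid`, `truth_map`,
#'   `cleaning`, `tuning`, `fit` (replicate fit), `evaluation`, `mess`,
#'   `suitability` (named list of projection-region mean maps, including
#'   `current`), `har`, and `manifest` (config snapshot, seed ledger, stage
#'   timings, output digests).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  seeds <- list(climate = derive_seed(config$master_seed, 1),
                elevation = derive_seed(config$master_seed, 2),
                sampling = derive_seed(config$master_seed, 3),
                background = derive_seed(config$master_seed, 4),
                replicates = derive_seed(config$master_seed, 5))

  grid <- grid_spec(config$n_rows, config$n_cols, config$cell_size_km,
                    config$origin_x, config$origin_y, config$nodata_mask)

  sim <- stage("simulate", {
    climate <- generate_climate(grid, seeds$climate)
    dem <- generate_elevation(grid, seeds$elevation)
    futures <- lapply(config$scenarios, function(sc) {
      generate_climate(grid, seeds$climate,
                       warming_offset_C = sc$warming_offset_C,
                       precip_factor = sc$precip_factor)
    })
    list(climate = climate, dem = dem, futures = futures)
  })

  bio <- stage("bioclim", {
    c(list(current = derive_bioclim(sim$climate)),
      lapply(sim$futures, derive_bioclim))
  })

  train_mask <- region_mask_cols(grid, config$training_cols)
  proj_mask <- region_mask_cols(grid, config$projection_cols)

  occ <- stage("sample", {
    truth_map <- true_suitability(bio$current, config$truth)
    truth_train <- truth_map
    truth_train[!train_mask] <- 0
    records <- sample_occurrences(truth_train, grid, sim$dem,
                                  n = config$n_occurrences,
                                  seed = seeds$sampling,
                                  error_rates = config$error_rates)
    list(truth_map = truth_map, records = records)
  })

  cleaned <- stage("clean", {
    clean_occurrences(occ$records, grid, sim$dem,
                      tolerance_m = config$elevation_tolerance_m)
  })

  design <- stage("extract", {
    train <- predictors_at(bio$current, train_mask)
    if (nrow(train$data) > config$background_max) {
      keep <- with_seed(seeds$background,
                        sample.int(nrow(train$data), config$background_max))
      bg <- train$data[keep, , drop = FALSE]
    } else {
      bg <- train$data
    }
    rc <- cell_of_xy(grid, cleaned$records$x, cleaned$records$y)
    idx <- (rc[, "col"] - 1L) * grid$n_rows + rc[, "row"]
    pres <- data.frame(gdd = bio$current$gdd[idx],
                       tmin_abs = bio$current$tmin_abs[idx],
                       wbal = bio$current$wbal[idx])
    proj <- lapply(bio, predictors_at, mask = proj_mask)
    list(presence = pres, background = bg, train_all = train, proj = proj)
  })

  tuning <- stage("tune", {
    tune_settings(design$presence, design$background,
                  cells = design$train_all$data,
                  classes_candidates = config$classes_candidates,
                  rm_candidates = config$rm_candidates,
                  n_hinge_knots = config$n_hinge_knots)
  })

  fit <- stage("fit", {
    replicate_fit(design$presence, design$background,
                  newdata = design$proj$current$data,
                  classes = tuning$best$classes, rm = tuning$best$rm,
                  n_hinge_knots = config$n_hinge_knots,
                  n_replicates = config$n_replicates,
                  test_fraction = config$test_fraction,
                  master_seed = seeds$replicates)
  })

  evaln <- stage("evaluate", {
    jk <- jackknife_importance(design$presence, design$background,
                               classes = tuning$best$classes,
                               rm = tuning$best$rm,
                               n_hinge_knots = config$n_hinge_knots)
    query <- do.call(rbind, lapply(design$proj, function(p) p$data))
    ms <- mess(design$background, query)
    list(report = evaluation_report(fit$auc, jk$importance, ms),
         jackknife = jk, mess = ms)
  })

  projmaps <- stage("project", {
    maps <- lapply(design$proj, function(p) {
      preds <- vapply(fit$models, function(mdl) predict_logistic(mdl, p$data),
                      numeric(nrow(p$data)))
      values_to_layer(grid, p$idx, rowMeans(matrix(preds, nrow(p$data))))
    })
    maps
  })

  har <- stage("har", {
    har_report(projmaps$current,
               projmaps[setdiff(names(projmaps), "current")],
               region_mask = proj_mask,
               cell_area_km2 = config$cell_area_km2)
  })

  outputs <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_occurrences(occ$records, p("occurrences_raw.csv"))
    write_occurrences(cleaned$records, p("occurrences_clean.csv"))
    write_raster(sim$dem, grid, p("elevation.asc"))
    for (nm in names(bio)) {
      write_raster(bio[[nm]]$gdd, grid, p(sprintf("gdd_%s.asc", nm)))
    }
    for (nm in names(projmaps)) {
      write_raster(projmaps[[nm]], grid, p(sprintf("suitability_%s.asc", nm)))
    }
    jsonlite::write_json(cleaned$report, p("cleaning_report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(tuning$results, p("tuning.csv"), row.names = FALSE)
    utils::write.csv(data.frame(replicate = seq_along(fit$auc), auc = fit$auc),
                     p("auc.csv"), row.names = FALSE)
    utils::write.csv(har$table, p("har_table.csv"), row.names = FALSE)
    write_model(tuning$model, p("model.json"))
    export_lambdas(tuning$model, p("model_lambdas.txt"))
    outputs <- list.files(outdir, full.names = TRUE)
  }

  manifest <- list(
    config = unclass(config)[setdiff(names(config), c("nodata_mask", "truth"))],
    truth = unclass(config$truth),
    seeds = seeds,
    timings = as.list(timings),
    counts = cleaned$report,
    selected = tuning$best,
    outputs = if (length(outputs)) {
      stats::setNames(as.list(unname(tools::md5sum(outputs))), basename(outputs))
    } else list()
  )

  structure(list(grid = grid, truth_map = occ$truth_map,
                 records = occ$records, cleaning = cleaned$report,
                 cleaned_records = cleaned$records,
                 design = design,
                 tuning = tuning, fit = fit,
                 evaluation = evaln$report, jackknife = evaln$jackknife,
                 mess = evaln$mess,
                 suitability = projmaps, har = har,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  records: %d in, %d retained\n",
              x$cleaning$n_input, x$cleaning$n_retained))
  cat(sprintf("  settings: %s, rm = %g\n",
              x$tuning$best$classes, x$tuning$best$rm))
  cat(sprintf("  AUC median %.3f (%s)\n",
              x$evaluation$auc_median, x$evaluation$auc_class))
  imp <- x$evaluation$jackknife_importance
  cat(sprintf("  importance: %s\n",
              paste(sprintf("%s=%.3f", names(imp), imp), collapse = ", ")))
  print(x$har)
  invisible(x)
}
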