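rec_row <- function(x, y, elev = NA_real_) {
  data.frame(species = "sp", x = x, y = y, cited_elevation_m = elev)
}

test_that("drop_offgrid removes sea and out-of-extent records only", {
  mask <- matrix(FALSE, 10, 10)
  mask[1, 1] <- TRUE
  g <- grid_spec(10, 10, cell_size_km = 10, origin_x = 0, origin_y = 0,
                 nodata_mask = mask)
  recs <- rbind(
    rec_row(5, 95),     # row 1 col 1 -> nodata
    rec_row(-5, 50),    # outside extent
    rec_row(55, 55),    # valid
    rec_row(15, 95)     # row 1 col 2 -> valid
  )
  out <- drop_offgrid(recs, g)
  expect_equal(out$n_removed, 2)
  expect_equal(out$records$x, c(55, 15))

  k <- drop_offgrid(rbind(rec_row(55, 55), rec_row(25, 25), rec_row(75, 75)), g)
  expect_equal(nrow(k$records), 3)
  empty <- drop_offgrid(recs[0, ], g)
  expect_equal(nrow(empty$records), 0)
})

test_that("elevation filter uses a strict 100 m boundary and keeps missing elevations", {
  g <- grid_spec(5, 5, cell_size_km = 10, origin_x = 0, origin_y = 0)
  dem <- matrix(620, 5, 5)
  r1 <- elevation_filter(rec_row(25, 25, 500), dem, g)     # diff 120 > 100
  expect_equal(r1$n_removed, 1)
  dem2 <- matrix(600, 5, 5)
  r2 <- elevation_filter(rec_row(25, 25, 500), dem2, g)    # diff exactly 100
  expect_equal(r2$n_removed, 0)
  r3 <- elevation_filter(rbind(rec_row(25, 25), rec_row(35, 35)), dem, g)
  expect_equal(r3$n_removed, 0)
  # record on a nodata dem cell is removed and counted by this filter
  dem_na <- dem; dem_na[3, 3] <- NA
  r4 <- elevation_filter(rec_row(25, 25, 620), dem_na, g)
  expect_equal(r4$n_removed, 1)
})

test_that("dedup keeps the first record of each occupied cell", {
  g <- grid_spec(5, 5, cell_size_km = 10, origin_x = 0, origin_y = 0)
  recs <- rbind(rec_row(21, 21), rec_row(25, 25), rec_row(29, 29),
                rec_row(41, 41))
  out <- dedup_cells(recs, g)
  expect_equal(out$n_removed, 2)
  expect_equal(out$records$x[1], 21)  # first-in-input kept

  distinct <- rbind(rec_row(5, 5), rec_row(15, 15), rec_row(25, 25))
  expect_equal(dedup_cells(distinct, g)$n_removed, 0)

  set.seed(1)
  batch <- rec_row(runif(60, 0, 50), runif(60, 0, 50))
  rc <- cell_of_xy(g, batch$x, batch$y)
  n_cells <- length(unique((rc[, "row"] - 1) * 5 + rc[, "col"]))
  expect_equal(nrow(dedup_cells(batch, g)$records), n_cells)
})

test_that("cleaning report counts reconcile", {
  w <- make_world(3)
  tr <- true_suitability(w$bio, truth_params(linear = c(gdd = 2)))
  rec <- sample_occurrences(tr, w$grid, w$dem, 200, seed = 12,
                            error_rates = list(offgrid = 0.1,
                                               elev_mismatch = 0.1,
                                               duplicate = 0.1))
  rep <- clean_occurrences(rec, w$grid, w$dem)$report
  expect_equal(rep$n_input,
               rep$n_retained + rep$n_removed_offgrid +
                 rep$n_removed_elevation + rep$n_removed_duplicate)
})

test_that("growing degree days match closed forms and are monotone in warming", {
  g <- grid_spec(3, 3)
  mk <- function(v) lapply(1:12, function(m) matrix(v, 3, 3))
  expect_equal(growing_degree_days(mk(15))[1, 1], 10 * 365)
  expect_equal(growing_degree_days(mk(-2))[1, 1], 0)
  expect_true(all(growing_degree_days(mk(5)) == 0))

  one_warm <- mk(5)
  one_warm[[1]] <- matrix(6, 3, 3)      # January, 31 days, 1 degree above base
  expect_equal(growing_degree_days(one_warm)[2, 2], 31)

  expect_error(growing_degree_days(mk(10)[1:11]), "12")

  set.seed(4)
  tm <- lapply(1:12, function(m) matrix(rnorm(9, 8, 6), 3, 3))
  tm_warm <- lapply(tm, function(t) t + 1.5)
  expect_true(all(growing_degree_days(tm_warm) >= growing_degree_days(tm)))
})

test_that("absolute minimum temperature is the monthly minimum, order-invariant", {
  vals <- c(-3, 0, 5, 8, 12, 15, 18, 16, 11, 6, 1, -1)
  tmin <- lapply(vals, function(v) matrix(v, 2, 2))
  expect_equal(absolute_min_temperature(tmin)[1, 1], -3)
  expect_equal(absolute_min_temperature(lapply(1:12, function(m) matrix(4, 2, 2)))[1, 1], 4)
  set.seed(2)
  perm <- sample(12)
  expect_identical(absolute_min_temperature(tmin),
                   absolute_min_temperature(tmin[perm]))
})

test_that("water balance matches the Thornthwaite oracle and its limits", {
  g <- grid_spec(2, 2, origin_y = 40 * 111.32)  # ~40 degrees north
  lat <- latitude_layer(g)
  mk <- function(v) lapply(1:12, function(m) matrix(v, 2, 2))

  # all months at or below freezing: PET vanishes, wbal = annual precipitation
  frozen <- water_balance(mk(50), mk(-4), lat)
  expect_equal(frozen[1, 1], 600)

  # warm and bone dry: wbal is strictly negative
  dry <- water_balance(mk(0), mk(18), lat)
  expect_true(all(dry < 0))

  # single-site worked case against the independent oracle, including the
  # uniform 12 h / 30-day convention
  days30 <- rep(30, 12)
  tm <- rep(10, 12); pr <- rep(40, 12)
  g_eq <- grid_spec(2, 2, origin_y = 0)   # equator: ~12 h day length
  lat_eq <- latitude_layer(g_eq)
  got <- water_balance(mk(40), mk(10), lat_eq, days_per_month = days30)[1, 1]
  dl <- sapply(ragrisk:::month_day_length(lat_eq, days30), function(L) L[1, 1])
  want <- thornthwaite_wbal_oracle(tm, pr, dl, days30)
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(sum((pmax(0, tm) / 5)^1.514), 12 * 2^1.514)

  # seasonal random site vs oracle
  set.seed(8)
  tm_r <- rnorm(12, 9, 7); pr_r <- runif(12, 10, 120)
  mts <- lapply(tm_r, function(v) matrix(v, 2, 2))
  mps <- lapply(pr_r, function(v) matrix(v, 2, 2))
  got_r <- water_balance(mps, mts, lat)[1, 1]
  dl_r <- sapply(ragrisk:::month_day_length(lat), function(L) L[1, 1])
  expect_equal(got_r, thornthwaite_wbal_oracle(tm_r, pr_r, dl_r, DAYS_PER_MONTH),
               tolerance = 1e-10)
})

test_that("derived predictors on synthetic data span plausible ranges", {
  w <- make_world(10, 30, 40)
  expect_true(all(w$bio$gdd >= 0))
  expect_true(all(w$bio$tmin_abs <= Reduce(pmin, w$climate$tmin)))
  expect_true(all(is.finite(w$bio$wbal)))
  # the cold band where peak suitability is expected is reachable
  expect_lt(min(w$bio$tmin_abs), 10)
  expect_gt(max(w$bio$tmin_abs), -30)
})
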