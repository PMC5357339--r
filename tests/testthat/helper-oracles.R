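# Independent oracles and small fixtures shared across test files.
# Each oracle is a direct-from-definition implementation, deliberately
# written without reference to the package internals it checks.

# exhaustive pairwise AUC: #(p > b) + 0.5 #(p = b) over all pairs
auc_bruteforce <- function(p, b) {
  tot <- 0
  for (pi in p) for (bi in b) {
    tot <- tot + (pi > bi) + 0.5 * (pi == bi)
  }
  tot / (length(p) * length(b))
}

# Thornthwaite PET + annual water balance for a single site, straight from
# the textbook formulation
thornthwaite_wbal_oracle <- function(tmean12, precip12, day_len12, ndays12) {
  tpos <- pmax(0, tmean12)
  I <- sum((tpos / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  pet <- numeric(12)
  for (m in 1:12) {
    pet[m] <- if (tmean12[m] <= 0 || I == 0) 0 else {
      16 * (day_len12[m] / 12) * (ndays12[m] / 30) * (10 * tpos[m] / I)^a
    }
  }
  sum(precip12 - pet)
}

# MESS similarity for one query point and one predictor, from the published
# piecewise definition (ties at the query value counted half)
mess_oracle_point <- function(ref, p) {
  n <- length(ref)
  f <- 100 * (sum(ref < p) + 0.5 * sum(ref == p)) / n
  mn <- min(ref); mx <- max(ref)
  if (mx == mn) return(if (p == mn) 0 else -Inf)
  if (f == 0) (p - mn) / (mx - mn) * 100
  else if (f <= 50) 2 * f
  else if (f < 100) 2 * (100 - f)
  else (mx - p) / (mx - mn) * 100
}

mess_oracle <- function(ref_df, query_df) {
  apply(query_df, 1, function(q) {
    min(vapply(names(ref_df), function(v) {
      mess_oracle_point(ref_df[[v]], as.numeric(q[[v]]))
    }, numeric(1)))
  })
}

# brute-force maximizer of the penalized maxent likelihood for 1 or 2
# features: iteratively refined grid search over lambda
maxent_gridsearch_oracle <- function(Xp, Xb, beta, lo = -20, hi = 20) {
  J <- ncol(Xb)
  fbar <- colMeans(Xp)
  obj <- function(l) {
    s <- drop(Xb %*% l)
    mx <- max(s)
    mx + log(sum(exp(s - mx))) - sum(fbar * l) + sum(beta * abs(l))
  }
  center <- rep(0, J)
  width <- hi - lo
  for (round in 1:8) {
    grids <- lapply(seq_len(J), function(j) {
      seq(center[j] - width / 2, center[j] + width / 2, length.out = 21)
    })
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1, obj)
    center <- cand[which.min(vals), ]
    width <- width / 5
  }
  center
}

# a small self-consistent synthetic world used by several test files
make_world <- function(seed = 11, n_rows = 24, n_cols = 36, mask = NULL) {
  g <- grid_spec(n_rows, n_cols, origin_y = 3800, nodata_mask = mask)
  climate <- generate_climate(g, seed)
  dem <- generate_elevation(g, seed)
  bio <- derive_bioclim(climate)
  list(grid = g, climate = climate, dem = dem, bio = bio)
}

# predictor data.frame over the valid cells of a world
world_background <- function(world) {
  ok <- which(!is.na(world$bio$gdd))
  data.frame(gdd = world$bio$gdd[ok],
             tmin_abs = world$bio$tmin_abs[ok],
             wbal = world$bio$wbal[ok])
}

# presences drawn from a truth surface, cleaned, and turned into a
# predictor data.frame (plus the raw pieces for cleaning tests)
world_presences <- function(world, params, n = 200, seed = 5,
                            error_rates = list(offgrid = 0,
                                               elev_mismatch = 0,
                                               duplicate = 0)) {
  tr <- true_suitability(world$bio, params)
  rec <- sample_occurrences(tr, world$grid, world$dem, n, seed,
                            error_rates = error_rates)
  cln <- clean_occurrences(rec, world$grid, world$dem)
  rc <- cell_of_xy(world$grid, cln$records$x, cln$records$y)
  idx <- (rc[, "col"] - 1L) * world$grid$n_rows + rc[, "row"]
  list(truth = tr, records = rec, cleaned = cln,
       data = data.frame(gdd = world$bio$gdd[idx],
                         tmin_abs = world$bio$tmin_abs[idx],
                         wbal = world$bio$wbal[idx]))
}
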