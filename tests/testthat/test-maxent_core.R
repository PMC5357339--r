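set.seed(100)
bg2 <- data.frame(a = runif(40), b = runif(40, -1, 1))
pres2 <- data.frame(a = runif(12, 0.4, 1), b = runif(12, 0, 1))

test_that("feature expansion has the contracted counts and scaling endpoints", {
  bg3 <- data.frame(x = runif(30), y = runif(30), z = runif(30))
  fl <- build_features(bg3, classes = "L")
  expect_length(fl$features, 3)
  flqp <- build_features(bg3, classes = "LQP")
  expect_length(flqp$features, 9)   # 3 L + 3 Q + 3 distinct pairs

  X <- feature_matrix(fl, bg3)
  expect_true(all(X >= 0 & X <= 1))
  at_min <- data.frame(x = min(bg3$x), y = min(bg3$y), z = min(bg3$z))
  at_max <- data.frame(x = max(bg3$x), y = max(bg3$y), z = max(bg3$z))
  expect_equal(unname(feature_matrix(fl, at_min)[1, "L_x"]), 0)
  expect_equal(unname(feature_matrix(fl, at_max)[1, "L_x"]), 1)

  fh <- build_features(bg3, classes = "H", n_hinge_knots = 7)
  Xh <- feature_matrix(fh, bg3)
  expect_true(all(Xh >= 0 & Xh <= 1))
  knots <- vapply(fh$features, function(f) f$knot, numeric(1))
  for (f in fh$features) {
    expect_gt(f$knot, fh$ranges[[f$var]][1])
    expect_lt(f$knot, fh$ranges[[f$var]][2])
  }

  bg_const <- data.frame(x = runif(20), c = rep(3, 20))
  expect_warning(fc <- build_features(bg_const, classes = "L"), "constant")
  expect_length(fc$features, 1)
})

test_that("extreme regularization collapses to the uniform model", {
  m <- fit_maxent(pres2, bg2, rm = 1e6, classes = "LQ")
  expect_true(all(m$lambda == 0))
  expect_equal(unname(predict_raw(m, bg2)), rep(1 / nrow(bg2), nrow(bg2)))
  expect_equal(m$H, log(nrow(bg2)))
  expect_equal(unique(round(predict_logistic(m, bg2), 12)), 0.5)
})

test_that("unpenalized fit satisfies moment matching and normalization", {
  m <- fit_maxent(pres2, bg2, rm = 1e-7, classes = "L", tol = 1e-10)
  Xb <- feature_matrix(m$featset, bg2)
  Xp <- feature_matrix(m$featset, pres2)
  p <- predict_raw(m, bg2)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_equal(drop(crossprod(Xb, p)), colMeans(Xp), tolerance = 1e-3)
})

test_that("fitted coefficients match the brute-force grid-search oracle", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    bg <- data.frame(a = runif(25), b = runif(25))
    pr <- data.frame(a = runif(8, 0.3, 1), b = runif(8, 0, 0.7))
    m <- fit_maxent(pr, bg, rm = 1, classes = "L", tol = 1e-12)
    Xb <- feature_matrix(m$featset, bg)
    Xp <- feature_matrix(m$featset, pr)
    lam_star <- maxent_gridsearch_oracle(Xp, Xb, m$beta)
    expect_equal(unname(m$lambda), unname(lam_star), tolerance = 1e-3)
  }
})

test_that("the l1 norm of the coefficients shrinks as rm grows", {
  norms <- vapply(c(0.5, 1, 2, 4), function(r) {
    sum(abs(fit_maxent(pres2, bg2, rm = r, classes = "LQ")$lambda))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("raw prediction is monotone under a single positive linear feature", {
  set.seed(7)
  bg <- data.frame(a = runif(60))
  pr <- data.frame(a = runif(15, 0.6, 1))
  m <- fit_maxent(pr, bg, rm = 0.5, classes = "L")
  expect_gt(m$lambda[["L_a"]], 0)
  grid <- data.frame(a = sort(runif(50)))
  expect_true(all(diff(predict_raw(m, grid)) >= 0))
})

test_that("logistic output follows the entropy transform", {
  m <- fit_maxent(pres2, bg2, rm = 1, classes = "LQ")
  idx <- c(2, 9, 17, 25, 33)
  r <- predict_raw(m, bg2[idx, ])
  expect_equal(predict_logistic(m, bg2[idx, ]),
               exp(m$H) * r / (1 + exp(m$H) * r))
  tau <- 0.3
  v <- exp(m$H) * r * tau / (1 - tau)
  expect_equal(predict_logistic(m, bg2[idx, ], tau = tau), v / (1 + v))
  r_all <- predict_raw(m, bg2)
  expect_true(all(diff(predict_logistic(m, bg2[order(r_all), ])) >= -1e-12))
})

test_that("AICc matches closed forms and hand arithmetic", {
  # k = 0: uniform raw over C cells
  m0 <- fit_maxent(pres2, bg2, rm = 1e6, classes = "L")
  C <- nrow(bg2); m_n <- nrow(pres2)
  sc <- aicc(m0, pres2, bg2)
  expect_equal(sc$k, 0)
  expect_equal(sc$lnL, m_n * log(1 / C))
  expect_equal(sc$aicc, -2 * m_n * log(1 / C))

  # worked tiny case: C = 10 cells, m = 5 presences, fitted k from the model
  set.seed(42)
  cells <- data.frame(a = seq(0, 1, length.out = 10))
  pr <- data.frame(a = c(0.55, 0.7, 0.8, 0.9, 1.0))
  mfit <- fit_maxent(pr, cells, rm = 0.2, classes = "LQ")
  sc2 <- aicc(mfit, pr, cells)
  raw_cells <- predict_raw(mfit, cells)
  raw_std_pres <- predict_raw(mfit, pr) / sum(raw_cells)
  k <- sum(mfit$lambda != 0)
  lnL_hand <- sum(log(raw_std_pres))
  expect_equal(sc2$lnL, lnL_hand)
  if (k < 4) {
    expect_equal(sc2$aicc, 2 * k - 2 * lnL_hand + 2 * k * (k + 1) / (5 - k - 1))
  } else {
    expect_equal(sc2$aicc, Inf)
  }

  # one extra nonzero coefficient at identical likelihood raises AICc
  aicc_formula <- function(k, lnL, m) 2 * k - 2 * lnL + 2 * k * (k + 1) / (m - k - 1)
  expect_gt(aicc_formula(3, -20, 12), aicc_formula(2, -20, 12))
})

test_that("tuning selects the AICc argmin with deterministic tie-breaks", {
  tr <- tune_settings(pres2, bg2, classes_candidates = c("L"),
                      rm_candidates = 1)
  expect_equal(tr$best, list(classes = "L", rm = 1))

  tr2 <- tune_settings(pres2, bg2, classes_candidates = c("L", "LQ"),
                       rm_candidates = c(0.5, 2))
  finite <- is.finite(tr2$results$aicc)
  best_aicc <- tr2$results$aicc[tr2$results$classes == tr2$best$classes &
                                  tr2$results$rm == tr2$best$rm]
  expect_true(all(best_aicc <= tr2$results$aicc[finite]))
})

test_that("replicate fitting is deterministic and the mean map is bounded by replicates", {
  w <- make_world(5, 16, 20)
  bg <- world_background(w)
  pr <- world_presences(w, truth_params(linear = c(gdd = 2.5)), n = 120,
                        seed = 3)$data
  r1 <- replicate_fit(pr, bg, newdata = bg, classes = "LQ", rm = 1,
                      n_replicates = 3, master_seed = 99)
  r2 <- replicate_fit(pr, bg, newdata = bg, classes = "LQ", rm = 1,
                      n_replicates = 3, master_seed = 99)
  expect_identical(r1$mean_map, r2$mean_map)
  expect_identical(r1$auc, r2$auc)
  expect_true(all(r1$mean_map <= apply(r1$replicate_maps, 1, max) + 1e-12))
  expect_true(all(r1$mean_map >= apply(r1$replicate_maps, 1, min) - 1e-12))

  single <- replicate_fit(pr, bg, newdata = bg, classes = "LQ", rm = 1,
                          n_replicates = 1, master_seed = 5)
  expect_equal(single$mean_map, single$replicate_maps[, 1])
  expect_error(replicate_fit(pr[1:4, ], bg, newdata = bg, n_replicates = 2),
               "too few")
})

test_that("response curves are consistent with direct prediction", {
  w <- make_world(5, 16, 20)
  bg <- world_background(w)
  pr <- world_presences(w, truth_params(linear = c(gdd = 3)), n = 150,
                        seed = 8)$data
  m <- fit_maxent(pr, bg, rm = 1, classes = "LQ")
  rc <- response_curve(m, "gdd", n_points = 25)
  expect_equal(nrow(rc), 25)
  ends <- data.frame(gdd = range(bg$gdd),
                     tmin_abs = rep(mean(bg$tmin_abs), 2),
                     wbal = rep(mean(bg$wbal), 2))
  expect_equal(rc$suitability[c(1, 25)], predict_logistic(m, ends))
  expect_error(response_curve(m, "nope"), "unknown predictor")

  # all-zero model: flat curve
  m0 <- fit_maxent(pr, bg, rm = 1e6, classes = "LQ")
  rc0 <- response_curve(m0, "gdd", n_points = 10)
  expect_equal(diff(range(rc0$suitability)), 0)
})

test_that("model serialization writes valid JSON and a lambdas table", {
  m <- fit_maxent(pres2, bg2, rm = 1, classes = "LQ")
  jf <- tempfile(fileext = ".json")
  lf <- tempfile(fileext = ".txt")
  write_model(m, jf)
  obj <- jsonlite::read_json(jf)
  expect_equal(unlist(obj$lambda), m$lambda, tolerance = 1e-12)
  expect_equal(obj$H, m$H, tolerance = 1e-12)
  export_lambdas(m, lf)
  tab <- utils::read.delim(lf)
  expect_equal(tab$lambda, unname(m$lambda))
})
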