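#' Fit a maximum-entropy presence-only model
#'
#' Finds the Gibbs distribution over the background that maximizes the
#' l1-penalized presence log-likelihood
#' \deqn{\frac1m \sum_i \sum_j \lambda_j f_j(x_i) - \ln Z(\lambda)
#'       - \sum_j \beta_j |\lambda_j|,}
#' where \eqn{Z(\lambda) = \sum_{x \in \mathrm{bg}} \exp(\sum_j \lambda_j
#' f_j(x))}. Per-feature penalties are \eqn{\beta_j = \mathrm{rm} \cdot
#' c_{\mathrm{class}} \cdot \sigma_j / \sqrt m} with \eqn{\sigma_j} the
#' presence-sample standard deviation of feature j and class constants 1.0
#' for linear/quadratic/product and 0.5 for hinge features (floored at 1e-8
#' so the objective stays coercive for features constant across presences).
#'
#' The convex problem is solved by proximal gradient descent (FISTA with
#' backtracking line search and function-value restart), iterated until the
#' relative objective change falls below `tol`; hitting the iteration cap
#' without converging is an error carrying the last objective value.
#'
#' @param presence data.frame of predictor values at presence points (m >= 5
#'   rows).
#' @param background data.frame of predictor values at background points
#'   (N >= m rows); also defines feature scaling when `featset` is NULL.
#' @param rm regularization multiplier (> 0).
#' @param classes feature classes, e.g. `"LQH"` (used when `featset` is NULL).
#' @param n_hinge_knots hinge knots per predictor (used when `featset` is
#'   NULL).
#' @param featset optional pre-built [build_features()] object.
#' @param max_iter iteration cap (default 10000).
#' @param tol relative objective tolerance (default 1e-6).
#' @return object of class `maxent_model`: feature set, coefficients
#'   `lambda`, penalties `beta`, `rm`, log-normalizer `lnZ`, entropy `H` of
#'   the fitted background distribution, the background data, and fit
#'   diagnostics.
#' @export
fit_maxent <- function(presence, background, rm = 1, classes = "LQH",
                       n_hinge_knots = 50, featset = NULL,
                       max_iter = 10000, tol = 1e-6) {
  m <- nrow(presence)
  if (m < 5) stop("need at least 5 presence points")
  if (nrow(background) < m) stop("background must have at least as many points as presences")
  if (rm <= 0) stop("rm must be > 0")
  if (is.null(featset)) {
    featset <- build_features(background, classes = classes,
                              n_hinge_knots = n_hinge_knots)
  }
  Xp <- feature_matrix(featset, presence)
  Xb <- feature_matrix(featset, background)
  if (any(!is.finite(Xp)) || any(!is.finite(Xb))) {
    stop("non-finite feature values")
  }
  cclass <- c(L = 1, Q = 1, P = 1, H = 0.5)[feature_classes(featset)]
  sigma <- apply(Xp, 2, stats::sd)
  beta <- pmax(rm * cclass * sigma / sqrt(m), 1e-8)

  fbar <- colMeans(Xp)
  smooth_obj <- function(lambda) {
    s <- drop(Xb %*% lambda)
    logsumexp(s) - sum(fbar * lambda)
  }
  smooth_grad <- function(lambda) {
    s <- drop(Xb %*% lambda)
    p <- exp(s - logsumexp(s))
    drop(crossprod(Xb, p)) - fbar
  }
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  full_obj <- function(lambda) smooth_obj(lambda) + sum(beta * abs(lambda))

  # backtracked proximal step from `from`: guarantees the majorization
  # inequality, hence F(z) <= F(from) when from == y
  prox_step <- function(from, step) {
    gy <- smooth_obj(from)
    grad <- smooth_grad(from)
    repeat {
      z <- soft(from - step * grad, step * beta)
      dz <- z - from
      gz <- smooth_obj(z)
      if (gz <= gy + sum(grad * dz) + sum(dz^2) / (2 * step) + 1e-12 ||
          step < 1e-14) {
        return(list(z = z, step = step, F = gz + sum(beta * abs(z))))
      }
      step <- step / 2
    }
  }

  J <- ncol(Xb)
  lambda <- numeric(J)
  lambda_prev <- lambda
  yv <- lambda
  tk <- 1
  step <- 1
  F_prev <- full_obj(lambda)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    ps <- prox_step(yv, step)
    step <- ps$step
    if (ps$F > F_prev) {
      # accelerated step overshot: restart momentum with a plain (monotone)
      # proximal step from the current iterate
      ps <- prox_step(lambda, step)
      step <- ps$step
      tk <- 1
    }
    z <- ps$z
    F_new <- ps$F
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yv <- z + ((tk - 1) / t_next) * (z - lambda)
    tk <- t_next
    lambda_prev <- lambda
    lambda <- z
    if (abs(F_prev - F_new) <= tol * max(1, abs(F_prev))) {
      F_prev <- F_new
      converged <- TRUE
      break
    }
    F_prev <- F_new
    step <- min(step * 2, 1e6)   # allow the step to grow back
  }
  if (!converged) {
    stop(sprintf("maxent solver did not converge in %d iterations (objective %.8g)",
                 max_iter, F_prev))
  }

  s_b <- drop(Xb %*% lambda)
  lnZ <- logsumexp(s_b)
  p_b <- exp(s_b - lnZ)
  H <- -sum(p_b * log(pmax(p_b, .Machine$double.xmin)))

  structure(list(featset = featset, lambda = stats::setNames(lambda, colnames(Xb)),
                 beta = beta, rm = rm,
                 lnZ = lnZ, Z = exp(lnZ), H = H,
                 background = background,
                 n_presence = m, n_background = nrow(background),
                 objective = F_prev, n_iter = it, converged = converged),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d features (%d nonzero), rm = %g, H = %.4f, %d iter\n",
    length(x$lambda), sum(x$lambda != 0), x$rm, x$H, x$n_iter))
  invisible(x)
}

#' Raw (relative occurrence rate) prediction
#'
#' `raw(x) = exp(sum_j lambda_j f_j(x)) / Z`; over the model's own background
#' the raw values sum to 1. Predictors outside the training range are clamped
#' into it by the feature transforms.
#'
#' @param model a [fit_maxent()] result.
#' @param data data.frame of predictor values.
#' @return numeric vector of raw values.
#' @export
predict_raw <- function(model, data) {
  X <- feature_matrix(model$featset, data)
  exp(drop(X %*% model$lambda) - model$lnZ)
}

#' Logistic suitability prediction
#'
#' The bounded suitability transform
#' `l(x) = e^H raw(x) tau/(1-tau) / (1 + e^H raw(x) tau/(1-tau))` using the
#' entropy H of the fitted background distribution; with the default
#' prevalence `tau = 0.5` this reduces to `e^H raw / (1 + e^H raw)`, so a
#' featureless (uniform) model scores 0.5 everywhere.
#'
#' @inheritParams predict_raw
#' @param tau assumed prevalence in (0,1), default 0.5.
#' @return numeric vector of suitabilities in (0,1).
#' @export
predict_logistic <- function(model, data, tau = 0.5) {
  r <- predict_raw(model, data)
  v <- exp(model$H) * r * tau / (1 - tau)
  v / (1 + v)
}

#' Sample-size-corrected AIC for a fitted model
#'
#' Standardizes the raw prediction over all cells of the modelling extent to
#' sum to 1, evaluates the presence log-likelihood under that distribution,
#' and applies the small-sample correction with k = number of nonzero
#' coefficients: `AICc = 2k - 2 lnL + 2k(k+1)/(m-k-1)`. Models with
#' `k >= m - 1` are invalid and score `Inf`.
#'
#' @param model a [fit_maxent()] result.
#' @param presence data.frame of predictor values at the m presence points.
#' @param cells data.frame of predictor values for all cells of the extent.
#' @return list with `aicc`, `k`, `lnL`.
#' @export
aicc <- function(model, presence, cells) {
  k <- sum(model$lambda != 0)
  m <- nrow(presence)
  raw_cells <- predict_raw(model, cells)
  raw_pres <- predict_raw(model, presence)
  lnL <- sum(log(raw_pres / sum(raw_cells)))
  if (k >= m - 1) {
    return(list(aicc = Inf, k = k, lnL = lnL))
  }
  list(aicc = 2 * k - 2 * lnL + 2 * k * (k + 1) / (m - k - 1), k = k, lnL = lnL)
}

#' Tune feature classes and regularization by AICc
#'
#' Fits every combination of candidate feature classes and regularization
#' multipliers on the full presence set and scores each with [aicc()]; the
#' minimum-AICc candidate wins, with deterministic tie-breaking by fewer
#' nonzero coefficients, then lower rm, then candidate order.
#'
#' @param presence,background data.frames of predictor values.
#' @param cells data.frame of all-cell predictor values for the AICc
#'   standardization (defaults to `background`).
#' @param classes_candidates character vector of feature-class strings.
#' @param rm_candidates numeric vector of regularization multipliers.
#' @param n_hinge_knots hinge knots per predictor.
#' @param ... passed to [fit_maxent()].
#' @return object of class `tuning_result`: `results` data.frame (classes,
#'   rm, k, lnL, aicc per candidate), `best` (classes, rm), and the selected
#'   fitted `model`.
#' @export
tune_settings <- function(presence, background, cells = background,
                          classes_candidates = c("L", "LQ", "LQH", "LQP", "LQPH"),
                          rm_candidates = c(0.5, 1, 2, 3, 4),
                          n_hinge_knots = 50, ...) {
  cand <- expand.grid(classes = classes_candidates, rm = rm_candidates,
                      stringsAsFactors = FALSE)
  cand <- cand[order(match(cand$classes, classes_candidates), cand$rm), ]
  rows <- list()
  models <- list()
  for (i in seq_len(nrow(cand))) {
    fit <- tryCatch(
      fit_maxent(presence, background, rm = cand$rm[i],
                 classes = cand$classes[i], n_hinge_knots = n_hinge_knots, ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[i]] <- data.frame(classes = cand$classes[i], rm = cand$rm[i],
                              k = NA_integer_, lnL = NA_real_, aicc = Inf)
      next
    }
    sc <- aicc(fit, presence, cells)
    rows[[i]] <- data.frame(classes = cand$classes[i], rm = cand$rm[i],
                            k = sc$k, lnL = sc$lnL, aicc = sc$aicc)
    models[[i]] <- fit
  }
  results <- do.call(rbind, rows)
  if (all(!is.finite(results$aicc))) stop("no candidate produced a finite AICc")
  ord <- order(results$aicc, results$k, results$rm, seq_len(nrow(results)))
  best_i <- ord[1]
  structure(list(results = results,
                 best = list(classes = results$classes[best_i],
                             rm = results$rm[best_i]),
                 model = models[[best_i]]),
            class = "tuning_result")
}

#' Replicate fitting with held-out AUC and an averaged suitability map
#'
#' Repeats a seeded random 75/25 presence split `n_replicates` times: fits on
#' the training presences, predicts logistic suitability for `newdata` (all
#' cells of the mapping extent), and scores the held-out presences against
#' the background by [auc()]. The reported map is the cellwise mean over
#' replicates.
#'
#' @param presence,background data.frames of predictor values.
#' @param newdata data.frame of predictor values for the cells to map.
#' @param classes,rm,n_hinge_knots model settings (e.g. from
#'   [tune_settings()]).
#' @param n_replicates number of replicates (default 15).
#' @param test_fraction held-out presence fraction (default 0.25).
#' @param master_seed integer; replicate seeds are derived from it, so runs
#'   with the same master seed are identical.
#' @param ... passed to [fit_maxent()].
#' @return list: `mean_map` (vector over `newdata` rows), `replicate_maps`
#'   (matrix, one column per replicate), `auc` (per-replicate vector),
#'   `auc_median`, `auc_sd`, `models` (list of fitted models).
#' @export
replicate_fit <- function(presence, background, newdata,
                          classes = "LQH", rm = 1, n_hinge_knots = 50,
                          n_replicates = 15, test_fraction = 0.25,
                          master_seed = 1, ...) {
  m <- nrow(presence)
  n_train <- m - floor(m * test_fraction)
  if (n_train < 5) stop("too few presences for the requested split")
  featset <- build_features(background, classes = classes,
                            n_hinge_knots = n_hinge_knots)
  maps <- matrix(NA_real_, nrow(newdata), n_replicates)
  aucs <- numeric(n_replicates)
  models <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    idx <- with_seed(derive_seed(master_seed, 1000 + r),
                     sample.int(m, n_train))
    fit <- fit_maxent(presence[idx, , drop = FALSE], background,
                      rm = rm, featset = featset, ...)
    models[[r]] <- fit
    maps[, r] <- predict_logistic(fit, newdata)
    test <- presence[-idx, , drop = FALSE]
    aucs[r] <- if (nrow(test) > 0) {
      auc(predict_logistic(fit, test), predict_logistic(fit, background))
    } else NA_real_
  }
  list(mean_map = rowMeans(maps), replicate_maps = maps,
       auc = aucs,
       auc_median = stats::median(aucs, na.rm = TRUE),
       auc_sd = stats::sd(aucs),
       models = models)
}

#' Response curve of a fitted model along one predictor
#'
#' Sweeps the named predictor across its background range while holding the
#' other predictors at their background means, and evaluates the logistic
#' output along the sweep.
#'
#' @param model a [fit_maxent()] result.
#' @param predictor predictor name.
#' @param n_points number of sweep points (default 100).
#' @return data.frame with columns `value` and `suitability`.
#' @export
response_curve <- function(model, predictor, n_points = 100) {
  fs <- model$featset
  if (!predictor %in% fs$vars) stop("unknown predictor: ", predictor)
  r <- fs$ranges[[predictor]]
  sweep_vals <- seq(r[1], r[2], length.out = n_points)
  data <- as.data.frame(lapply(fs$means, rep, n_points))
  data[[predictor]] <- sweep_vals
  data.frame(value = sweep_vals,
             suitability = predict_logistic(model, data))
}

#' Serialize a fitted model
#'
#' `write_model` stores the feature definitions, coefficients, penalties and
#' normalization constants as JSON; `export_lambdas` writes a plain-text
#' coefficient table (feature id, lambda, beta) for human inspection.
#'
#' @param model a [fit_maxent()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    features = lapply(model$featset$features, function(f) f[!vapply(f, is.null, TRUE)]),
    vars = model$featset$vars,
    ranges = model$featset$ranges,
    means = as.list(model$featset$means),
    lambda = as.list(model$lambda),
    beta = as.list(stats::setNames(model$beta, names(model$lambda))),
    rm = model$rm, lnZ = model$lnZ, H = model$H,
    n_presence = model$n_presence, n_background = model$n_background
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
export_lambdas <- function(model, path) {
  df <- data.frame(feature = names(model$lambda),
                   lambda = unname(model$lambda),
                   beta = unname(model$beta))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
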