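#' Presence/background AUC
#'
#' Rank-based (Mann--Whitney) area under the ROC curve treating background
#' points as pseudo-absences: the probability that a random presence outscores
#' a random background point, with ties counted half. Computed via ranks but
#' contractually equal to the exhaustive pairwise count
#' `(#(p > b) + 0.5 #(p = b)) / (n_p n_b)`.
#'
#' @param presence_scores,background_scores nonempty numeric vectors.
#' @return AUC in \[0,1\].
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("score vectors must be nonempty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Discrimination-ability label for an AUC value
#'
#' Conventional bands: > 0.9 "very good", > 0.8 "good", > 0.7 "useful",
#' otherwise "none" (all strict).
#'
#' @param value AUC in \[0,1\].
#' @return one of `"very good"`, `"good"`, `"useful"`, `"none"`.
#' @export
classify_auc <- function(value) {
  if (value < 0 || value > 1) stop("AUC must lie in [0,1]")
  if (value > 0.9) "very good"
  else if (value > 0.8) "good"
  else if (value > 0.7) "useful"
  else "none"
}

# training gain of a model: mean presence log-improvement over the uniform
# background distribution, (1/m) sum ln(N raw(x_i))
training_gain <- function(model, presence) {
  raw <- predict_raw(model, presence)
  mean(log(pmax(raw, .Machine$double.xmin) * model$n_background))
}

#' Jackknife variable importance
#'
#' Fits, for each predictor, a model using only that predictor (its linear,
#' quadratic and hinge features; products need two predictors) and records its
#' training gain relative to the uniform distribution. Importances are the
#' only-variable gains floored at zero and normalized to sum to 1 — the
#' convention under which a table of per-variable explanatory powers sums to
#' 1.000 per species. Without-variable and all-variable gains are reported
#' alongside for the classic jackknife bar chart.
#'
#' @param presence,background data.frames of predictor values (>= 2
#'   predictors).
#' @param classes,rm,n_hinge_knots model settings for the jackknife fits.
#' @param ... passed to [fit_maxent()].
#' @return list: `importance` (named, sums to 1), `gains` data.frame
#'   (variable, gain_only, gain_without), `gain_all`.
#' @export
jackknife_importance <- function(presence, background, classes = "LQH",
                                 rm = 1, n_hinge_knots = 50, ...) {
  vars <- names(background)
  if (length(vars) < 2) stop("need at least 2 predictors")
  single_classes <- gsub("P", "", classes)
  gain_only <- gain_without <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    fit_v <- fit_maxent(presence[, v, drop = FALSE],
                        background[, v, drop = FALSE],
                        rm = rm, classes = single_classes,
                        n_hinge_knots = n_hinge_knots, ...)
    gain_only[v] <- training_gain(fit_v, presence[, v, drop = FALSE])
    rest <- setdiff(vars, v)
    fit_wo <- fit_maxent(presence[, rest, drop = FALSE],
                         background[, rest, drop = FALSE],
                         rm = rm, classes = classes,
                         n_hinge_knots = n_hinge_knots, ...)
    gain_without[v] <- training_gain(fit_wo, presence[, rest, drop = FALSE])
  }
  fit_all <- fit_maxent(presence, background, rm = rm, classes = classes,
                        n_hinge_knots = n_hinge_knots, ...)
  gain_all <- training_gain(fit_all, presence)
  g <- pmax(gain_only, 0)
  if (sum(g) == 0) {
    warning("all only-variable gains <= 0; reporting uniform importances")
    imp <- stats::setNames(rep(1 / length(vars), length(vars)), vars)
  } else {
    imp <- g / sum(g)
  }
  list(importance = imp,
       gains = data.frame(variable = vars,
                          gain_only = unname(gain_only),
                          gain_without = unname(gain_without)),
       gain_all = gain_all)
}

# similarity of query values p to a reference sample (one predictor);
# f = percent of reference values below p, ties counted half
mess_similarity <- function(reference, p) {
  n <- length(reference)
  lo <- min(reference); hi <- max(reference)
  f <- 100 * (vapply(p, function(q) sum(reference < q), numeric(1)) +
                0.5 * vapply(p, function(q) sum(reference == q), numeric(1))) / n
  s <- numeric(length(p))
  if (hi == lo) {
    s <- ifelse(p == lo, 0, -Inf)
    return(s)
  }
  s[f == 0] <- (p[f == 0] - lo) / (hi - lo) * 100
  sel <- f > 0 & f <= 50
  s[sel] <- 2 * f[sel]
  sel <- f > 50 & f < 100
  s[sel] <- 2 * (100 - f[sel])
  s[f == 100] <- (hi - p[f == 100]) / (hi - lo) * 100
  s
}

#' Multivariate environmental similarity surface (MESS)
#'
#' Compares query (projection-region) predictor values with the reference
#' sample (the training background). Per predictor, similarity is
#' percent-like and negative exactly where the query value falls outside the
#' reference range; the MESS value of a point is the minimum similarity over
#' predictors, and `most_dissimilar` names the predictor attaining it.
#'
#' @param reference data.frame of reference predictor values (>= 1 row).
#' @param query data.frame of query predictor values (same columns).
#' @return list: `mess` (vector over query rows), `similarity` (matrix, one
#'   column per predictor), `most_dissimilar` (character vector),
#'   `fraction_nonneg` (share of query points with MESS >= 0).
#' @export
mess <- function(reference, query) {
  vars <- names(reference)
  if (nrow(reference) < 1) stop("reference must have at least one point")
  if (!all(vars %in% names(query))) stop("query lacks reference predictors")
  S <- vapply(vars, function(v) mess_similarity(reference[[v]], query[[v]]),
              numeric(nrow(query)))
  S <- matrix(S, nrow = nrow(query),
              dimnames = list(NULL, vars))
  mn <- apply(S, 1, min)
  list(mess = mn,
       similarity = S,
       most_dissimilar = vars[apply(S, 1, which.min)],
       fraction_nonneg = mean(mn >= 0))
}

#' Bundle an evaluation report
#'
#' @param auc_values per-replicate AUC vector.
#' @param importance jackknife importances (named, summing to 1).
#' @param mess_result a [mess()] result (optional).
#' @return list of class `evaluation_report` with AUC summary statistics,
#'   the AUC discrimination label of the median, importances and MESS
#'   summary.
#' @export
evaluation_report <- function(auc_values, importance, mess_result = NULL) {
  med <- stats::median(auc_values, na.rm = TRUE)
  structure(list(
    auc_per_replicate = auc_values,
    auc_median = med,
    auc_sd = stats::sd(auc_values),
    auc_min = min(auc_values, na.rm = TRUE),
    auc_max = max(auc_values, na.rm = TRUE),
    auc_class = classify_auc(med),
    jackknife_importance = importance,
    fraction_nonneg_mess = if (is.null(mess_result)) NA_real_ else mess_result$fraction_nonneg
  ), class = "evaluation_report")
}
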