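#' Feature expansion for maximum-entropy modelling
#'
#' Builds the feature set from background predictor values: linear (L),
#' quadratic (Q), pairwise-product (P) and hinge (H) transforms, each min-max
#' scaled so that every feature maps background values into \[0,1\]. Hinge
#' knots are placed at background quantiles strictly inside the predictor
#' range, with both forward (`max(0, x - k)`) and reverse (`max(0, k - x)`)
#' directions. When predicting, inputs are clamped to the background range of
#' each predictor before the transforms, so features stay in \[0,1\] outside
#' the training envelope (extrapolation is reported separately via [mess()]).
#'
#' Constant predictors (no spread over the background) contribute no features;
#' they are recorded in the returned object's `dropped` field with a warning.
#'
#' @param background data.frame of predictor values over the background.
#' @param classes string of feature-class letters among `"LQPH"`, e.g.
#'   `"LQH"`.
#' @param n_hinge_knots number of hinge knot positions per predictor
#'   (default 50); each knot yields a forward and a reverse hinge.
#' @return object of class `feature_set`: feature definitions plus per-
#'   predictor background ranges and means.
#' @export
build_features <- function(background, classes = "LQPH", n_hinge_knots = 50) {
  vars <- names(background)
  cls <- strsplit(toupper(classes), "")[[1]]
  if (!all(cls %in% c("L", "Q", "P", "H"))) {
    stop("classes must be letters among L, Q, P, H")
  }
  rng <- lapply(background, range)
  mmeans <- vapply(background, mean, numeric(1))
  dropped <- vars[vapply(rng, function(r) r[1] == r[2], logical(1))]
  if (length(dropped)) {
    warning("constant predictor(s) dropped from features: ",
            paste(dropped, collapse = ", "))
  }
  use <- setdiff(vars, dropped)
  if (length(use) < 1) stop("no predictor with at least 2 distinct values")

  feats <- list()
  add <- function(f) feats[[length(feats) + 1]] <<- f
  for (v in use) {
    lo <- rng[[v]][1]; hi <- rng[[v]][2]
    if ("L" %in% cls) {
      add(list(kind = "linear", var = v, lo = lo, hi = hi,
               id = paste0("L_", v), class = "L"))
    }
    if ("Q" %in% cls) {
      sq <- range(background[[v]]^2)
      add(list(kind = "quadratic", var = v, lo = sq[1], hi = sq[2],
               id = paste0("Q_", v), class = "Q"))
    }
    if ("H" %in% cls) {
      probs <- seq_len(n_hinge_knots) / (n_hinge_knots + 1)
      knots <- unique(stats::quantile(background[[v]], probs, names = FALSE,
                                      type = 7))
      knots <- knots[knots > lo & knots < hi]
      for (k in knots) {
        add(list(kind = "hinge_fwd", var = v, knot = k, lo = lo, hi = hi,
                 id = sprintf("Hf_%s_%.8g", v, k), class = "H"))
        add(list(kind = "hinge_rev", var = v, knot = k, lo = lo, hi = hi,
                 id = sprintf("Hr_%s_%.8g", v, k), class = "H"))
      }
    }
  }
  if ("P" %in% cls && length(use) >= 2) {
    pairs <- utils::combn(use, 2)
    for (j in seq_len(ncol(pairs))) {
      v1 <- pairs[1, j]; v2 <- pairs[2, j]
      pr <- range(background[[v1]] * background[[v2]])
      add(list(kind = "product", var = v1, var2 = v2, lo = pr[1], hi = pr[2],
               id = paste0("P_", v1, "_", v2), class = "P"))
    }
  }
  structure(list(features = feats,
                 vars = use,
                 ranges = rng[use],
                 means = mmeans[use],
                 classes = paste(cls, collapse = ""),
                 dropped = dropped),
            class = "feature_set")
}

clamp_to_range <- function(x, r) pmin(pmax(x, r[1]), r[2])

#' Evaluate a feature set on new predictor values
#'
#' @param featset a [build_features()] result.
#' @param data data.frame containing all predictors named in `featset`.
#' @return numeric matrix, one column per feature, values in \[0,1\].
#' @export
feature_matrix <- function(featset, data) {
  n <- nrow(data)
  clamped <- lapply(featset$vars, function(v) {
    clamp_to_range(data[[v]], featset$ranges[[v]])
  })
  names(clamped) <- featset$vars
  J <- length(featset$features)
  X <- matrix(0, n, J)
  ids <- character(J)
  for (j in seq_len(J)) {
    f <- featset$features[[j]]
    ids[j] <- f$id
    x <- clamped[[f$var]]
    X[, j] <- switch(f$kind,
      linear = (x - f$lo) / (f$hi - f$lo),
      quadratic = (x^2 - f$lo) / (f$hi - f$lo),
      product = {
        p <- x * clamped[[f$var2]]
        pmin(pmax((p - f$lo) / (f$hi - f$lo), 0), 1)
      },
      hinge_fwd = pmax(0, x - f$knot) / (f$hi - f$knot),
      hinge_rev = pmax(0, f$knot - x) / (f$knot - f$lo),
      stop("unknown feature kind: ", f$kind)
    )
  }
  colnames(X) <- ids
  X
}

feature_classes <- function(featset) {
  vapply(featset$features, function(f) f$class, character(1))
}
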