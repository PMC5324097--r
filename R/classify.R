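label_to_binary <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.numeric(label)) return(as.integer(label != 0))
  as.integer(as.character(label) == "malignant")
}

#' Logistic-regression malignancy scores
#'
#' Fits a maximum-likelihood binomial GLM with the logit link on the
#' feature columns and returns the fitted probability of the malignant
#' class for every row.  Features are z-scored before fitting (the GLM is
#' equivariant, but standardization stabilizes the ridge fallback).  If
#' the fit shows (quasi-)separation or fails to converge, a warning is
#' issued and scores come from a lightly ridge-penalized fit instead.
#'
#' @param table feature table with a `label` column
#'   (`benign`/`malignant`).
#' @param standardize z-score the features first (default TRUE).
#' @return Numeric vector of scores in `(0, 1)`, one per row.
#' @export
fit_logistic_scores <- function(table, standardize = TRUE) {
  y <- label_to_binary(table$label)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 2) stop("need at least 2 rows per class")
  X <- feature_matrix(table)
  if (ncol(X) == 0) {          # intercept-only model: scores = prevalence
    return(rep(mean(y), length(y)))
  }
  if (standardize) X <- zscore_fit_apply(X, X)$test
  df <- data.frame(X, check.names = TRUE)
  df$.y <- y
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated) {
    warning("(quasi-)separation in logistic fit; using ridge fallback")
    Xr <- if (ncol(X) < 2) cbind(X, 0) else X    # glmnet needs >= 2 cols
    rf <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = FALSE)
    return(as.numeric(stats::predict(rf, newx = Xr, type = "response")))
  }
  as.numeric(stats::fitted(fit))
}

#' Cross-validated logistic scores
#'
#' Honest out-of-fold probabilities: the table is split into stratified
#' folds, the GLM is fitted on each training split (standardization fitted
#' there too) and rows are scored only by the model that never saw them.
#' Used for held-out evaluation and for null (label-shuffled) controls,
#' where in-sample scores would be optimistically biased.
#'
#' @inheritParams fit_logistic_scores
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return Numeric score vector, one per row.
#' @export
cv_logistic_scores <- function(table, k = 10, seed = 1) {
  y <- label_to_binary(table$label)
  X <- feature_matrix(table)
  folds <- stratified_folds(y, k, seed)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    sc <- zscore_fit_apply(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    df_tr <- data.frame(sc$train, check.names = TRUE); df_tr$.y <- y[tr]
    df_te <- data.frame(sc$test, check.names = TRUE)
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df_tr, family = stats::binomial()))
    scores[!tr] <- suppressWarnings(
      stats::predict(fit, newdata = df_te, type = "response"))
  }
  scores
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (ties
#' grouped), yielding the staircase of (false-positive rate, true-positive
#' rate) vertices from (0, 0) to (1, 1), and the trapezoidal area under
#' the curve.
#'
#' @param scores numeric scores, larger = more malignant.
#' @param labels class labels (`benign`/`malignant`, logical or 0/1).
#' @return Object of class `roc_curve`: `fpr`, `tpr`, `thresholds`
#'   (`Inf` for the (0,0) vertex), `auc`, and the class totals `P`, `N`.
#' @export
roc_curve <- function(scores, labels) {
  y <- label_to_binary(labels)
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / P, 0.0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / N, 0.0)
  fpr <- c(0, fpr); tpr <- c(0, tpr); thr <- c(Inf, thr)
  if (fpr[length(fpr)] < 1 || tpr[length(tpr)] < 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1); thr <- c(thr, -Inf)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc,
                 P = P, N = N),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d vertices, AUC = %.4f (P = %d, N = %d)>\n",
              length(x$fpr), x$auc, x$P, x$N))
  invisible(x)
}

#' Cost-slope optimal operating point
#'
#' Selects the ROC vertex first touched by an iso-cost line of slope
#' \deqn{m = \frac{\phi(P|N) - \phi(N|N)}{\phi(N|P) - \phi(P|P)}
#'       \cdot \frac{N}{P}}
#' swept down from the upper-left corner — equivalently the vertex
#' maximizing `tpr - m * fpr`, which minimizes the expected
#' misclassification cost.  Costs default to the symmetric scheme
#' `phi(N|P) = phi(P|N) = 0.5` with zero cost for correct calls.  Ties are
#' broken toward higher specificity (lower false-positive rate).
#'
#' @param roc a [roc_curve()].
#' @param cost_fn cost of calling a malignant node benign, `phi(N|P)`.
#' @param cost_fp cost of calling a benign node malignant, `phi(P|N)`.
#' @param cost_tp,cost_tn costs of correct calls, `phi(P|P)`, `phi(N|N)`.
#' @param P,N class totals; default those stored in `roc`.
#' @return Object of class `operating_point`: `threshold`, `sensitivity`,
#'   `specificity`, `slope_m`, `expected_cost`, `fpr`, `tpr`.
#' @export
optimal_operating_point <- function(roc, cost_fn = 0.5, cost_fp = 0.5,
                                    cost_tp = 0, cost_tn = 0,
                                    P = roc$P, N = roc$N) {
  stopifnot(inherits(roc, "roc_curve"), P > 0, N > 0)
  if (cost_fn - cost_tp == 0) stop("zero denominator in slope m")
  m <- (cost_fp - cost_tn) / (cost_fn - cost_tp) * N / P
  obj <- roc$tpr - m * roc$fpr
  best <- which(obj >= max(obj) - 1e-12)
  best <- best[which.min(roc$fpr[best])]    # tie -> higher specificity
  fn <- (1 - roc$tpr[best]) * P
  fp <- roc$fpr[best] * N
  structure(list(threshold = roc$thresholds[best],
                 sensitivity = roc$tpr[best],
                 specificity = 1 - roc$fpr[best],
                 slope_m = m,
                 expected_cost = cost_fn * fn + cost_fp * fp +
                   cost_tp * (roc$tpr[best] * P) +
                   cost_tn * ((1 - roc$fpr[best]) * N),
                 fpr = roc$fpr[best], tpr = roc$tpr[best]),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(paste0("<operating_point: threshold %.4g, SEN %.3f, ",
                     "SPE %.3f, m = %.3g>\n"),
              x$threshold, x$sensitivity, x$specificity, x$slope_m))
  invisible(x)
}

# staircase tpr at given fpr values: highest tpr attained at fpr <= f
tpr_at <- function(roc, grid) {
  agg <- tapply(roc$tpr, roc$fpr, max)
  xs <- as.numeric(names(agg)); ys <- as.numeric(agg)
  stats::approx(xs, ys, xout = grid, method = "constant",
                f = 0, rule = 2, ties = max)$y
}

#' Pointwise ROC confidence bands by bootstrap vertical averaging
#'
#' Resamples the data with a class-stratified bootstrap (so every replica
#' keeps both classes and the prevalence), rebuilds each replica's ROC,
#' reads its true-positive rate at a fixed grid of false-positive rates
#' (vertical averaging), and reports percentile bands and the vertical
#' average across replicas.
#'
#' @param scores,labels as in [roc_curve()].
#' @param n_boot bootstrap replicas (default 1000).
#' @param grid false-positive-rate grid (default 0 to 1 by 0.01).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; same seed gives identical bands.
#' @return List with `grid`, `lower`, `upper`, `mean_tpr`, `level`,
#'   `n_boot`.
#' @export
roc_confidence_bands <- function(scores, labels, n_boot = 1000,
                                 grid = seq(0, 1, by = 0.01),
                                 level = 0.95, seed = 1) {
  y <- label_to_binary(labels)
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tprs <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    tprs[b, ] <- tpr_at(roc_curve(scores[idx], y[idx]), grid)
  }
  a <- (1 - level) / 2
  list(grid = grid,
       lower = apply(tprs, 2, stats::quantile, probs = a),
       upper = apply(tprs, 2, stats::quantile, probs = 1 - a),
       mean_tpr = colMeans(tprs),
       level = level, n_boot = n_boot)
}

# stratified fold assignment: shuffle within class, deal folds round-robin
stratified_folds <- function(y, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    if (length(idx) < k)
      stop("class too small to stratify into ", k, " folds")
    folds[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}

# z-score using training statistics only; zero-variance features map to 0
zscore_fit_apply <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- Inf      # constant feature -> all zeros
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"))
}

# Pooled-covariance linear discriminant with a small ridge for stability.
ridge_lda_fit <- function(X, y, ridge = 1e-6) {
  classes <- sort(unique(y))
  mus <- lapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  n <- nrow(X); p <- ncol(X)
  Sp <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    Sp <- Sp + crossprod(sweep(Xi, 2, mus[[i]]))
  }
  Sp <- Sp / (n - length(classes)) + diag(ridge, p)
  Spi <- solve(Sp)
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  list(classes = classes, mus = mus, Spi = Spi, priors = priors)
}

ridge_lda_predict <- function(fit, X) {
  scores <- vapply(seq_along(fit$classes), function(i) {
    mu <- fit$mus[[i]]
    as.numeric(X %*% (fit$Spi %*% mu)) -
      0.5 * as.numeric(t(mu) %*% fit$Spi %*% mu) + log(fit$priors[i])
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Stratified tenfold cross-validation
#'
#' Splits the table into stratified folds, z-scores features with the
#' training split's statistics only (no leakage), trains the requested
#' classifier and reports per-fold and mean accuracy.  Classifiers:
#' linear-kernel SVM with C = 1 (RBF behind `svm_kernel = "radial"`),
#' Gaussian naive Bayes, and a pooled-covariance linear discriminant with
#' ridge `1e-6`.
#'
#' @param table feature table with `label`.
#' @param classifier `"svm"`, `"naive_bayes"` or `"lda"`.
#' @param seed fold-assignment seed.
#' @param k folds (default 10).
#' @param svm_kernel `"linear"` (default) or `"radial"`.
#' @param svm_cost SVM cost parameter C (default 1).
#' @return Object of class `cv_result`: `fold_accuracy` (k values),
#'   `mean_accuracy` (percent), `classifier`, `seed`, `folds`.
#' @export
tenfold_cv <- function(table, classifier = c("svm", "naive_bayes", "lda"),
                       seed = 1, k = 10, svm_kernel = "linear",
                       svm_cost = 1) {
  classifier <- match.arg(classifier)
  y <- label_to_binary(table$label)
  X <- feature_matrix(table)
  folds <- stratified_folds(y, k, seed)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    sc <- zscore_fit_apply(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    Xtr <- sc$train; Xte <- sc$test
    keep <- apply(Xtr, 2, function(v) stats::sd(v) > 0)
    if (!any(keep)) {          # nothing informative: majority vote
      pred <- rep(as.integer(mean(y[tr]) >= 0.5), sum(!tr))
    } else {
      Xtr <- Xtr[, keep, drop = FALSE]; Xte <- Xte[, keep, drop = FALSE]
      pred <- switch(classifier,
        svm = {
          fit <- e1071::svm(Xtr, factor(y[tr], levels = c(0, 1)),
                            kernel = svm_kernel, cost = svm_cost,
                            scale = FALSE)
          as.integer(as.character(stats::predict(fit, Xte)))
        },
        naive_bayes = {
          fit <- e1071::naiveBayes(Xtr, factor(y[tr], levels = c(0, 1)))
          as.integer(as.character(stats::predict(fit, Xte)))
        },
        lda = {
          fit <- ridge_lda_fit(Xtr, y[tr])
          ridge_lda_predict(fit, Xte)
        })
    }
    acc[f] <- mean(pred == y[!tr])
  }
  structure(list(fold_accuracy = acc,
                 mean_accuracy = 100 * mean(acc),
                 classifier = classifier, seed = seed, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s: mean accuracy %.1f%% over %d folds>\n",
              x$classifier, x$mean_accuracy, length(x$fold_accuracy)))
  invisible(x)
}
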