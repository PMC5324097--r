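make_table <- function(X, y) {
  cbind(data.frame(image_id = sprintf("s%03d", seq_along(y)),
                   label = ifelse(y == 1, "malignant", "benign"),
                   stringsAsFactors = FALSE),
        as.data.frame(X))
}

test_that("logistic scores separate a perfectly ordered 1-D feature", {
  y <- rep(c(0, 1), each = 20)
  X <- matrix(c(seq(0, 1, length.out = 20), seq(2, 3, length.out = 20)))
  colnames(X) <- "f1"
  s <- suppressWarnings(fit_logistic_scores(make_table(X, y)))
  expect_equal(roc_curve(s, y)$auc, 1)
})

test_that("separation triggers a warning and a usable ridge fallback", {
  y <- rep(c(0, 1), each = 20)
  X <- matrix(c(seq(0, 1, length.out = 20), seq(2, 3, length.out = 20)))
  colnames(X) <- "f1"
  expect_warning(s <- fit_logistic_scores(make_table(X, y)),
                 "separation")
  expect_true(all(s > 0 & s < 1))
  expect_equal(roc_curve(s, y)$auc, 1)
})

test_that("an intercept-only model scores everyone at the prevalence", {
  y <- c(rep(0, 30), rep(1, 10))
  tab <- data.frame(image_id = as.character(seq_along(y)),
                    label = ifelse(y == 1, "malignant", "benign"))
  expect_equal(fit_logistic_scores(tab), rep(0.25, 40))
})

test_that("null features give chance-level scores", {
  set.seed(202)
  y <- rep(c(0, 1), each = 100)
  X <- matrix(stats::rnorm(200 * 2), 200, 2,
              dimnames = list(NULL, c("f1", "f2")))
  s <- fit_logistic_scores(make_table(X, y))
  expect_lt(abs(roc_curve(s, y)$auc - 0.5), 0.1)
})

test_that("trapezoidal AUC equals the pairwise oracle, ties included", {
  set.seed(77)
  for (i in 1:60) {
    d <- random_score_set(30)
    r <- roc_curve(d$scores, d$y)
    expect_equal(r$auc, oracle_auc(d$scores, d$y), tolerance = 1e-12)
    expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
    expect_equal(r$fpr[length(r$fpr)], 1)
    expect_true(all(diff(r$fpr) >= 0))
  }
  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under monotone transforms, flips with labels", {
  set.seed(5)
  s <- stats::runif(50); y <- sample(c(0, 1), 50, replace = TRUE)
  y[1:2] <- c(0, 1)
  a <- roc_curve(s, y)$auc
  expect_equal(roc_curve(stats::qlogis(s * 0.98 + 0.01), y)$auc, a)
  expect_equal(roc_curve(s^3, y)$auc, a)
  expect_equal(roc_curve(s, 1 - y)$auc, 1 - a, tolerance = 1e-12)
})

test_that("perfect and all-tied scores hit the degenerate AUC values", {
  expect_equal(roc_curve(c(0.9, 0.9, 0.1), c(1, 1, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
})

test_that("the cost-slope vertex matches brute-force cost minimization", {
  set.seed(303)
  for (i in 1:100) {
    d <- random_score_set(25)
    r <- roc_curve(d$scores, d$y)
    cfn <- stats::runif(1, 0.1, 2); cfp <- stats::runif(1, 0.1, 2)
    op <- optimal_operating_point(r, cost_fn = cfn, cost_fp = cfp)
    k <- oracle_min_cost_vertex(r$fpr, r$tpr, cfn, cfp, r$P, r$N)
    expect_equal(op$fpr, r$fpr[k])
    expect_equal(op$tpr, r$tpr[k])
    expect_equal(op$expected_cost,
                 cfn * (1 - r$tpr[k]) * r$P + cfp * r$fpr[k] * r$N,
                 tolerance = 1e-12)
  }
})

test_that("symmetric costs with balanced classes force slope one", {
  y <- rep(c(0, 1), each = 15)
  r <- roc_curve(stats::runif(30), y)
  op <- optimal_operating_point(r, cost_fn = 0.5, cost_fp = 0.5)
  expect_identical(op$slope_m, 1)
  # perfect ROC: the dominant vertex is (fpr 0, tpr 1)
  rp <- roc_curve(c(rep(0.1, 15), rep(0.9, 15)), y)
  opp <- optimal_operating_point(rp)
  expect_equal(opp$fpr, 0); expect_equal(opp$tpr, 1)
  expect_error(optimal_operating_point(r, cost_fn = 0, cost_tp = 0),
               "denominator")
})

test_that("our ROC machinery agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(88)
  s <- stats::runif(80); y <- sample(c(0, 1), 80, replace = TRUE)
  y[1:2] <- c(0, 1)
  ref <- suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(roc_curve(s, y)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("bootstrap bands are deterministic and collapse at n_boot = 1", {
  set.seed(12)
  y <- rep(c(0, 1), each = 30)
  s <- c(stats::rnorm(30, 0), stats::rnorm(30, 1.5))
  b1 <- roc_confidence_bands(s, y, n_boot = 50, seed = 4)
  b2 <- roc_confidence_bands(s, y, n_boot = 50, seed = 4)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  one <- roc_confidence_bands(s, y, n_boot = 1, seed = 4)
  expect_equal(one$lower, one$upper)
  expect_equal(one$lower, one$mean_tpr)
  expect_true(all(b1$lower <= b1$upper))
})

test_that("bands cover the point-estimate curve on separable data", {
  set.seed(41)
  y <- rep(c(0, 1), each = 100)
  s <- c(stats::rnorm(100, 0), stats::rnorm(100, 2))
  r <- roc_curve(s, y)
  b <- roc_confidence_bands(s, y, n_boot = 300, seed = 7)
  point <- nodetex:::tpr_at(r, b$grid)
  covered <- mean(point >= b$lower - 1e-9 & point <= b$upper + 1e-9)
  expect_gte(covered, 0.9)
})

test_that("tenfold CV nails separable Gaussians and stays at chance on null", {
  set.seed(55)
  y <- rep(c(0, 1), each = 50)
  X <- rbind(matrix(stats::rnorm(50 * 3, 0), 50, 3),
             matrix(stats::rnorm(50 * 3, 4), 50, 3))
  colnames(X) <- paste0("f", 1:3)
  tab <- make_table(X, y)
  for (cl in c("svm", "naive_bayes", "lda"))
    expect_gte(tenfold_cv(tab, cl, seed = 2)$mean_accuracy, 95)

  Xn <- matrix(stats::rnorm(100 * 3), 100, 3,
               dimnames = list(NULL, paste0("f", 1:3)))
  null_acc <- mean(vapply(1:3, function(s)
    tenfold_cv(make_table(Xn, sample(y)), "svm",
               seed = s)$mean_accuracy, 0.0))
  expect_lt(abs(null_acc - 50), 10)
})

test_that("CV is deterministic per seed with valid stratified folds", {
  set.seed(66)
  y <- rep(c(0, 1), each = 25)
  X <- matrix(stats::rnorm(50 * 2), 50, 2,
              dimnames = list(NULL, c("f1", "f2")))
  tab <- make_table(X, y)
  a <- tenfold_cv(tab, "lda", seed = 10)
  b <- tenfold_cv(tab, "lda", seed = 10)
  expect_identical(a$fold_accuracy, b$fold_accuracy)
  expect_identical(a$folds, b$folds)
  for (f in 1:10)
    expect_equal(sum(a$folds == f & y == 1), sum(a$folds == f & y == 0))
  expect_equal(a$mean_accuracy, 100 * mean(a$fold_accuracy))
  expect_error(tenfold_cv(make_table(X[1:12, ], y[c(1:6, 26:31)]), "svm"),
               "too small")
})

test_that("the ridge discriminant matches classical LDA when well posed", {
  skip_if_not_installed("MASS")
  set.seed(99)
  y <- rep(c(0, 1), each = 40)
  X <- rbind(matrix(stats::rnorm(40 * 4, 0), 40, 4),
             matrix(stats::rnorm(40 * 4, 1), 40, 4))
  fit <- nodetex:::ridge_lda_fit(X, y)
  ours <- nodetex:::ridge_lda_predict(fit, X)
  ref <- as.integer(as.character(
    stats::predict(MASS::lda(X, grouping = y), X)$class))
  expect_gte(mean(ours == ref), 0.99)
})

test_that("cross-validated logistic scores are honest on null features", {
  set.seed(110)
  y <- rep(c(0, 1), each = 60)
  X <- matrix(stats::rnorm(120 * 10), 120, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  tab <- make_table(X, y)
  in_sample <- roc_curve(suppressWarnings(fit_logistic_scores(tab)),
                         y)$auc
  cv_auc <- mean(vapply(1:5, function(s)
    roc_curve(cv_logistic_scores(tab, seed = s), y)$auc, 0.0))
  expect_gt(in_sample, cv_auc)    # optimism of in-sample scoring
  expect_lt(abs(cv_auc - 0.5), 0.1)
})
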