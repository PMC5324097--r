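# rolling 31-bit hash of the config's JSON form, hex-encoded; embedded in
# every output artifact so runs are traceable to their exact settings
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", derive_seed(0, as.character(s)))
}

#' Run the full texture-classification pipeline
#'
#' End-to-end orchestration: obtain a cohort (simulated, or loaded from an
#' image directory plus ROI table), extract the requested feature
#' combination, score with logistic regression, build the ROC with its
#' cost-slope operating point (and optionally bootstrap confidence bands),
#' and run stratified tenfold cross-validation with the requested
#' classifiers.  All artifacts (feature CSV, ROC vertices CSV, band CSV,
#' metrics JSON) carry the configuration hash and seeds.
#'
#' @param config list with entries:
#'   \describe{
#'     \item{combo}{combination name, see [list_combos()].}
#'     \item{seed}{global integer seed (default 1).}
#'     \item{simulate}{list for [generate_cohort()] (`n_per_class`, and
#'       optionally class spec overrides), or `NULL` to load files.}
#'     \item{images_dir, roi_table}{input paths when not simulating.}
#'     \item{L, offset, noise_variance, imc, synth}{extraction settings,
#'       see [extract_combo()].}
#'     \item{classifiers}{character subset of svm / naive_bayes / lda
#'       (default all three); empty vector skips cross-validation.}
#'     \item{cv_folds}{folds for cross-validation (default 10).}
#'     \item{bands}{logical: compute bootstrap ROC bands (default FALSE);
#'       `n_boot` (default 1000).}
#'     \item{holdout}{logical: score by honest cross-validated logistic
#'       probabilities instead of in-sample fitted ones (default FALSE).}
#'     \item{out_dir}{output directory, or `NULL` for no files.}
#'   }
#' @return List with `table`, `roc`, `operating_point`, `cv` (per
#'   classifier), `bands` (or NULL), `metrics` (flat summary), `hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$combo))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  # hash only the scientific settings, not where artifacts land
  hash <- config_hash(config[setdiff(names(config), "out_dir")])

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    args <- list(n_per_class = sim$n_per_class, seed = seed)
    if (!is.null(sim$spec_benign)) args$spec_benign <- sim$spec_benign
    if (!is.null(sim$spec_malignant))
      args$spec_malignant <- sim$spec_malignant
    cohort <- do.call(generate_cohort, args)
    dataset <- cohort$samples
  } else {
    rois <- read_roi_table(config$roi_table)
    dataset <- lapply(rois, function(roi) {
      path <- file.path(config$images_dir, paste0(roi$image_id, ".png"))
      if (!file.exists(path))
        path <- file.path(config$images_dir, paste0(roi$image_id, ".tif"))
      list(image = load_image(path), roi = roi)
    })
  }

  extract_args <- list(combo = config$combo, seed = seed)
  for (nm in c("L", "offset", "noise_variance", "imc", "synth"))
    if (!is.null(config[[nm]])) extract_args[[nm]] <- config[[nm]]
  table <- do.call(build_feature_table,
                   c(list(dataset = dataset), extract_args))

  holdout <- isTRUE(config$holdout)
  scores <- if (holdout) cv_logistic_scores(table, seed = seed)
            else fit_logistic_scores(table)
  roc <- roc_curve(scores, table$label)
  op <- optimal_operating_point(roc)

  bands <- NULL
  if (isTRUE(config$bands)) {
    nb <- if (is.null(config$n_boot)) 1000L else config$n_boot
    bands <- roc_confidence_bands(scores, table$label, n_boot = nb,
                                  seed = seed)
  }

  classifiers <- if (is.null(config$classifiers))
    c("svm", "naive_bayes", "lda") else config$classifiers
  k <- if (is.null(config$cv_folds)) 10 else config$cv_folds
  cv <- lapply(classifiers, function(cl)
    tenfold_cv(table, classifier = cl, seed = seed, k = k))
  names(cv) <- classifiers

  metrics <- c(list(combo = config$combo, seed = seed, hash = hash,
                    n = nrow(table), holdout = holdout,
                    auc = roc$auc, sen = op$sensitivity,
                    spe = op$specificity, slope_m = op$slope_m),
               stats::setNames(lapply(cv, function(r) r$mean_accuracy),
                               paste0("accuracy_", classifiers)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(table,
                        file.path(config$out_dir, "features.csv"),
                        params = c(extract_args, list(hash = hash)))
    utils::write.csv(data.frame(fpr = roc$fpr, tpr = roc$tpr,
                                threshold = roc$thresholds),
                     file.path(config$out_dir, "roc.csv"),
                     row.names = FALSE)
    if (!is.null(bands))
      utils::write.csv(data.frame(fpr = bands$grid, lower = bands$lower,
                                  upper = bands$upper,
                                  mean_tpr = bands$mean_tpr),
                       file.path(config$out_dir, "roc_bands.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      c(metrics,
        list(fold_accuracy = lapply(cv, function(r) r$fold_accuracy))),
      file.path(config$out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA)
  }

  list(table = table, roc = roc, operating_point = op, cv = cv,
       bands = bands, metrics = metrics, hash = hash)
}
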