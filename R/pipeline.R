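#' Feature combination registry
#'
#' The evaluation protocol compares fixed, named combinations of the three
#' feature families: GLCM descriptors on the raw ROI, semivariogram lags
#' with (`nSV`) or without (`SV`) noise enhancement, and semivariogram lags
#' on a synthesized enlargement (`sSV1`: 20 lags of a 200 x 200 synthesis;
#' `sSV2`: 30 lags of a 250 x 250 synthesis).  `combo_spec()` resolves a
#' combination name into its component list.
#'
#' @param name one of `"GLCM4"`, `"GLCM20"`, `"SV10"`, `"nSV10"`,
#'   `"GLCM20+SV10"`, `"GLCM20+nSV10"`, `"GLCM20+nSV10+sSV1"`,
#'   `"GLCM4+nSV10+sSV2"`, `"GLCM20+nSV10+sSV2"`.
#' @return A `combo_spec` list with elements `name`, `glcm` (NULL,
#'   `"basic4"` or `"full20"`), `sv_lags` (NULL or 10), `sv_noise`
#'   (logical), `ssv` (NULL or list with `lags` and `size`).
#' @export
combo_spec <- function(name) {
  ssv1 <- list(lags = 20L, size = c(200L, 200L))
  ssv2 <- list(lags = 30L, size = c(250L, 250L))
  registry <- list(
    "GLCM4"              = list(glcm = "basic4", sv_lags = NULL,
                                sv_noise = FALSE, ssv = NULL),
    "GLCM20"             = list(glcm = "full20", sv_lags = NULL,
                                sv_noise = FALSE, ssv = NULL),
    "SV10"               = list(glcm = NULL, sv_lags = 10L,
                                sv_noise = FALSE, ssv = NULL),
    "nSV10"              = list(glcm = NULL, sv_lags = 10L,
                                sv_noise = TRUE, ssv = NULL),
    "GLCM20+SV10"        = list(glcm = "full20", sv_lags = 10L,
                                sv_noise = FALSE, ssv = NULL),
    "GLCM20+nSV10"       = list(glcm = "full20", sv_lags = 10L,
                                sv_noise = TRUE, ssv = NULL),
    "GLCM20+nSV10+sSV1"  = list(glcm = "full20", sv_lags = 10L,
                                sv_noise = TRUE, ssv = ssv1),
    "GLCM4+nSV10+sSV2"   = list(glcm = "basic4", sv_lags = 10L,
                                sv_noise = TRUE, ssv = ssv2),
    "GLCM20+nSV10+sSV2"  = list(glcm = "full20", sv_lags = 10L,
                                sv_noise = TRUE, ssv = ssv2))
  if (!name %in% names(registry))
    stop("unknown combination: ", name, "; known: ",
         paste(names(registry), collapse = ", "))
  structure(c(list(name = name), registry[[name]]), class = "combo_spec")
}

#' @rdname combo_spec
#' @export
list_combos <- function() {
  c("GLCM4", "GLCM20", "SV10", "nSV10", "GLCM20+SV10", "GLCM20+nSV10",
    "GLCM20+nSV10+sSV1", "GLCM4+nSV10+sSV2", "GLCM20+nSV10+sSV2")
}

#' Extract one combination's feature vector from an ROI image
#'
#' Runs the branches of the extraction pipeline on one ROI: the ROI is
#' first rescaled to `[0, 1]`; the GLCM branch quantizes it to `L` levels
#' and computes the requested descriptor set; the (n)SV branch computes the
#' semivariogram of the (noise-enhanced) ROI at lags `1..10`; the sSV
#' branch synthesizes an enlargement of the raw normalized ROI (synthesis
#' and noise are parallel branches — the synthesizer never sees added
#' noise) and computes its semivariogram at the larger lags.  Components
#' are concatenated in the fixed order GLCM, nSV/SV, sSV.
#'
#' Noise and synthesis draws are seeded per sample from `seed` and
#' `image_id`, so a full table extraction is reproducible and
#' sample-distinct.
#'
#' @param roi_image `gray_image` (an already-extracted ROI).
#' @param combo a [combo_spec()] or combination name.
#' @param image_id sample identifier used for seed derivation.
#' @param L gray levels for the GLCM branch (default 8).
#' @param offset GLCM offset (default `c(0, 1)`: next pixel on the row).
#' @param noise_variance nSV noise variance on the unit scale (default
#'   0.02).
#' @param imc `"both"` or `"one"` information measures (see
#'   [glcm_features()]).
#' @param seed global integer seed.
#' @param synth patch-synthesis parameters: list with `patch`, `overlap`,
#'   `tolerance`.
#' @return Named numeric feature vector.
#' @export
extract_combo <- function(roi_image, combo, image_id = "roi", L = 8,
                          offset = c(0L, 1L), noise_variance = 0.02,
                          imc = c("both", "one"), seed = 1,
                          synth = list(patch = 10, overlap = 6,
                                       tolerance = 0.1)) {
  if (is.character(combo)) combo <- combo_spec(combo)
  imc <- match.arg(imc)
  norm <- normalize_unit(roi_image)
  out <- numeric(0)
  if (!is.null(combo$glcm)) {
    g <- compute_glcm(quantize(norm, L = L), offset = offset)
    out <- c(out, glcm_features(g, set = combo$glcm, imc = imc))
  }
  if (!is.null(combo$sv_lags)) {
    img <- norm
    prefix <- "sv"
    if (combo$sv_noise) {
      img <- add_gaussian_noise(norm, variance = noise_variance,
                                seed = derive_seed(seed,
                                                   paste0(image_id, "_noise")))
      prefix <- "nsv"
    }
    curve <- empirical_semivariogram(img, max_lag = combo$sv_lags)
    out <- c(out, sv_features(curve, combo$sv_lags, prefix = prefix))
  }
  if (!is.null(combo$ssv)) {
    cfg <- synthesis_config(out_height = combo$ssv$size[1],
                            out_width = combo$ssv$size[2],
                            patch = synth$patch, overlap = synth$overlap,
                            tolerance = synth$tolerance,
                            seed = derive_seed(seed,
                                               paste0(image_id, "_synth")))
    big <- synthesize(norm, cfg)
    curve <- empirical_semivariogram(big, max_lag = combo$ssv$lags)
    out <- c(out, sv_features(curve, combo$ssv$lags, prefix = "ssv"))
  }
  if (!all(is.finite(out)))
    stop("non-finite feature values for ", image_id)
  out
}

#' Build a labeled feature table for a dataset
#'
#' Applies [extract_combo()] to every (image, ROI) pair and assembles one
#' row per ROI, in input order, with `image_id` and `label` metadata
#' columns followed by the feature columns.  Any per-sample failure aborts
#' with the offending `image_id`.
#'
#' @param dataset a `synthetic_cohort`, or a list whose elements are lists
#'   with `image` (`gray_image`) and `roi` ([roi_record()]).
#' @param combo combination name or [combo_spec()].
#' @param ... passed to [extract_combo()] (`L`, `noise_variance`, `imc`,
#'   `seed`, `synth`, ...).
#' @return A `data.frame` feature table.
#' @export
build_feature_table <- function(dataset, combo, ...) {
  if (inherits(dataset, "synthetic_cohort")) dataset <- dataset$samples
  if (is.character(combo)) combo <- combo_spec(combo)
  rows <- lapply(dataset, function(s) {
    roi_img <- extract_roi(s$image, s$roi)
    feats <- tryCatch(
      extract_combo(roi_img, combo, image_id = s$roi$image_id, ...),
      error = function(e)
        stop("feature extraction failed for ", s$roi$image_id, ": ",
             conditionMessage(e), call. = FALSE))
    cbind(data.frame(image_id = s$roi$image_id, label = s$roi$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(feats), check.names = FALSE))
  })
  if (length(rows) == 0) {
    return(data.frame(image_id = character(0), label = character(0)))
  }
  do.call(rbind, rows)
}

#' Write / read a feature table with a parameter sidecar
#'
#' The CSV holds one row per ROI; a JSON sidecar (`<path>.json`) records
#' the extraction parameters and seeds so tables are self-describing.
#'
#' @param table feature table from [build_feature_table()].
#' @param path CSV destination.
#' @param params list of extraction parameters to record.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, params = list()) {
  utils::write.csv(table, path, row.names = FALSE)
  if (length(params))
    jsonlite::write_json(params, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# numeric feature columns of a table (everything but the metadata)
feature_matrix <- function(table) {
  cols <- setdiff(names(table), c("image_id", "label"))
  as.matrix(table[, cols, drop = FALSE])
}
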