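#' Texture synthesis configuration
#'
#' Parameters for tolerance-based texture enlargement.  Defaults follow the
#' standard settings for this family of synthesizers: a 10 x 10 patch
#' window, 6 pixels of overlap between placed patches, and tolerance
#' `epsilon = 0.1` on the candidate set.  The patch distance is a
#' Gaussian-weighted normalized sum of squared differences; the kernel
#' width defaults to `patch / 6.4`, a conventional choice for windowed SSD
#' metrics.
#'
#' @param out_height,out_width target size in pixels (the pipeline uses
#'   200 x 200 for 20-lag and 250 x 250 for 30-lag semivariograms).
#' @param patch square window side n (default 10).
#' @param overlap pixels of overlap o between placed patches, 0 < o < n
#'   (default 6).
#' @param tolerance candidate tolerance epsilon >= 0 (default 0.1): every
#'   window with distance `<= (1 + epsilon) * d_min` is a candidate.
#' @param seed integer seed driving all random choices.
#' @param kernel `"gaussian_ssd"` (weighted) or `"plain_ssd"` (unweighted).
#' @param mode `"patch"` (default; places whole patches, scored on the
#'   overlap region) or `"pixel"` (sequential per-pixel generation).
#' @param sigma Gaussian kernel width; default `patch / 6.4`.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(out_height, out_width, patch = 10, overlap = 6,
                             tolerance = 0.1, seed = 1,
                             kernel = c("gaussian_ssd", "plain_ssd"),
                             mode = c("patch", "pixel"),
                             sigma = patch / 6.4) {
  kernel <- match.arg(kernel)
  mode <- match.arg(mode)
  stopifnot(patch >= 2, overlap > 0, overlap < patch,
            tolerance >= 0, out_height >= patch, out_width >= patch,
            sigma > 0)
  structure(list(out_height = as.integer(out_height),
                 out_width = as.integer(out_width),
                 patch = as.integer(patch), overlap = as.integer(overlap),
                 tolerance = tolerance, seed = as.integer(seed),
                 kernel = kernel, mode = mode, sigma = sigma),
            class = "synthesis_config")
}

#' Masked patch distance
#'
#' Distance between a target region and a candidate source region of the
#' same shape: the sum of (optionally Gaussian-weighted) squared
#' differences over the valid pixels, normalized by the sum of the weights
#' used.  Only pixels flagged in `mask` (the already-synthesized ones)
#' enter the comparison.  The distance is symmetric in its two arguments
#' and zero iff the regions agree on the mask.
#'
#' @param target,candidate numeric matrices of identical shape.
#' @param mask logical matrix of the same shape; `NULL` means all pixels.
#' @param kernel `"gaussian_ssd"` or `"plain_ssd"`.
#' @param sigma Gaussian width (default `nrow / 6.4`).
#' @return Nonnegative scalar.
#' @export
patch_distance <- function(target, candidate, mask = NULL,
                           kernel = c("gaussian_ssd", "plain_ssd"),
                           sigma = nrow(target) / 6.4) {
  kernel <- match.arg(kernel)
  target <- as.matrix(target); candidate <- as.matrix(candidate)
  if (!all(dim(target) == dim(candidate)))
    stop("regions must have the same shape")
  if (is.null(mask)) mask <- array(TRUE, dim(target))
  if (!any(mask)) stop("empty valid mask")
  if (kernel == "gaussian_ssd") {
    n <- nrow(target); m <- ncol(target)
    ci <- (n - 1) / 2; cj <- (m - 1) / 2
    w <- outer(seq_len(n) - 1, seq_len(m) - 1,
               function(i, j) exp(-((i - ci)^2 + (j - cj)^2) /
                                    (2 * sigma^2)))
  } else {
    w <- array(1, dim(target))
  }
  num <- sum(w[mask] * (target[mask] - candidate[mask])^2)
  num / sum(w[mask])
}

#' Tolerance-based candidate set
#'
#' Given the distances of every source window to the region being
#' synthesized, returns the indices whose distance is within a factor
#' `(1 + tolerance)` of the minimum.  When the minimum is 0 this is the set
#' of exact matches.
#'
#' @param distances numeric vector, nonempty and finite.
#' @param tolerance epsilon >= 0.
#' @return List with `indices` (1-based) and `d_min`.
#' @export
candidate_set <- function(distances, tolerance = 0.1) {
  if (length(distances) == 0) stop("empty distance vector")
  if (!all(is.finite(distances))) stop("non-finite distances")
  d_min <- min(distances)
  thr <- (1 + tolerance) * d_min + 1e-12 * (1 + d_min)
  list(indices = which(distances <= thr), d_min = d_min)
}

#' Synthesize an enlarged texture from a small sample
#'
#' Generates an `out_height x out_width` image that emulates the stochastic
#' texture of `source`.  In the default patch mode, n x n source windows
#' are placed in raster order, each overlapping already-synthesized content
#' by `overlap` pixels; every source window is scored on the overlap region
#' with the masked Gaussian-weighted SSD, the candidate set keeps the
#' windows within `(1 + tolerance)` of the minimum distance, and one is
#' drawn uniformly at random.  The first patch is drawn uniformly from all
#' source windows.  A new patch overwrites the overlap region (no seam
#' cut).  In pixel mode, pixels are generated one at a time from candidate
#' neighbourhood matches.
#'
#' Every output pixel value occurs in the source (no blending), and the
#' run is fully determined by `config$seed`.  The per-step audit (chosen
#' distance and step minimum) is attached as attribute `"audit"` in patch
#' mode.
#'
#' @param source `gray_image` or matrix, at least `patch` in each dimension.
#' @param config a [synthesis_config()].
#' @return `gray_image` of the target size.
#' @export
synthesize <- function(source, config) {
  stopifnot(inherits(config, "synthesis_config"))
  source <- as_gray_image(source)
  px <- source$pixels
  if (nrow(px) < config$patch || ncol(px) < config$patch)
    stop("source smaller than the patch window")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  gaussian <- config$kernel == "gaussian_ssd"
  if (config$mode == "patch") {
    res <- synth_patch_cpp(px, config$patch, config$overlap,
                           config$out_height, config$out_width,
                           config$tolerance, config$sigma, gaussian)
    out <- gray_image(res$pixels, value_range = source$value_range)
    attr(out, "audit") <- data.frame(d_chosen = res$d_chosen,
                                     d_min = res$d_min)
  } else {
    res <- synth_pixel_cpp(px, config$patch,
                           config$out_height, config$out_width,
                           config$tolerance, config$sigma, gaussian)
    out <- gray_image(res$pixels, value_range = source$value_range)
  }
  out
}
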