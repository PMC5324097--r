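#' Experimental semivariogram of an image
#'
#' The semivariogram treats pixel intensities as a regionalized variable
#' f(u) and summarizes spatial correlation as
#' \deqn{\gamma(h) = \frac{1}{2 M(h)} \sum (f(u) - f(v))^2}
#' over all pixel pairs (u, v) separated by lag h along the requested axis
#' directions.  Horizontal and vertical pairs are pooled into a single
#' M(h) per lag: for an H x W image using both directions,
#' `M(h) = H (W - h) + W (H - h)`.
#'
#' Lags with no pairs (h at least the image extent in every requested
#' direction) are dropped with a warning.
#'
#' @param image `gray_image` or matrix.
#' @param max_lag largest lag H (pixels), >= 1.
#' @param directions subset of `c("horizontal", "vertical")`.
#' @return Object of class `semivariogram`: `lags`, `gamma` (intensity^2
#'   units), `pair_count`.
#' @export
empirical_semivariogram <- function(image, max_lag,
                                    directions = c("horizontal", "vertical")) {
  image <- as_gray_image(image)
  directions <- match.arg(directions, c("horizontal", "vertical"),
                          several.ok = TRUE)
  if (max_lag < 1) stop("max_lag must be >= 1")
  x <- image$pixels
  H <- nrow(x); W <- ncol(x)
  lags <- seq_len(max_lag)
  ss <- numeric(max_lag)      # sum of squared differences
  m <- numeric(max_lag)       # pair counts
  for (h in lags) {
    if ("horizontal" %in% directions && h < W) {
      d <- x[, seq_len(W - h), drop = FALSE] -
           x[, h + seq_len(W - h), drop = FALSE]
      ss[h] <- ss[h] + sum(d * d)
      m[h] <- m[h] + H * (W - h)
    }
    if ("vertical" %in% directions && h < H) {
      d <- x[seq_len(H - h), , drop = FALSE] -
           x[h + seq_len(H - h), , drop = FALSE]
      ss[h] <- ss[h] + sum(d * d)
      m[h] <- m[h] + W * (H - h)
    }
  }
  keep <- m > 0
  if (!any(keep)) stop("image too small for any requested lag")
  if (!all(keep))
    warning("dropping lags with no pixel pairs: ",
            paste(lags[!keep], collapse = ", "))
  structure(list(lags = lags[keep], gamma = ss[keep] / (2 * m[keep]),
                 pair_count = m[keep]),
            class = "semivariogram")
}

#' @export
print.semivariogram <- function(x, ...) {
  cat(sprintf("<semivariogram, lags 1..%d>\n", max(x$lags)))
  print(data.frame(lag = x$lags, gamma = x$gamma, pairs = x$pair_count),
        row.names = FALSE)
  invisible(x)
}

#' Add white Gaussian noise to an image
#'
#' Adds i.i.d. `N(0, variance)` noise per pixel.  Deliberately enhancing
#' texture this way before semivariogram extraction gives the
#' noise-enhanced curve (nSV); the default variance 0.02 assumes the image
#' has been passed through [normalize_unit()] so the scale is meaningful.
#' No clipping is applied: clipping would bias the semivariogram near the
#' intensity bounds.
#'
#' @param image `gray_image` or matrix, normally on the `[0, 1]` scale.
#' @param variance noise variance, >= 0.
#' @param seed optional integer; fixing it makes the draw reproducible.
#' @return `gray_image` with the same dimensions.
#' @export
add_gaussian_noise <- function(image, variance = 0.02, seed = NULL) {
  image <- as_gray_image(image)
  if (variance < 0) stop("variance must be >= 0")
  if (variance == 0) return(image)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  px <- image$pixels
  noise <- matrix(stats::rnorm(length(px), 0, sqrt(variance)),
                  nrow(px), ncol(px))
  gray_image(px + noise, value_range = image$value_range)
}

#' Semivariogram lag features
#'
#' Flattens the first `n_lags` values of a semivariogram into a named
#' feature vector `<prefix>_h1 .. <prefix>_hN`.  The prefix records
#' provenance: `sv` plain, `nsv` noise-enhanced, `ssv` computed on a
#' synthesized enlargement.
#'
#' @param curve `semivariogram`.
#' @param n_lags number of leading lags to keep (the pipeline uses 10, 20
#'   or 30).
#' @param prefix name prefix.
#' @return Named numeric vector of length `n_lags`.
#' @export
sv_features <- function(curve, n_lags, prefix = "sv") {
  stopifnot(inherits(curve, "semivariogram"))
  want <- seq_len(n_lags)
  idx <- match(want, curve$lags)
  if (anyNA(idx))
    stop("curve does not cover requested lags 1..", n_lags)
  stats::setNames(curve$gamma[idx], paste0(prefix, "_h", want))
}
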