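# Deterministic 31-bit seed derived from a global seed and a sample id,
# so cohorts and per-ROI noise/synthesis draws are reproducible yet
# sample-distinct.
derive_seed <- function(seed, id) {
  h <- 0
  for (c in utf8ToInt(as.character(id))) h <- (h * 31 + c) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Simulate a stationary Gaussian random field
#'
#' Generates a zero-mean Gaussian random field on a regular grid with
#' isotropic exponential covariance `s * exp(-d / r)` (sill `s`, range
#' `r`, Euclidean distance `d` in pixels), via circulant embedding on a
#' doubled torus with FFT sampling.  The exponential model's semivariogram
#' has the closed form `s * (1 - exp(-h / r))`, which makes these fields
#' exact ground truth for the semivariogram estimator.  If the embedding
#' is not nonnegative definite, small grids fall back to dense Cholesky
#' factorization of the covariance matrix; large grids clamp the
#' (negligible) negative spectral mass with a warning.
#'
#' @param height,width grid size, both >= 8.
#' @param sill marginal variance s > 0.
#' @param range_param correlation range r > 0 (pixels).
#' @param seed integer seed; fixed seed gives an identical field.
#' @param mean_level constant added to the field before normalization.
#' @param normalize map the result to `[0, 1]` via [normalize_unit()]
#'   (default); pass `FALSE` to keep the raw scale, on which the empirical
#'   semivariogram matches the analytic `s (1 - exp(-h/r))`.
#' @return A `gray_image`.
#' @export
generate_grf <- function(height, width, sill, range_param, seed,
                         mean_level = 0, normalize = TRUE) {
  stopifnot(height >= 8, width >= 8, sill > 0, range_param > 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  M1 <- 2L * height; M2 <- 2L * width
  di <- pmin(0:(M1 - 1), M1 - (0:(M1 - 1)))
  dj <- pmin(0:(M2 - 1), M2 - (0:(M2 - 1)))
  dist <- sqrt(outer(di^2, dj^2, "+"))
  C <- sill * exp(-dist / range_param)
  lam <- Re(stats::fft(C))
  if (min(lam) < -1e-6 * max(lam)) {
    if (height * width <= 4096) {
      return(grf_dense(height, width, sill, range_param, mean_level,
                       normalize))
    }
    warning("circulant embedding not nonnegative definite; ",
            "clamping negative spectral mass")
  }
  lam[lam < 0] <- 0
  eps <- matrix(complex(real = stats::rnorm(M1 * M2),
                        imaginary = stats::rnorm(M1 * M2)), M1, M2)
  Z <- stats::fft(sqrt(lam / (M1 * M2)) * eps)
  field <- Re(Z)[seq_len(height), seq_len(width)] + mean_level
  img <- gray_image(field)
  if (normalize) normalize_unit(img) else img
}

# Dense-factorization fallback: exact sampling from the covariance matrix.
# Only viable for small grids; the RNG state set by the caller is reused.
grf_dense <- function(height, width, sill, range_param, mean_level,
                      normalize) {
  coords <- expand.grid(r = seq_len(height), c = seq_len(width))
  D <- as.matrix(stats::dist(coords))
  C <- sill * exp(-D / range_param)
  Lch <- chol(C + diag(1e-10, nrow(C)))
  field <- matrix(as.vector(t(Lch) %*% stats::rnorm(nrow(C))),
                  height, width) + mean_level
  img <- gray_image(field)
  if (normalize) normalize_unit(img) else img
}

#' Texture class specification
#'
#' Ground-truth spatial statistics for one diagnostic class of synthetic
#' patches: exponential-covariance parameters plus the range of rectangle
#' sizes to draw.  The default size bounds span the small node-sized
#' rectangles the pipeline is designed for.
#'
#' @param sill marginal variance s > 0.
#' @param range_param correlation range r > 0 (pixels).
#' @param mean_level constant intensity offset (only visible downstream
#'   under a fixed global quantization range; per-ROI normalization removes
#'   it).
#' @param size_min,size_max integer `(height, width)` bounds, inclusive.
#' @return A `texture_class_spec`.
#' @export
texture_class_spec <- function(sill = 1, range_param = 6, mean_level = 0,
                               size_min = c(26L, 18L),
                               size_max = c(122L, 112L)) {
  stopifnot(sill > 0, range_param > 0,
            all(size_min >= 8), all(size_max >= size_min))
  structure(list(sill = sill, range_param = range_param,
                 mean_level = mean_level,
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max)),
            class = "texture_class_spec")
}

#' Generate a two-class synthetic cohort
#'
#' Draws `n_per_class` benign and `n_per_class` malignant rectangular
#' patches.  Each patch is a Gaussian random field with its class's
#' exponential covariance; heights and widths are uniform integers within
#' the class size bounds.  The default design is separable by spatial
#' correlation alone: benign fields are smooth (range 6 pixels), malignant
#' fields rough (range 1.5), both with unit sill — so semivariogram
#' features discriminate while marginal intensity histograms do not.
#' Generation is a pure function of the arguments; every sample's field is
#' driven by a seed derived from `seed` and the sample id.
#'
#' @param n_per_class samples per class, >= 2.
#' @param spec_benign,spec_malignant [texture_class_spec()] per class.
#' @param seed master integer seed.
#' @param normalize pass-through to [generate_grf()].
#' @return A `synthetic_cohort`: list with `samples` (each a list of
#'   `image` and `roi`), plus the generating parameters.
#' @export
generate_cohort <- function(n_per_class,
                            spec_benign = texture_class_spec(
                              range_param = 6,
                              size_min = c(26L, 18L),
                              size_max = c(122L, 112L)),
                            spec_malignant = texture_class_spec(
                              range_param = 1.5,
                              size_min = c(16L, 24L),
                              size_max = c(84L, 85L)),
                            seed = 1, normalize = TRUE) {
  stopifnot(n_per_class >= 2)
  make_class <- function(spec, label) {
    lapply(seq_len(n_per_class), function(i) {
      id <- sprintf("%s_%03d", label, i)
      s <- derive_seed(seed, paste0(id, "_size"))
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(s)
      h <- sample(spec$size_min[1]:spec$size_max[1], 1)
      w <- sample(spec$size_min[2]:spec$size_max[2], 1)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      img <- generate_grf(h, w, spec$sill, spec$range_param,
                          seed = derive_seed(seed, id),
                          mean_level = spec$mean_level,
                          normalize = normalize)
      list(image = img,
           roi = roi_record(id, 0, 0, h, w, label))
    })
  }
  structure(list(samples = c(make_class(spec_benign, "benign"),
                             make_class(spec_malignant, "malignant")),
                 n_per_class = n_per_class,
                 spec_benign = spec_benign,
                 spec_malignant = spec_malignant,
                 seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d benign + %d malignant, seed %d>\n",
              x$n_per_class, x$n_per_class, x$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits one 8-bit PNG per sample plus an ROI table CSV compatible with
#' [read_roi_table()], so a simulated cohort round-trips through the same
#' file interface as real data.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return The ROI CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$samples, function(s) {
    img <- normalize_unit(s$image)
    path <- file.path(dir, paste0(s$roi$image_id, ".png"))
    write_image(gray_image(round(img$pixels * 255),
                           value_range = c(0, 255)), path)
    data.frame(image_id = s$roi$image_id, row0 = s$roi$row0,
               col0 = s$roi$col0, height = s$roi$height,
               width = s$roi$width, label = s$roi$label)
  })
  tab <- do.call(rbind, rows)
  csv <- file.path(dir, "rois.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(csv)
}
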