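#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(f_u = p, f_v = q)` whose locations differ by
#' the given `(drow, dcol)` offset, over all positions where both pixels lie
#' inside the image.  The default offset `(0, 1)` pairs each pixel with its
#' right-hand neighbour on the same row, the single direction used by the
#' headline pipeline.  With `symmetric = TRUE` the transposed pairs are
#' added (the symmetric Haralick convention).
#'
#' @param qimage a `quantized_image` from [quantize()].
#' @param offset integer `(drow, dcol)`, nonzero.
#' @param symmetric also count each pair in the reverse order.
#' @return An object of class `glcm`: `counts` (L x L integer), `probs`
#'   (counts / n_pairs), `offset`, `n_pairs`, `symmetric`, `L`.
#' @export
compute_glcm <- function(qimage, offset = c(0L, 1L), symmetric = FALSE) {
  stopifnot(inherits(qimage, "quantized_image"))
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  if (dr == 0L && dc == 0L) stop("offset must be nonzero")
  lev <- qimage$levels
  L <- qimage$L
  H <- nrow(lev); W <- ncol(lev)
  # valid source positions: (r, c) with (r + dr, c + dc) inside the image
  r1 <- max(1L, 1L - dr); r2 <- min(H, H - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(W, W - dc)
  if (r1 > r2 || c1 > c2)
    stop("image smaller than offset: no pixel pairs at (",
         dr, ", ", dc, ")")
  from <- lev[r1:r2, c1:c2, drop = FALSE]
  to   <- lev[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
  counts <- matrix(0L, L, L)
  tab <- table(factor(from, levels = 1:L), factor(to, levels = 1:L))
  counts <- counts + unclass(tab)
  if (symmetric) counts <- counts + t(counts)
  counts <- matrix(as.integer(counts), L, L)
  n_pairs <- sum(counts)
  structure(list(counts = counts,
                 probs = counts / n_pairs,
                 offset = c(dr, dc), n_pairs = n_pairs,
                 symmetric = symmetric, L = L),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm L = %d, offset (%d, %d), %d pairs%s>\n", x$L,
              x$offset[1], x$offset[2], x$n_pairs,
              if (x$symmetric) ", symmetric" else ""))
  invisible(x)
}

# x log x with the 0 log 0 = 0 convention
xlogx <- function(p, base) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log(p[nz], base = base)
  out
}

#' Texture features from a co-occurrence matrix
#'
#' Computes either the four classical descriptors (`basic4`: contrast,
#' correlation, energy, homogeneity) or the full descriptor set (`full20`)
#' in a frozen, versioned order:
#' entropy, energy, correlation, contrast, sum of squares (variance), sum
#' average, sum variance, sum entropy, difference variance, difference
#' entropy, the two information measures of correlation, autocorrelation,
#' dissimilarity, homogeneity, cluster prominence, cluster shade, maximum
#' probability, inverse difference, inverse difference normalized, inverse
#' difference moment normalized.
#'
#' Definitions, with `P` the normalized GLCM, `p,q` gray levels `1..L`,
#' marginals `px, py`, means `mux, muy`, sds `sx, sy`, and diagonal /
#' cross-diagonal marginals `p_{x+y}`, `p_{x-y}`:
#' energy `sum P^2`; contrast `sum (p-q)^2 P`; correlation
#' `sum (p-mux)(q-muy) P / (sx sy)`; homogeneity `sum P / (1+|p-q|)`;
#' entropy `-sum P log P`; sum average `sum k p_{x+y}(k)`; sum variance is
#' taken about the sum average; difference variance is the variance of
#' `p_{x-y}`; autocorrelation `sum pq P`; dissimilarity `sum |p-q| P`;
#' cluster shade and prominence are the 3rd and 4th central cross moments;
#' inverse difference `sum P / (1+|p-q|)` (numerically identical to
#' homogeneity under these conventions, both kept for completeness of the
#' descriptor list); inverse difference normalized and moment normalized
#' damp by `|p-q|/L` and `(p-q)^2/L^2`.
#'
#' The two information measures of correlation are both returned by
#' default (21 values for `full20`); pass `imc = "one"` to keep only the
#' first, giving a strict count of 20.
#'
#' Degenerate marginals (a constant image: `sx` or `sy` zero) yield
#' correlation and information measures of 0 with a warning rather than an
#' error, so constant ROIs pass through the pipeline.
#'
#' @param glcm a `glcm` from [compute_glcm()].
#' @param set `"basic4"` or `"full20"`.
#' @param base logarithm base for the entropy-type features (natural log
#'   by default; the choice only rescales those features).
#' @param imc `"both"` or `"one"` information measure(s) of correlation.
#' @return Named numeric vector of features.
#' @export
glcm_features <- function(glcm, set = c("full20", "basic4"),
                          base = exp(1), imc = c("both", "one")) {
  set <- match.arg(set)
  imc <- match.arg(imc)
  stopifnot(inherits(glcm, "glcm"))
  P <- glcm$probs
  L <- glcm$L
  if (sum(P) == 0) stop("empty GLCM")
  p <- matrix(1:L, L, L)        # row index (first level)
  q <- t(p)                     # col index (second level)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sx <- sqrt(sum(((1:L) - mux)^2 * px))
  sy <- sqrt(sum(((1:L) - muy)^2 * py))

  contrast <- sum((p - q)^2 * P)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + abs(p - q)))
  degenerate <- (sx == 0 || sy == 0)
  correlation <- if (degenerate) {
    warning("constant marginal: correlation set to 0")
    0
  } else sum((p - mux) * (q - muy) * P) / (sx * sy)

  if (set == "basic4") {
    return(c(glcm_contrast = contrast, glcm_correlation = correlation,
             glcm_energy = energy, glcm_homogeneity = homogeneity))
  }

  entropy <- -sum(xlogx(P, base))
  # marginal distributions of p+q (2..2L) and |p-q| (0..L-1)
  pxy_sum <- vapply(2:(2 * L), function(k) sum(P[p + q == k]), 0.0)
  pxy_dif <- vapply(0:(L - 1), function(k) sum(P[abs(p - q) == k]), 0.0)
  ks <- 2:(2 * L); kd <- 0:(L - 1)
  sum_average <- sum(ks * pxy_sum)
  sum_variance <- sum((ks - sum_average)^2 * pxy_sum)
  sum_entropy <- -sum(xlogx(pxy_sum, base))
  dif_mean <- sum(kd * pxy_dif)
  difference_variance <- sum((kd - dif_mean)^2 * pxy_dif)
  difference_entropy <- -sum(xlogx(pxy_dif, base))

  if (degenerate) {
    imc1 <- imc2 <- 0
  } else {
    hx <- -sum(xlogx(px, base)); hy <- -sum(xlogx(py, base))
    pxpy <- outer(px, py)
    lg <- matrix(0, L, L)
    nz <- pxpy > 0
    lg[nz] <- log(pxpy[nz], base = base)
    hxy1 <- -sum(P * lg)
    hxy2 <- -sum(pxpy[nz] * lg[nz])
    imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
    arg <- 1 - exp(-2 * (hxy2 - entropy) * log(base))
    imc2 <- sqrt(max(arg, 0))
  }

  sum_of_squares <- sum((p - mux)^2 * P)
  autocorrelation <- sum(p * q * P)
  dissimilarity <- sum(abs(p - q) * P)
  cshade <- sum((p + q - mux - muy)^3 * P)
  cprom <- sum((p + q - mux - muy)^4 * P)
  maxprob <- max(P)
  inv_difference <- sum(P / (1 + abs(p - q)))
  idn <- sum(P / (1 + abs(p - q) / L))
  idmn <- sum(P / (1 + (p - q)^2 / L^2))

  out <- c(glcm_entropy = entropy, glcm_energy = energy,
           glcm_correlation = correlation, glcm_contrast = contrast,
           glcm_sum_of_squares = sum_of_squares,
           glcm_sum_average = sum_average, glcm_sum_variance = sum_variance,
           glcm_sum_entropy = sum_entropy,
           glcm_difference_variance = difference_variance,
           glcm_difference_entropy = difference_entropy,
           glcm_imc1 = imc1, glcm_imc2 = imc2,
           glcm_autocorrelation = autocorrelation,
           glcm_dissimilarity = dissimilarity,
           glcm_homogeneity = homogeneity,
           glcm_cluster_prominence = cprom, glcm_cluster_shade = cshade,
           glcm_maximum_probability = maxprob,
           glcm_inverse_difference = inv_difference,
           glcm_inverse_difference_normalized = idn,
           glcm_inverse_difference_moment_normalized = idmn)
  if (imc == "one") out <- out[names(out) != "glcm_imc2"]
  out
}
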