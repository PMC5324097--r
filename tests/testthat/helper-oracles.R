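# Independent brute-force oracles, written against the definitions only.
# They deliberately avoid the package's vectorized code paths: everything
# is explicit double loops over the co-occurrence table / score pairs.

# All descriptors from a normalized L x L co-occurrence table, natural log.
oracle_glcm_features <- function(P) {
  L <- nrow(P)
  px <- numeric(L); py <- numeric(L)
  for (p in 1:L) for (q in 1:L) {
    px[p] <- px[p] + P[p, q]
    py[q] <- py[q] + P[p, q]
  }
  mux <- 0; muy <- 0
  for (p in 1:L) { mux <- mux + p * px[p]; muy <- muy + p * py[p] }
  sx2 <- 0; sy2 <- 0
  for (p in 1:L) { sx2 <- sx2 + (p - mux)^2 * px[p]
                   sy2 <- sy2 + (p - muy)^2 * py[p] }
  sx <- sqrt(sx2); sy <- sqrt(sy2)

  lg <- function(v) if (v > 0) log(v) else 0
  ent <- 0; ene <- 0; con <- 0; cor <- 0; hom <- 0; ssq <- 0
  aut <- 0; dis <- 0; csh <- 0; cpr <- 0; mxp <- 0
  ind <- 0; idn <- 0; idmn <- 0
  for (p in 1:L) for (q in 1:L) {
    v <- P[p, q]
    ent <- ent - v * lg(v)
    ene <- ene + v^2
    con <- con + (p - q)^2 * v
    if (sx > 0 && sy > 0) cor <- cor + (p - mux) * (q - muy) * v / (sx * sy)
    hom <- hom + v / (1 + abs(p - q))
    ssq <- ssq + (p - mux)^2 * v
    aut <- aut + p * q * v
    dis <- dis + abs(p - q) * v
    csh <- csh + (p + q - mux - muy)^3 * v
    cpr <- cpr + (p + q - mux - muy)^4 * v
    if (v > mxp) mxp <- v
    ind <- ind + v / (1 + abs(p - q))
    idn <- idn + v / (1 + abs(p - q) / L)
    idmn <- idmn + v / (1 + (p - q)^2 / L^2)
  }
  psum <- numeric(2 * L); pdif <- numeric(L)         # k and k+1 indexing
  for (p in 1:L) for (q in 1:L) {
    psum[p + q] <- psum[p + q] + P[p, q]
    pdif[abs(p - q) + 1] <- pdif[abs(p - q) + 1] + P[p, q]
  }
  sa <- 0; for (k in 2:(2 * L)) sa <- sa + k * psum[k]
  svr <- 0; for (k in 2:(2 * L)) svr <- svr + (k - sa)^2 * psum[k]
  se <- 0; for (k in 2:(2 * L)) se <- se - psum[k] * lg(psum[k])
  dm <- 0; for (k in 0:(L - 1)) dm <- dm + k * pdif[k + 1]
  dv <- 0; for (k in 0:(L - 1)) dv <- dv + (k - dm)^2 * pdif[k + 1]
  de <- 0; for (k in 0:(L - 1)) de <- de - pdif[k + 1] * lg(pdif[k + 1])

  if (sx > 0 && sy > 0) {
    hx <- 0; hy <- 0
    for (p in 1:L) { hx <- hx - px[p] * lg(px[p]); hy <- hy - py[p] * lg(py[p]) }
    hxy1 <- 0; hxy2 <- 0
    for (p in 1:L) for (q in 1:L) {
      hxy1 <- hxy1 - P[p, q] * lg(px[p] * py[q])
      hxy2 <- hxy2 - px[p] * py[q] * lg(px[p] * py[q])
    }
    imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
    imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  } else {
    imc1 <- 0; imc2 <- 0
  }

  c(glcm_entropy = ent, glcm_energy = ene, glcm_correlation = cor,
    glcm_contrast = con, glcm_sum_of_squares = ssq, glcm_sum_average = sa,
    glcm_sum_variance = svr, glcm_sum_entropy = se,
    glcm_difference_variance = dv, glcm_difference_entropy = de,
    glcm_imc1 = imc1, glcm_imc2 = imc2, glcm_autocorrelation = aut,
    glcm_dissimilarity = dis, glcm_homogeneity = hom,
    glcm_cluster_prominence = cpr, glcm_cluster_shade = csh,
    glcm_maximum_probability = mxp, glcm_inverse_difference = ind,
    glcm_inverse_difference_normalized = idn,
    glcm_inverse_difference_moment_normalized = idmn)
}

# Brute-force co-occurrence counts at an offset, ordered pairs.
oracle_glcm_counts <- function(lev, L, dr, dc) {
  counts <- matrix(0L, L, L)
  H <- nrow(lev); W <- ncol(lev)
  for (r in 1:H) for (c in 1:W) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W)
      counts[lev[r, c], lev[r2, c2]] <- counts[lev[r, c], lev[r2, c2]] + 1L
  }
  counts
}

# AUC as P(score_pos > score_neg) + 0.5 P(tie), by full pair enumeration.
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Expected-cost minimizing vertex of an ROC by exhaustive search.
oracle_min_cost_vertex <- function(fpr, tpr, cost_fn, cost_fp, P, N) {
  cost <- cost_fn * (1 - tpr) * P + cost_fp * fpr * N
  best <- which(cost <= min(cost) + 1e-12)
  best[which.min(fpr[best])]
}

# Brute-force semivariogram over horizontal+vertical pairs.
oracle_semivariogram <- function(x, h) {
  H <- nrow(x); W <- ncol(x)
  ss <- 0; m <- 0
  for (r in 1:H) for (c in 1:(W - h)) {
    ss <- ss + (x[r, c] - x[r, c + h])^2; m <- m + 1
  }
  if (H > h)
    for (r in 1:(H - h)) for (c in 1:W) {
      ss <- ss + (x[r, c] - x[r + h, c])^2; m <- m + 1
    }
  ss / (2 * m)
}

# random score/label sets, some with heavy ties
random_score_set <- function(n, tie_prob = 0.3) {
  scores <- if (stats::runif(1) < tie_prob)
    sample(seq(0, 1, by = 0.1), n, replace = TRUE)
  else stats::runif(n)
  y <- sample(c(0L, 1L), n, replace = TRUE)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(scores = scores, y = y)
}

feature_matrix_for_test <- function(tab)
  as.matrix(tab[, setdiff(names(tab), c("image_id", "label")),
                drop = FALSE])
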