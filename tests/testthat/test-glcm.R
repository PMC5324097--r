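qimg <- function(m, L = max(m)) {
  structure(list(levels = matrix(as.integer(m), nrow(m), ncol(m)),
                 L = as.integer(L)),
            class = "quantized_image")
}

test_that("co-occurrence counts match hand-counted pairs", {
  g <- compute_glcm(qimg(matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE)))
  expect_equal(g$counts[1, 1], 1L)
  expect_equal(g$counts[2, 2], 1L)
  expect_equal(g$n_pairs, 2)
  expect_equal(diag(g$probs), c(0.5, 0.5))
  expect_equal(sum(g$probs), 1)
})

test_that("constant images give a single-cell distribution", {
  g <- compute_glcm(qimg(matrix(1, 5, 5), L = 4))
  expect_equal(g$probs[1, 1], 1)
  expect_equal(sum(g$probs), 1)
})

test_that("symmetric mode yields a symmetric probability table", {
  set.seed(7)
  q <- qimg(matrix(sample(1:5, 64, replace = TRUE), 8, 8), L = 5)
  g <- compute_glcm(q, symmetric = TRUE)
  expect_equal(g$probs, t(g$probs))
  expect_equal(sum(g$probs), 1)
})

test_that("counts agree with a brute-force pair scan at several offsets", {
  set.seed(21)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(0L, 2L),
                   c(-1L, 1L))) {
    q <- qimg(matrix(sample(1:4, 45, replace = TRUE), 9, 5), L = 4)
    g <- compute_glcm(q, offset = off)
    expect_equal(g$counts, oracle_glcm_counts(q$levels, 4, off[1], off[2]),
                 info = paste(off, collapse = ","))
  }
  expect_error(compute_glcm(qimg(matrix(1:2, 1, 2), L = 2),
                            offset = c(0L, 5L)), "no pixel pairs")
  expect_error(compute_glcm(qimg(matrix(1:2, 1, 2), L = 2),
                            offset = c(0L, 0L)), "nonzero")
})

test_that("degenerate and closed-form feature values are exact", {
  g <- compute_glcm(qimg(matrix(1, 4, 4), L = 3))
  f <- suppressWarnings(glcm_features(g))
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_maximum_probability"]), 1)
  expect_warning(glcm_features(g), "constant marginal")

  # row 1 1 2 2 1 1 2 2 1 visits all four cells equally: uniform 2x2 table
  g2 <- compute_glcm(qimg(matrix(c(1, 1, 2, 2, 1, 1, 2, 2, 1), 1), L = 2))
  expect_equal(g2$probs, matrix(0.25, 2, 2))
  f2 <- glcm_features(g2)
  expect_equal(unname(f2["glcm_energy"]), 0.25)
  expect_equal(unname(f2["glcm_entropy"]), log(4))
  f2b <- glcm_features(g2, base = 2)
  expect_equal(unname(f2b["glcm_entropy"]), 2)
})

test_that("all descriptors match the brute-force oracle on random images", {
  set.seed(42)
  for (i in 1:50) {
    q <- qimg(matrix(sample(1:8, 256, replace = TRUE), 16, 16), L = 8)
    g <- compute_glcm(q)
    full <- glcm_features(g, set = "full20")
    expect_equal(full, oracle_glcm_features(g$probs), tolerance = 1e-10)
    basic <- glcm_features(g, set = "basic4")
    expect_equal(unname(basic["glcm_contrast"]),
                 unname(full["glcm_contrast"]), tolerance = 1e-10)
    expect_equal(unname(basic["glcm_correlation"]),
                 unname(full["glcm_correlation"]), tolerance = 1e-10)
    expect_equal(unname(basic["glcm_energy"]),
                 unname(full["glcm_energy"]), tolerance = 1e-10)
    expect_equal(unname(basic["glcm_homogeneity"]),
                 unname(full["glcm_homogeneity"]), tolerance = 1e-10)
  }
})

test_that("contrast vanishes exactly when all mass sits on the diagonal", {
  g_diag <- compute_glcm(qimg(matrix(rep(c(1, 2, 3), each = 4), 3, 4,
                                     byrow = TRUE), L = 3))
  expect_true(all(g_diag$counts[row(g_diag$counts) !=
                                  col(g_diag$counts)] == 0))
  expect_equal(unname(glcm_features(g_diag)["glcm_contrast"]), 0)

  g_off <- compute_glcm(qimg(matrix(c(1, 2, 1, 2), 1), L = 2))
  expect_gt(unname(glcm_features(g_off)["glcm_contrast"]), 0)
})

test_that("the imc switch controls the descriptor count", {
  set.seed(3)
  q <- qimg(matrix(sample(1:8, 144, replace = TRUE), 12, 12), L = 8)
  g <- compute_glcm(q)
  expect_length(glcm_features(g, set = "full20", imc = "both"), 21)
  expect_length(glcm_features(g, set = "full20", imc = "one"), 20)
  expect_length(glcm_features(g, set = "basic4"), 4)
})
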