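test_that("patch distance is zero on identity, symmetric, and hand-exact", {
  set.seed(13)
  a <- matrix(stats::runif(25), 5, 5)
  b <- matrix(stats::runif(25), 5, 5)
  expect_equal(patch_distance(a, a), 0)
  expect_equal(patch_distance(a, b), patch_distance(b, a))
  expect_gt(patch_distance(a, b), 0)
  # 1x2 regions [0,1] vs [0,0], unweighted: one squared diff of 1 over 2 px
  expect_equal(patch_distance(matrix(c(0, 1), 1), matrix(c(0, 0), 1),
                              kernel = "plain_ssd"), 0.5)
  # masked: only the agreeing pixel counts
  expect_equal(patch_distance(matrix(c(0, 1), 1), matrix(c(0, 0), 1),
                              mask = matrix(c(TRUE, FALSE), 1),
                              kernel = "plain_ssd"), 0)
  expect_error(patch_distance(a, b, mask = matrix(FALSE, 5, 5)),
               "empty valid mask")
  expect_error(patch_distance(a, matrix(0, 2, 2)), "same shape")
})

test_that("candidate sets apply the (1 + eps) d_min rule", {
  cs <- candidate_set(c(0.5, 0.54, 1.0), tolerance = 0.1)
  expect_equal(cs$indices, c(1L, 2L))      # threshold 0.55
  expect_equal(cs$d_min, 0.5)
  expect_equal(candidate_set(rep(0.3, 5), 0)$indices, 1:5)
  expect_equal(candidate_set(c(0.2, 0.5, 0.9), 0)$indices, 1L)
  # d_min = 0: all exact matches are candidates
  expect_equal(candidate_set(c(0, 1, 0), 0.1)$indices, c(1L, 3L))
  expect_error(candidate_set(numeric(0)), "empty")
  expect_error(candidate_set(c(1, NA)), "non-finite")
})

test_that("a constant source synthesizes a constant image of target size", {
  out <- synthesize(matrix(0.42, 12, 12),
                    synthesis_config(64, 48, seed = 3))
  expect_equal(dim(out$pixels), c(64L, 48L))
  expect_true(all(out$pixels == 0.42))
})

test_that("synthesis is seed-deterministic with entropy across seeds", {
  src <- generate_grf(24, 24, sill = 1, range_param = 3, seed = 50)
  cfg <- function(s) synthesis_config(60, 60, patch = 8, overlap = 4,
                                      seed = s)
  a <- synthesize(src, cfg(1)); b <- synthesize(src, cfg(1))
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, synthesize(src, cfg(2))$pixels))
})

test_that("every placed patch honours the tolerance contract", {
  src <- generate_grf(24, 24, sill = 1, range_param = 2, seed = 60)
  out <- synthesize(src, synthesis_config(70, 70, seed = 4,
                                          tolerance = 0.1))
  audit <- attr(out, "audit")
  expect_gt(nrow(audit), 1)
  slack <- 1e-9 * (1 + audit$d_min)
  expect_true(all(audit$d_chosen <= (1 + 0.1) * audit$d_min + slack))
})

test_that("output pixels are a subset of source values, range included", {
  src <- generate_grf(20, 20, sill = 1, range_param = 2, seed = 61)
  out <- synthesize(src, synthesis_config(50, 50, patch = 8, overlap = 4,
                                          seed = 9))
  expect_true(all(out$pixels %in% src$pixels))
  expect_gte(min(out$pixels), min(src$pixels))
  expect_lte(max(out$pixels), max(src$pixels))
})

test_that("plain-SSD kernel and per-pixel mode also satisfy the contracts", {
  src <- generate_grf(20, 20, sill = 1, range_param = 2, seed = 62)
  out <- synthesize(src, synthesis_config(40, 40, patch = 8, overlap = 4,
                                          seed = 5, kernel = "plain_ssd"))
  audit <- attr(out, "audit")
  expect_true(all(audit$d_chosen <=
                    1.1 * audit$d_min + 1e-9 * (1 + audit$d_min)))

  px <- synthesize(src, synthesis_config(26, 26, patch = 7, overlap = 3,
                                         seed = 6, mode = "pixel"))
  expect_equal(dim(px$pixels), c(26L, 26L))
  expect_true(all(px$pixels %in% src$pixels))
  px2 <- synthesize(src, synthesis_config(26, 26, patch = 7, overlap = 3,
                                          seed = 6, mode = "pixel"))
  expect_identical(px$pixels, px2$pixels)
})

test_that("degenerate configurations are rejected", {
  expect_error(synthesis_config(50, 50, patch = 10, overlap = 10))
  expect_error(synthesis_config(50, 50, patch = 10, overlap = 0))
  expect_error(synthesis_config(5, 50, patch = 10))
  expect_error(synthesize(matrix(1, 4, 4), synthesis_config(50, 50)),
               "smaller than the patch")
})

test_that("synthesized textures preserve the source semivariogram shape", {
  devs <- vapply(1:3, function(i) {
    src <- generate_grf(32, 32, sill = 1, range_param = 3, seed = 100 + i)
    out <- synthesize(src, synthesis_config(120, 120, seed = 200 + i))
    gs <- empirical_semivariogram(src, 10)$gamma
    go <- empirical_semivariogram(out, 10)$gamma
    stats::median(abs(go - gs) / gs)
  }, 0.0)
  expect_lt(stats::median(devs), 0.25)
})
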