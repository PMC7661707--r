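test_that("bounding_box follows the half-open convention", {
  m <- matrix(FALSE, 10, 10); m[5, 7] <- TRUE
  expect_equal(unname(bounding_box(m)), c(5, 6, 7, 8))

  m2 <- matrix(TRUE, 6, 9)
  expect_equal(unname(bounding_box(m2)), c(1, 7, 1, 10))

  m3 <- matrix(FALSE, 12, 12)
  m3[2:8, 3:4] <- TRUE; m3[2:8, 9] <- TRUE   # L/union shape
  expect_equal(unname(bounding_box(m3)), c(2, 9, 3, 10))

  expect_error(bounding_box(matrix(FALSE, 3, 3), id = "S9/2"), "S9/2")
})

test_that("quantize bins equal-width and handles degenerate input", {
  expect_true(all(quantize(matrix(3.7, 5, 5), 32) == 1L))
  two <- quantize(matrix(c(0, 100, 0, 100), 2, 2), 2)
  expect_equal(sort(unique(as.vector(two))), c(1L, 2L))
  ramp <- matrix(rep(0:31, each = 4), 4, 32)
  q <- quantize(ramp, 32)
  expect_equal(q[1, ], 1:32)
  expect_equal(unname(table(q)), rep(4L, 32), ignore_attr = TRUE)
})

test_that("texture matrices match hand-enumerated fixtures", {
  cfg <- texture_config(n_gray_levels = 2)
  img <- matrix(c(1, 2, 1, 2), 2, 2)  # rows [1,1] and [2,2]
  P <- texture_matrix(img, "GLCM", cfg, offset = c(0L, 1L))
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2), ignore_attr = TRUE)

  rl <- texture_matrix(matrix(c(1, 1, 2, 2), 1, 4), "GLRLM", cfg,
                       offset = c(0L, 1L))
  expect_equal(rl[1, 2], 1); expect_equal(rl[2, 2], 1)
  expect_equal(sum(rl), 2)

  sz <- texture_matrix(matrix(1L, 4, 4), "GLSZM", cfg)
  expect_equal(sz[1, 16], 1)
  expect_equal(sum(sz), 1)

  expect_error(texture_matrix(img, "FOO", cfg), "unknown")
})

test_that("texture_features: manifest, degenerate limits, oracle spot checks", {
  set.seed(3)
  roi <- matrix(runif(64), 8, 8)
  v <- texture_features(roi)
  expect_length(v, 42)
  expect_true(all(is.finite(v)))
  expect_equal(sum(startsWith(names(v), "glcm_")), 11)
  expect_equal(sum(startsWith(names(v), "glrlm_")), 13)
  expect_equal(sum(startsWith(names(v), "glszm_")), 13)
  expect_equal(sum(startsWith(names(v), "ngtdm_")), 5)

  cf <- texture_features(matrix(5, 6, 6))
  expect_equal(unname(cf["glcm_energy"]), 1)
  expect_equal(unname(cf["glcm_contrast"]), 0)
  expect_equal(unname(cf["glcm_entropy"]), 0)

  # 4x4 checkerboard at 2 levels vs the independent loop oracle
  chk <- matrix(rep(c(1, 2), 8), 4, 4)
  chk[, c(2, 4)] <- 3 - chk[, c(2, 4)]
  got <- texture_features(chk, texture_config(n_gray_levels = 2))
  want <- oracle_texture_features(quantize(chk, 2), 2)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)

  expect_error(texture_features(matrix(1, 1, 5)), "2x2")
})

test_that("minkowski features match hand-computable geometry", {
  img <- matrix(0, 9, 9); msk <- matrix(FALSE, 9, 9)
  msk[3:7, 3:7] <- TRUE; img[msk] <- 1
  mf <- minkowski_features(img, msk, minkowski_config(1))
  expect_equal(unname(mf), c(25, 20, 1))

  # 1x1 hole in the middle
  img2 <- img; img2[5, 5] <- 0
  mf2 <- minkowski_features(img2, msk, minkowski_config(2))
  expect_equal(unname(mf2["Area2"]), 24)
  expect_equal(unname(mf2["Euler2"]), 0)
  expect_equal(unname(mf2["Perimeter2"]), 24)  # outer 20 + hole 4

  # two disjoint 2x2 squares
  msk3 <- matrix(FALSE, 8, 8); msk3[1:2, 1:2] <- TRUE; msk3[5:6, 5:6] <- TRUE
  img3 <- matrix(1, 8, 8)
  mf3 <- minkowski_features(img3, msk3, minkowski_config(1))
  expect_equal(unname(mf3), c(8, 16, 2))

  expect_error(minkowski_features(img, matrix(FALSE, 9, 9)), "empty mask")
})

test_that("minkowski area is non-increasing across thresholds", {
  co <- small_cohort()
  for (rec in co$slices[1:4]) {
    mf <- minkowski_features(rec$image, rec$mask)
    areas <- mf[paste0("Area", 1:16)]
    expect_true(all(diff(areas) <= 0))
    expect_gte(unname(mf["Area16"]), 1)  # >= comparison keeps the max pixel
    expect_equal(unname(mf["Area1"]), sum(rec$mask))
  }
})

test_that("features are invariant to mask translation", {
  set.seed(9)
  block <- matrix(runif(15 * 15), 15, 15)
  make <- function(r, c) {
    img <- matrix(0.5, 50, 50); msk <- matrix(FALSE, 50, 50)
    img[r:(r + 14), c:(c + 14)] <- block
    msk[r:(r + 14), c:(c + 14)] <- TRUE
    s <- list(subject_id = "A", slice_index = 1L, label = "control",
              image = img, mask = msk)
    class(s) <- "slice_record"
    extract_slice_features(s)$values
  }
  expect_equal(make(3, 5), make(20, 30))
})

test_that("extract_slice_features yields the 90-feature row", {
  co <- small_cohort()
  fr <- extract_slice_features(co$slices[[1]])
  expect_length(fr$values, 90)
  expect_equal(sum(grepl("^(Area|Perimeter|Euler)", names(fr$values))), 48)
  expect_equal(fr$mask_pixel_count, sum(co$slices[[1]]$mask))
})

test_that("radiomic_feature_table has a stable manifest and metadata", {
  co <- small_cohort()
  ft <- radiomic_feature_table(co)
  expect_equal(nrow(ft), length(co$slices))
  expect_length(attr(ft, "features"), 90)
  expect_true(all(ft$label %in% c("control", "treated")))
  expect_true(all(vapply(ft[, attr(ft, "features")], is.numeric, TRUE)))
  expect_false(anyNA(ft))
})
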