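test_that("make_sources builds distinct nonnegative unit-max profiles", {
  gs <- make_sources(K = 2, L = 512, ppm_range = c(0.5, 4.5), seed = 7)
  expect_true(all(gs$profiles >= 0))
  expect_equal(unname(apply(gs$profiles, 1, max)), c(1, 1))
  expect_true(all(diff(gs$ppm_axis) < 0))
  nrm <- gs$profiles / sqrt(rowSums(gs$profiles^2))
  expect_lt(tcrossprod(nrm)[1, 2], 0.99)

  expect_identical(make_sources(K = 2, L = 512, seed = 7), gs)
  expect_error(make_sources(K = 50, L = 128), "peak templates")
  expect_error(make_sources(K = 1, L = 128))
})

test_that("make_cohort respects the spec and is seed-deterministic", {
  co <- small_cohort()
  sub <- co$subjects
  expect_equal(sum(sub$label == "control"), 6)
  expect_equal(sum(sub$label == "treated"), 6)
  expect_true(all(sub$n_slices[sub$split == "train"] == 1))
  expect_true(all(sub$n_slices[sub$split == "holdout"] %in% 2:3))
  expect_equal(length(co$slices), sum(sub$n_slices))

  co2 <- make_cohort(small_spec(), small_sources())
  expect_identical(co2$slices[[1]]$image, co$slices[[1]]$image)
  expect_identical(co2$slices[[5]]$grid$spectra, co$slices[[5]]$grid$spectra)
  expect_identical(co2$subjects, co$subjects)
})

test_that("paper-scale spec yields 63 subjects split 29/34", {
  spec <- cohort_spec()
  expect_equal(spec$n_control + spec$n_treated, 63)
  expect_equal(spec$n_control, 29)
  expect_equal(spec$n_treated, 34)
})

test_that("in_tumor flags match mask/block geometry", {
  co <- small_cohort()
  rec <- co$slices[[1]]
  bm <- rec$grid$block_map
  manual <- vapply(seq_len(nrow(bm)), function(i) {
    all(rec$mask[bm$r0[i]:(bm$r1[i] - 1L), bm$c0[i]:(bm$c1[i] - 1L)])
  }, logical(1))
  expect_identical(rec$grid$in_tumor, manual)
  # blocks are disjoint and inside the image
  expect_true(all(bm$r0 >= 1 & bm$r1 <= nrow(rec$image) + 1))
  expect_true(all(bm$c0 >= 1 & bm$c1 <= ncol(rec$image) + 1))
  px <- unlist(lapply(seq_len(nrow(bm)), function(i) {
    outer((bm$r0[i]:(bm$r1[i] - 1)), (bm$c0[i]:(bm$c1[i] - 1)) * 10000, "+")
  }))
  expect_equal(anyDuplicated(px), 0)
})

test_that("zero-noise in-tumor spectra lie exactly in the source span", {
  gs <- small_sources()
  spec <- small_spec(seed = 77L, noise_sd = 0)
  co <- make_cohort(spec, gs)
  rec <- co$slices[[1]]
  gt <- co$mixing[[names(co$slices)[1]]]
  keep <- which(rec$grid$in_tumor)
  expect_equal(nrow(gt), length(keep))
  H <- as.matrix(gt[, -(1:2)])
  expect_true(all(H >= 0))
  recon <- H %*% gs$profiles
  expect_equal(unname(rec$grid$spectra[keep, ]), unname(recon),
               tolerance = 1e-12)
})

test_that("treated images carry more hypointense structure than control", {
  co <- small_cohort()
  frac_dark <- vapply(co$slices, function(s) {
    v <- s$image[s$mask]
    mean(v < 0.55)  # tumor base intensity is ~0.78
  }, numeric(1))
  labs <- vapply(co$slices, `[[`, "", "label")
  expect_gt(mean(frac_dark[labs == "treated"]),
            mean(frac_dark[labs == "control"]))
})

test_that("disjoint zero-noise mixing is linearly separable at voxel level", {
  gs <- small_sources()
  spec <- small_spec(seed = 55L, noise_sd = 0)
  spec$class_mixing <- list(control = c(0, 5, 0, 1.5),
                            treated = c(5, 0, 1.5, 0))
  co <- make_cohort(spec, gs)
  H <- do.call(rbind, lapply(names(co$mixing), function(k) {
    m <- co$mixing[[k]]
    if (nrow(m) == 0) return(NULL)
    cbind(as.matrix(m[, -(1:2)]),
          y = if (co$slices[[k]]$label == "treated") 1 else -1)
  }))
  X <- H[, 1:4]; y <- H[, "y"]
  mod <- train_linear(X, y, "lda")
  expect_equal(mean(score_to_label(predict(mod, X)) == y), 1)
})

test_that("write_cohort round-trips files to disk", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  # subset: keep it light
  mini <- co
  mini$slices <- co$slices[1:2]
  mini$mixing <- co$mixing[1:2]
  write_cohort(mini, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth_mixing.csv")))
  key <- names(mini$slices)[1]
  img <- png::readPNG(file.path(dir, "images", paste0(key, ".png")))
  expect_equal(dim(img), dim(mini$slices[[1]]$image))
  sp <- utils::read.csv(file.path(dir, "spectra", paste0(key, ".csv")))
  expect_equal(nrow(sp), 100)
  expect_equal(ncol(sp), 3 + 128)
})
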