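test_that("select_tumor_spectra keeps exactly the tumor-complete voxels", {
  s_all <- toy_slice(mask_all = TRUE)
  sm <- select_tumor_spectra(s_all)
  expect_equal(nrow(sm$X), 100)
  # row-major deterministic order
  expect_equal(sm$row_ids$row, rep(1:10, each = 10))
  expect_equal(sm$row_ids$col, rep(1:10, 10))

  s_none <- toy_slice()
  s_none$mask[] <- FALSE
  s_none$mask[1, 1] <- TRUE          # nonempty but covers no block
  expect_warning(sm0 <- select_tumor_spectra(s_none), "excluded")
  expect_equal(nrow(sm0$X), 0)

  # central blocks only: mask covering exactly blocks (4:6, 4:6)
  s3 <- toy_slice()
  bm <- s3$grid$block_map
  s3$mask[] <- FALSE
  sel <- bm$row %in% 4:6 & bm$col %in% 4:6
  for (i in which(sel)) {
    s3$mask[bm$r0[i]:(bm$r1[i] - 1), bm$c0[i]:(bm$c1[i] - 1)] <- TRUE
  }
  s3$grid$in_tumor <- sel
  expect_equal(nrow(select_tumor_spectra(s3)$X), 9)
})

test_that("convex NMF recovers an exact factorization to machine precision", {
  gs <- small_sources()
  X <- gs$profiles[rep(1:4, each = 8), ]
  ss <- fit_convex_nmf(X, K = 4, seed = 3)
  expect_lt(utils::tail(ss$error_trace, 1), 1e-6)
  expect_true(all(ss$W >= 0))
  expect_true(all(ss$G >= 0))
  expect_true(all(diff(ss$error_trace) <= 1e-8))
  mm <- match_sources(ss$F, gs$profiles)
  expect_true(all(mm$cosine >= 0.999))
  # seeded determinism
  ss2 <- fit_convex_nmf(X, K = 4, seed = 3)
  expect_identical(ss$F, ss2$F)
  expect_identical(ss$error_trace, ss2$error_trace)
})

test_that("convex NMF input contracts", {
  X <- matrix(runif(40), 4, 10)
  expect_error(fit_convex_nmf(X, K = 5), "exceeds")
  X[1, 1] <- NA
  expect_error(fit_convex_nmf(X, K = 2), "non-finite")
})

test_that("source recovery from noisy class-mixed spectra", {
  gs <- small_sources()
  set.seed(21)
  conc <- default_class_mixing(4)
  H <- rbind(
    t(replicate(150, glioresponse:::.rmix(conc$control))),
    t(replicate(150, glioresponse:::.rmix(conc$treated))))
  X <- H %*% gs$profiles +
    matrix(rnorm(300 * 128, 0, 0.05), 300, 128)   # 5% of unit peak amplitude
  ss <- fit_convex_nmf(X, K = 4, seed = 5)
  mm <- match_sources(ss$F, gs$profiles)
  expect_gte(mean(mm$cosine), 0.95)
  # projection of training spectra approximates the fitted mixing matrix
  W <- project_spectra(X, ss)
  rowcos <- vapply(seq_len(nrow(W)), function(i) {
    a <- W[i, ]; b <- ss$G[i, ]
    if (sum(a) == 0 || sum(b) == 0) return(1)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_gte(mean(rowcos), 0.95)
})

test_that("NNLS projection matches the enumeration oracle and scales", {
  gs <- small_sources()
  Fm <- gs$profiles[1:3, ]
  ss <- list(F = Fm, ppm_axis = gs$ppm_axis, K = 3L)
  class(ss) <- "source_set"

  w <- project_spectra(Fm[3, , drop = FALSE], ss)
  expect_lte(sum(w[1, 1:2]), 1e-8)
  expect_equal(unname(w[1, 3]), 1, tolerance = 1e-8)

  expect_equal(unname(project_spectra(matrix(0, 1, 128), ss))[1, ],
               rep(0, 3))

  w1 <- project_spectra(Fm[1, , drop = FALSE], ss)
  w2 <- project_spectra(2 * Fm[1, , drop = FALSE], ss)
  expect_equal(unname(w2), unname(2 * w1), tolerance = 1e-8)

  # random targets vs brute-force active-set enumeration
  set.seed(12)
  A <- t(Fm)
  for (i in 1:20) {
    b <- rnorm(128, 0, 0.3) + as.numeric(runif(3) %*% Fm)
    expect_equal(nnls_solve(A, b), oracle_nnls(A, b), tolerance = 1e-7)
  }
})

test_that("projection errors on mismatched axes or lengths", {
  gs <- small_sources()
  ss <- fit_convex_nmf(gs$profiles[rep(1:4, each = 4), ], K = 4, seed = 1,
                       ppm_axis = gs$ppm_axis)
  sm <- structure(list(X = matrix(0, 2, 128),
                       ppm_axis = rev(gs$ppm_axis)),
                  class = "spectrum_matrix")
  expect_error(project_spectra(sm, ss), "ppm axis")
  expect_error(project_spectra(matrix(0, 2, 64), ss), "length mismatch")
})
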