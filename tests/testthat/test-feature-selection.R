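make_table <- function(n = 60, effect = 3, p_noise = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c("control", "treated"), each = n / 2)
  X <- cbind(sig1 = ifelse(y == "treated", 1, -1) * effect / 2 + rnorm(n),
             sig2 = ifelse(y == "treated", 1, -1) * effect / 2 + rnorm(n))
  for (i in seq_len(p_noise)) X <- cbind(X, rnorm(n))
  colnames(X) <- c("sig1", "sig2", paste0("noise", seq_len(p_noise)))
  list(X = X, y = y)
}

test_that("ttest_rank orders by |t| with documented edge cases", {
  tb <- make_table()
  X <- cbind(tb$X, flat = rep(1, nrow(tb$X)))
  rk <- ttest_rank(X, tb$y)
  expect_equal(utils::tail(rk$features, 1), "flat")
  expect_equal(utils::tail(rk$scores, 1), 0)
  expect_true(all(diff(rk$scores) <= 0))
  expect_true(all(c("sig1", "sig2") %in% rk$features[1:2]))

  # |t| equals the hand-evaluated Welch formula on a fixed 6x3 table
  Xf <- matrix(c(1.0, 2.0, 1.5, 4.0, 5.0, 4.5,
                 0.3, 0.1, 0.2, 0.4, 0.2, 0.3,
                 7, 7, 7, 7, 7, 7), 6, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  yf <- c(-1, -1, -1, 1, 1, 1)
  rkf <- ttest_rank(Xf, yf)
  want_a <- oracle_welch_t(Xf[4:6, "a"], Xf[1:3, "a"])
  expect_equal(rkf$scores[match("a", rkf$features)], want_a)
  expect_equal(rkf$scores[match("c", rkf$features)], 0)
})

test_that("embedded relevance is the mean absolute weight", {
  m1 <- list(weights = c(a = 3, b = -1, c = 0.5), intercept = 0)
  class(m1) <- "classifier_model"
  expect_equal(embedded_relevance(list(m1)), c(a = 3, b = 1, c = 0.5))

  m2 <- list(weights = c(a = 1, b = -1), intercept = 0)
  m3 <- list(weights = c(a = -1, b = 1), intercept = 0)
  class(m2) <- class(m3) <- "classifier_model"
  expect_equal(embedded_relevance(list(m2, m3)), c(a = 1, b = 1))

  m4 <- list(weights = c(z = 1, b = -1), intercept = 0)
  class(m4) <- "classifier_model"
  expect_error(embedded_relevance(list(m2, m4)), "manifest")
})

test_that("embedded RFE eliminates constants first and returns nested subsets", {
  tb <- make_table(seed = 4)
  X <- cbind(tb$X[, "sig1", drop = FALSE], konst = rep(5, nrow(tb$X)))
  r <- embedded_rfe(X, tb$y, model_type = "lda", k_folds = 3, seed = 1)
  expect_equal(r$elimination_order[1], "konst")

  r2 <- embedded_rfe(tb$X, tb$y, model_type = "lda", k_folds = 3, seed = 1)
  expect_length(r2$elimination_order, ncol(tb$X))
  for (m in seq_len(length(r2$subsets) - 1)) {
    expect_true(all(r2$subsets[[m]] %in% r2$subsets[[m + 1]]))
  }
})

test_that("wrapper RFE removes an anti-informative feature first", {
  set.seed(8)
  n <- 80
  y <- rep(c("control", "treated"), each = n / 2)
  yy <- ifelse(y == "treated", 1, -1)
  X <- cbind(good1 = yy * 1.5 + rnorm(n),
             good2 = yy * 1.5 + rnorm(n),
             # anti-informative: pure noise that swamps the model
             anti = rnorm(n, 0, 8))
  r <- wrapper_rfe(X, y, model_type = "lda", protocol = "kfold", k = 5,
                   seed = 2)
  expect_equal(r$elimination_order[1], "anti")
  tr <- r$trace
  a3 <- tr$cv_accuracy[tr$subset_size == 3]
  a2 <- tr$cv_accuracy[tr$subset_size == 2]
  expect_gte(a2, a3)
  expect_equal(nrow(tr), 3)
  # wrapper accuracy at the full set equals plain CV accuracy
  full <- cv_evaluate(X, y, seq_len(n), "lda", protocol = "kfold", k = 5,
                      seed = 2)$accuracy
  expect_equal(a3, full)
  # nested subsets by construction
  for (m in 1:2) expect_true(all(r$subsets[[m]] %in% r$subsets[[m + 1]]))
})

test_that("hybrid embedded-then-wrapper truncates to m and recovers signal", {
  tb <- make_table(n = 80, p_noise = 6, seed = 10)
  h <- hybrid_embedded_then_wrapper(tb$X, tb$y, model_type = "lda",
                                    k_folds = 3, protocol = "kfold", k = 5,
                                    m = 4, seed = 1)
  expect_length(h$ranking, 4)
  expect_length(h$embedded_ranking, ncol(tb$X))
  expect_true(all(c("sig1", "sig2") %in% h$ranking))
  expect_equal(h$scheme, "hybrid")

  # m = feature count: wrapper over the full embedded ranking
  h2 <- hybrid_embedded_then_wrapper(tb$X, tb$y, model_type = "lda",
                                     k_folds = 3, protocol = "kfold", k = 5,
                                     m = ncol(tb$X), seed = 1)
  expect_length(h2$ranking, ncol(tb$X))
})

test_that("all three schemes rank a perfectly separating feature first", {
  set.seed(31)
  n <- 40
  y <- rep(c("control", "treated"), each = n / 2)
  X <- cbind(perfect = ifelse(y == "treated", 1, 0) + rnorm(n, 0, 1e-3),
             junk1 = rnorm(n), junk2 = rnorm(n))
  expect_equal(ttest_rank(X, y)$features[1], "perfect")
  expect_equal(embedded_rfe(X, y, model_type = "lda", k_folds = 4,
                            seed = 1)$ranking[1], "perfect")
  expect_equal(wrapper_rfe(X, y, model_type = "lda", protocol = "kfold",
                           k = 4, seed = 1)$ranking[1], "perfect")
})
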