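# Feature selection: univariate Welch t-test filter, embedded recursive
# feature elimination (relevance = mean |weight| over K fold-trained linear
# models), wrapper RFE (relevance = CV accuracy after removal), and the
# hybrid embedded-then-wrapper chain used for the low cases-to-features MRI
# setting. All RFE outputs are nested: the subset of size m is contained in
# every subset of size > m.

#' Univariate t-test feature ranking
#'
#' Welch two-sample t per feature between the two classes; features ranked by
#' `|t|` descending, ties broken by feature name. A feature with zero
#' variance in both classes gets score 0 and ranks last.
#'
#' @param X matrix or data frame of features (columns named).
#' @param labels row labels (`control`/`treated` or -1/+1).
#' @return list of class `relevance_ranking`: `features` (names in rank
#'   order), `scores` (|t| in the same order), `scheme = "ttest"`.
#' @export
ttest_rank <- function(X, labels) {
  X <- as.matrix(X)
  y <- .encode_labels(labels)
  stopifnot(sum(y > 0) >= 2, sum(y < 0) >= 2)
  tstat <- apply(X, 2, function(v) {
    a <- v[y > 0]; b <- v[y < 0]
    va <- stats::var(a); vb <- stats::var(b)
    if (va == 0 && vb == 0) return(0)
    se <- sqrt(va / length(a) + vb / length(b))
    if (se == 0) return(0)
    abs(mean(a) - mean(b)) / se
  })
  ord <- order(-tstat, colnames(X))
  structure(list(features = colnames(X)[ord], scores = unname(tstat[ord]),
                 scheme = "ttest"),
            class = "relevance_ranking")
}

#' Embedded relevance from fold-trained linear models
#'
#' Relevance of feature i is the mean over models of `|w_ij|`: irrelevant
#' features move the (monotone-link) classifier output less than relevant
#' ones, and for ranking purposes the link derivative is a common factor that
#' cancels.
#'
#' @param models list of `classifier_model`s sharing one feature manifest.
#' @return named nonnegative score vector.
#' @export
embedded_relevance <- function(models) {
  manifest <- names(models[[1]]$weights)
  for (m in models) {
    if (!identical(names(m$weights), manifest)) {
      stop("feature manifest mismatch across models")
    }
  }
  W <- do.call(rbind, lapply(models, function(m) abs(m$weights)))
  colMeans(W)
}

#' Embedded recursive feature elimination
#'
#' At each step, K linear models are trained on the training side of K
#' grouped stratified folds, features are scored by [embedded_relevance()],
#' and the least relevant one is removed (ties by feature name). Features are
#' z-scored inside [train_linear()], so weight magnitudes are comparable.
#'
#' @param X features (columns named).
#' @param labels row labels.
#' @param groups subject ids (folds never split a subject).
#' @param model_type linear model used for the fold fits.
#' @param k_folds number of folds K.
#' @param seed fold seed.
#' @return list of class `rfe_result`: `elimination_order` (first removed
#'   first), `ranking` (most relevant first, i.e. reversed elimination),
#'   `subsets` (list: subset of each size 1..p, nested), `scheme`.
#' @export
embedded_rfe <- function(X, labels, groups = seq_len(nrow(X)),
                         model_type = "lr", k_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- .encode_labels(labels)
  folds <- make_grouped_folds(groups, labels, k_folds, seed)
  active <- colnames(X)
  eliminated <- character(0)
  while (length(active) > 1) {
    models <- lapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      train_linear(X[tr, active, drop = FALSE], y[tr], model_type)
    })
    rel <- embedded_relevance(models)
    drop_f <- names(rel)[order(rel, names(rel))][1]
    eliminated <- c(eliminated, drop_f)
    active <- setdiff(active, drop_f)
  }
  eliminated <- c(eliminated, active)
  ranking <- rev(eliminated)
  subsets <- lapply(seq_along(ranking), function(m) ranking[seq_len(m)])
  structure(list(elimination_order = eliminated, ranking = ranking,
                 subsets = subsets, scheme = "embedded_rfe"),
            class = "rfe_result")
}

#' Wrapper recursive feature elimination
#'
#' At each step, the grouped-CV accuracy of the classifier is evaluated with
#' each single remaining feature removed; the feature whose removal yields
#' the highest accuracy is eliminated. Ties are broken by lower univariate
#' |t|, then by feature name. The accuracy trace stores the CV accuracy of
#' the retained subset at every size.
#'
#' @inheritParams embedded_rfe
#' @param protocol,k CV protocol passed to [cv_evaluate()].
#' @return `rfe_result` with an extra `trace` data frame
#'   (`subset_size`, `cv_accuracy`).
#' @export
wrapper_rfe <- function(X, labels, groups = seq_len(nrow(X)),
                        model_type = "lr", protocol = "loo", k = 20L,
                        seed = 1L) {
  X <- as.matrix(X)
  y <- .encode_labels(labels)
  tt <- ttest_rank(X, labels)
  tscore <- stats::setNames(tt$scores, tt$features)
  cv_acc <- function(cols) {
    cv_evaluate(X[, cols, drop = FALSE], y, groups, model_type,
                protocol = protocol, k = k, seed = seed)$accuracy
  }
  active <- colnames(X)
  eliminated <- character(0)
  trace <- data.frame(subset_size = length(active),
                      cv_accuracy = cv_acc(active))
  while (length(active) > 1) {
    acc_wo <- vapply(active, function(f) cv_acc(setdiff(active, f)),
                     numeric(1))
    ord <- order(-acc_wo, tscore[active], active)
    drop_f <- active[ord][1]
    eliminated <- c(eliminated, drop_f)
    active <- setdiff(active, drop_f)
    trace <- rbind(trace, data.frame(subset_size = length(active),
                                     cv_accuracy = max(acc_wo)))
  }
  eliminated <- c(eliminated, active)
  ranking <- rev(eliminated)
  subsets <- lapply(seq_along(ranking), function(m) ranking[seq_len(m)])
  structure(list(elimination_order = eliminated, ranking = ranking,
                 subsets = subsets, trace = trace, scheme = "wrapper_rfe"),
            class = "rfe_result")
}

#' Hybrid embedded-then-wrapper selection
#'
#' Runs [embedded_rfe()], keeps only the `m` most relevant features
#' (everything else is discarded outright), then refines within them with
#' [wrapper_rfe()]. This is the scheme for the low cases-to-features MRI
#' setting, where a plain wrapper cannot distinguish feature relevance in the
#' early steps.
#'
#' @inheritParams wrapper_rfe
#' @param k_folds folds for the embedded stage.
#' @param m features retained after the embedded stage (default 30).
#' @return `rfe_result` over the retained features, with `trace` and
#'   `embedded_ranking` (the full embedded stage ranking).
#' @export
hybrid_embedded_then_wrapper <- function(X, labels,
                                         groups = seq_len(nrow(X)),
                                         model_type = "lr", k_folds = 5L,
                                         protocol = "loo", k = 20L,
                                         m = 30L, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(m >= 1, m <= ncol(X))
  emb <- embedded_rfe(X, labels, groups, model_type, k_folds, seed)
  keep <- emb$ranking[seq_len(m)]
  wr <- wrapper_rfe(X[, keep, drop = FALSE], labels, groups, model_type,
                    protocol, k, seed)
  wr$embedded_ranking <- emb$ranking
  wr$scheme <- "hybrid"
  wr
}
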