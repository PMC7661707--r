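# Linear classifiers (logistic regression, LDA, linear SVM) with internal
# z-scoring, and grouped cross-validation (leave-one-subject-out or k-fold
# with all rows of a subject kept in one fold).
#
# Label encoding is fixed across the package: control = -1, treated = +1
# (treated is the positive class). Decision score s = w'x + b; predicted
# label = sign(s), with s = 0 mapped to +1.

.encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(-1, 1)))
    return(as.numeric(labels))
  }
  stopifnot(all(labels %in% c("control", "treated")))
  ifelse(labels == "treated", 1, -1)
}

.zscore_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.zscore_apply <- function(X, zs) {
  sweep(sweep(X, 2, zs$center, "-"), 2, zs$scale, "/")
}

# L2-penalized logistic regression by Newton-Raphson (penalty 1/(2C) |w|^2,
# intercept unpenalized)
.fit_lr <- function(X, y, C = 1) {
  n <- nrow(X); p <- ncol(X)
  Xi <- cbind(1, X)
  beta <- numeric(p + 1)
  lambda <- 1 / C
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  for (it in 1:100) {
    eta <- drop(Xi %*% beta)
    mu <- 1 / (1 + exp(-eta))
    wgt <- pmax(mu * (1 - mu), 1e-10)
    y01 <- (y + 1) / 2
    grad <- drop(crossprod(Xi, y01 - mu)) - pen %*% beta
    hess <- crossprod(Xi * wgt, Xi) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  list(weights = beta[-1], intercept = beta[1])
}

# LDA with pooled covariance (small ridge for stability); intercept includes
# the log prior ratio
.fit_lda <- function(X, y) {
  pos <- X[y > 0, , drop = FALSE]
  neg <- X[y < 0, , drop = FALSE]
  mu_p <- colMeans(pos); mu_n <- colMeans(neg)
  n <- nrow(X); p <- ncol(X)
  S <- ((nrow(pos) - 1) * stats::cov(pos) +
          (nrow(neg) - 1) * stats::cov(neg)) / (n - 2)
  S <- S + diag(1e-6 * (sum(diag(S)) / p + 1e-12), p)
  w <- solve(S, mu_p - mu_n)
  b <- -sum(w * (mu_p + mu_n)) / 2 + log(nrow(pos) / nrow(neg))
  list(weights = drop(w), intercept = b)
}

# linear SVM, L2-regularized squared hinge, solved by BFGS (smooth objective;
# deterministic from the zero start)
.fit_svm <- function(X, y, C = 1) {
  n <- nrow(X); p <- ncol(X)
  obj <- function(th) {
    w <- th[-1]; b <- th[1]
    m <- 1 - y * (drop(X %*% w) + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  grd <- function(th) {
    w <- th[-1]; b <- th[1]
    m <- 1 - y * (drop(X %*% w) + b)
    act <- m > 0
    gw <- w - 2 * C * drop(crossprod(X[act, , drop = FALSE],
                                     (y * m)[act]))
    gb <- -2 * C * sum((y * m)[act])
    c(gb, gw)
  }
  fit <- stats::optim(numeric(p + 1), obj, grd, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(weights = fit$par[-1], intercept = fit$par[1])
}

#' Train a linear classifier
#'
#' Fits one of three linear models on z-scored features (statistics learned
#' from the training rows and stored in the model). Weights are reported on
#' the standardized scale, which makes their magnitudes comparable across
#' features for embedded relevance ranking.
#'
#' @param X numeric matrix or `feature_table` rows x features.
#' @param labels `"control"`/`"treated"` or -1/+1.
#' @param model_type `"lr"`, `"lda"` or `"svm"`.
#' @param C regularization strength for LR/SVM (fixed at 1 by default).
#' @return list of class `classifier_model`: `weights` (named), `intercept`,
#'   `model_type`, `link` (`"logistic"` for LR else `"identity"`), z-scoring
#'   parameters.
#' @export
train_linear <- function(X, labels, model_type = c("lr", "lda", "svm"),
                         C = 1) {
  model_type <- match.arg(model_type)
  X <- as.matrix(X)
  y <- .encode_labels(labels)
  if (length(unique(y)) < 2) stop("single-class input")
  zs <- .zscore_fit(X)
  Xs <- .zscore_apply(X, zs)
  fit <- switch(model_type,
                lr = .fit_lr(Xs, y, C),
                lda = .fit_lda(Xs, y),
                svm = .fit_svm(Xs, y, C))
  names(fit$weights) <- colnames(X)
  structure(list(weights = fit$weights, intercept = fit$intercept,
                 model_type = model_type,
                 link = if (model_type == "lr") "logistic" else "identity",
                 zscore = zs, C = C),
            class = "classifier_model")
}

#' Decision scores of a linear model
#'
#' @param object a `classifier_model`.
#' @param newdata matrix of raw (unstandardized) features.
#' @param ... unused.
#' @return numeric vector of scores `s = w'x + b`; predicted label is
#'   `sign(s)` with ties to +1 (treated).
#' @export
predict.classifier_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, names(object$weights), drop = FALSE]
  Xs <- .zscore_apply(X, object$zscore)
  drop(Xs %*% object$weights) + object$intercept
}

#' Predicted labels from scores
#'
#' @param scores numeric decision scores.
#' @return vector in {-1, +1}; a score of exactly 0 maps to +1 (treated).
#' @export
score_to_label <- function(scores) ifelse(scores >= 0, 1, -1)

#' Build grouped CV folds
#'
#' Assigns groups (subjects) to folds so all rows of a subject share a fold;
#' k-fold assignment is stratified by the subject's label. `k = number of
#' groups` gives leave-one-subject-out.
#'
#' @param groups character vector, one entry per row.
#' @param labels row labels (used for stratification).
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @return integer fold id per row.
#' @export
make_grouped_folds <- function(groups, labels, k, seed = 1L) {
  g <- unique(groups)
  if (k > length(g)) stop("k = ", k, " exceeds the ", length(g), " groups")
  y <- .encode_labels(labels)[match(g, groups)]
  set.seed(as.integer(seed))
  fold_of <- integer(length(g)); names(fold_of) <- g
  for (cls in c(-1, 1)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  unname(fold_of[groups])
}

#' Grouped cross-validation of a linear classifier
#'
#' @param X feature matrix (rows x features).
#' @param labels row labels.
#' @param groups subject id per row (folds never split a subject).
#' @param model_type passed to [train_linear()].
#' @param protocol `"loo"` (leave-one-subject-out) or `"kfold"`.
#' @param k folds when `protocol = "kfold"` (default 20, the MRSI protocol;
#'   the MRI protocol is `protocol = "loo"`).
#' @param seed fold seed.
#' @return list: `accuracy` (row-level out-of-fold accuracy), `scores`
#'   (out-of-fold score per row), `predicted`, `folds`.
#' @export
cv_evaluate <- function(X, labels, groups, model_type = "lr",
                        protocol = c("loo", "kfold"), k = 20L, seed = 1L) {
  protocol <- match.arg(protocol)
  X <- as.matrix(X)
  y <- .encode_labels(labels)
  n_groups <- length(unique(groups))
  kk <- if (protocol == "loo") n_groups else k
  if (kk > n_groups) stop("k = ", kk, " exceeds the ", n_groups, " groups")
  folds <- if (protocol == "loo") {
    match(groups, unique(groups))
  } else {
    make_grouped_folds(groups, labels, kk, seed)
  }
  scores <- numeric(nrow(X))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) {
      stop("degenerate fold: single class in training split")
    }
    mod <- train_linear(X[tr, , drop = FALSE], y[tr], model_type)
    scores[!tr] <- predict(mod, X[!tr, , drop = FALSE])
  }
  pred <- score_to_label(scores)
  list(accuracy = mean(pred == y), scores = scores, predicted = pred,
       folds = folds)
}
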