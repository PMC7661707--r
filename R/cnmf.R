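# Convex non-negative matrix factorization of MRSI spectra (Ding-style
# multiplicative updates), tumor-complete voxel selection, and nonnegative
# least-squares projection of new spectra onto fitted sources.
#
# Model: X (n x L, rows = spectra) is approximated by G F with
# F = t(W) X (K x L): each source is a nonnegative combination of data rows
# (W >= 0, n x K) and each spectrum a nonnegative mixture of sources
# (G >= 0, n x K). The data themselves may contain negative values.

#' Select tumor-complete voxel spectra from a slice
#'
#' Keeps only voxels whose full pixel block lies inside the tumor mask, in
#' deterministic row-major grid order.
#'
#' @param slice a `slice_record` with a grid and mask.
#' @return list of class `spectrum_matrix`: `X` (n x L), `row_ids`
#'   (data frame: subject_id, slice_index, row, col), `ppm_axis`. Zero
#'   qualifying voxels give a 0-row matrix with a warning.
#' @export
select_tumor_spectra <- function(slice) {
  stopifnot(inherits(slice, "slice_record"), !is.null(slice$grid))
  g <- slice$grid
  # derive tumor-completeness from the mask itself rather than trusting the
  # stored flag
  keep <- which(.block_in_mask(slice$mask, g$block_map))
  if (length(keep) == 0) {
    warning("no tumor-complete voxel in ", slice$subject_id, "/",
            slice$slice_index, "; slice excluded from the MRSI pipeline")
  }
  X <- g$spectra[keep, , drop = FALSE]
  structure(list(
    X = X,
    row_ids = data.frame(subject_id = rep(slice$subject_id, length(keep)),
                         slice_index = rep(slice$slice_index, length(keep)),
                         row = g$block_map$row[keep],
                         col = g$block_map$col[keep],
                         stringsAsFactors = FALSE),
    ppm_axis = g$ppm_axis
  ), class = "spectrum_matrix")
}

#' Pool tumor spectra across slices
#'
#' @param slices list of `slice_record`s.
#' @return one `spectrum_matrix` stacking the tumor-complete voxels of every
#'   slice (slices without any are dropped).
#' @export
pool_tumor_spectra <- function(slices) {
  mats <- lapply(slices, function(s) suppressWarnings(select_tumor_spectra(s)))
  mats <- Filter(function(m) nrow(m$X) > 0, mats)
  if (length(mats) == 0) stop("no tumor-complete voxels in any slice")
  structure(list(
    X = do.call(rbind, lapply(mats, `[[`, "X")),
    row_ids = do.call(rbind, lapply(mats, `[[`, "row_ids")),
    ppm_axis = mats[[1]]$ppm_axis
  ), class = "spectrum_matrix")
}

.cnmf_error <- function(X, W, G) {
  # relative Frobenius error of X ~ G (t(W) X)
  norm(X - G %*% (t(W) %*% X), "F") / norm(X, "F")
}

#' Fit convex NMF
#'
#' Multiplicative updates on W and G with k-means cluster-indicator
#' initialization (random nonnegative fallback), iterated until the relative
#' change of the reconstruction error drops below `tol` or `max_iter` is
#' reached. Nonnegativity of W and G is preserved at every iterate and the
#' reconstruction-error trace is non-increasing. Because multiplicative
#' updates converge only sublinearly near a fix point, the fit optionally
#' finishes with exact alternating nonnegative-least-squares polish rounds
#' (refit W toward the least-squares-optimal sources, then refit G row-wise);
#' a polish round is kept only if it lowers the reconstruction error, so the
#' trace stays monotone. On data admitting an exact factorization this
#' reaches machine-precision error.
#'
#' @param X n x L spectrum matrix (rows = spectra), finite, n >= K.
#' @param K number of sources (default 20).
#' @param seed integer seed for the initialization.
#' @param max_iter,tol stopping rule (relative error change).
#' @param init `"kmeans"` or `"random"`.
#' @param polish `"full"` (NNLS refit of W and G), `"g"` (G only; cheap, used
#'   for large n) or `"none"`. Default `"auto"`: full when n <= 400, else G
#'   only.
#' @param ppm_axis optional chemical-shift axis carried into the result
#'   (taken from `X` when it is a `spectrum_matrix`).
#' @return list of class `source_set`: `F` (K x L sources), `W` (n x K),
#'   `G` (n x K), `K`, `ppm_axis`, `error_trace`, `iterations`, `seed`.
#' @export
fit_convex_nmf <- function(X, K = 20L, seed = 1L, max_iter = 500L,
                           tol = 1e-6, init = c("kmeans", "random"),
                           polish = c("auto", "full", "g", "none"),
                           ppm_axis = NULL) {
  polish <- match.arg(polish)
  if (inherits(X, "spectrum_matrix")) {
    if (is.null(ppm_axis)) ppm_axis <- X$ppm_axis
    X <- X$X
  }
  init <- match.arg(init)
  n <- nrow(X)
  if (!all(is.finite(X))) stop("non-finite values in X")
  if (K > n) stop("K = ", K, " exceeds the number of spectra (", n, ")")
  set.seed(as.integer(seed))

  # init per Ding et al.: k-means cluster indicators H (n x K);
  # G0 = H + 0.2, W0 = H D^-1 (D = diag cluster sizes)
  H <- NULL
  if (init == "kmeans" && n > K) {
    km <- tryCatch(
      stats::kmeans(X, centers = K, nstart = 3, iter.max = 50),
      error = function(e) NULL)
    if (!is.null(km)) {
      H <- matrix(0, n, K)
      H[cbind(seq_len(n), km$cluster)] <- 1
    }
  }
  if (is.null(H)) {
    H <- matrix(0, n, K)
    H[cbind(seq_len(n), sample.int(K, n, replace = TRUE))] <- 1
  }
  G <- H + 0.2
  W <- sweep(H + 0.2, 2, colSums(H + 0.2), "/")

  A <- X %*% t(X)                 # n x n Gram matrix of spectra
  Ap <- (abs(A) + A) / 2
  Am <- (abs(A) - A) / 2
  eps <- .Machine$double.eps

  err <- .cnmf_error(X, W, G)
  trace <- err
  for (it in seq_len(max_iter)) {
    # update G
    WtAW_p <- t(W) %*% Ap %*% W
    WtAW_m <- t(W) %*% Am %*% W
    num <- Ap %*% W + G %*% WtAW_m
    den <- Am %*% W + G %*% WtAW_p
    G <- G * sqrt((num + eps) / (den + eps))
    # update W
    GtG <- t(G) %*% G
    num <- Ap %*% G + Am %*% W %*% GtG
    den <- Am %*% G + Ap %*% W %*% GtG
    W <- W * sqrt((num + eps) / (den + eps))
    new_err <- .cnmf_error(X, W, G)
    trace <- c(trace, new_err)
    if (abs(err - new_err) < tol * max(err, eps)) {
      err <- new_err
      break
    }
    err <- new_err
  }

  if (polish == "auto") polish <- if (n <= 400) "full" else "g"
  if (polish != "none") {
    for (round in 1:5) {
      W2 <- W; G2 <- G
      if (polish == "full") {
        # least-squares-optimal sources for the current G, re-expressed as
        # nonnegative combinations of data rows
        Fls <- qr.coef(qr(G2), X)
        Fls[is.na(Fls)] <- 0
        Xt <- t(X)
        W2 <- vapply(seq_len(K), function(k) nnls_solve(Xt, Fls[k, ]),
                     numeric(n))
      }
      Fk <- t(W2) %*% X
      G2 <- t(vapply(seq_len(n), function(i) nnls_solve(t(Fk), X[i, ]),
                     numeric(K)))
      new_err <- .cnmf_error(X, W2, G2)
      if (new_err <= err) {
        W <- W2; G <- G2
        improved <- err - new_err
        trace <- c(trace, new_err)
        err <- new_err
        if (improved < tol * max(err, eps)) break
      } else break
    }
  }

  Fmat <- t(W) %*% X
  rownames(Fmat) <- paste0("source", seq_len(K))
  colnames(G) <- rownames(Fmat)
  structure(list(F = Fmat, W = W, G = G, K = as.integer(K),
                 ppm_axis = ppm_axis, error_trace = trace,
                 iterations = length(trace) - 1L, seed = as.integer(seed)),
            class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat("Convex-NMF source set: K =", x$K, ", L =", ncol(x$F),
      ", iterations =", x$iterations,
      sprintf(", final relative error %.3g\n", utils::tail(x$error_trace, 1)))
  invisible(x)
}

#' Nonnegative least squares
#'
#' Lawson-Hanson active-set solution of `min || A x - b ||^2, x >= 0`.
#'
#' @param A numeric matrix (m x k).
#' @param b numeric vector (length m).
#' @return nonnegative coefficient vector of length k.
#' @export
nnls_solve <- function(A, b) {
  k <- ncol(A)
  x <- numeric(k)
  passive <- logical(k)
  w <- drop(crossprod(A, b))           # gradient at x = 0
  tol <- 1e-10 * max(1, sum(abs(crossprod(A, b))))
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30 * k) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      idx <- which(passive)
      z <- numeric(k)
      z[idx] <- qr.coef(qr(A[, idx, drop = FALSE]), b)
      z[idx][is.na(z[idx])] <- 0
      if (all(z[idx] > tol)) {
        x <- z
        break
      }
      neg <- idx[z[idx] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg] + .Machine$double.eps))
      x <- x + alpha * (z - x)
      passive[passive] <- x[passive] > tol
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Project spectra onto a fitted source set
#'
#' Each row of `spectra` gets the nonnegative weights solving
#' `min || x - w F ||^2, w >= 0` (nonnegative least squares on the source
#' matrix). Deterministic.
#'
#' @param spectra `spectrum_matrix` or bare n x L matrix on the same ppm axis
#'   as the sources.
#' @param source_set a [fit_convex_nmf()] result.
#' @return n x K nonnegative weight matrix.
#' @export
project_spectra <- function(spectra, source_set) {
  X <- spectra
  if (inherits(spectra, "spectrum_matrix")) {
    if (!is.null(source_set$ppm_axis) &&
        !isTRUE(all.equal(spectra$ppm_axis, source_set$ppm_axis))) {
      stop("ppm axis mismatch between spectra and sources")
    }
    X <- spectra$X
  }
  if (ncol(X) != ncol(source_set$F)) stop("spectrum length mismatch")
  A <- t(source_set$F)                  # L x K
  W <- t(apply(X, 1, function(b) nnls_solve(A, b)))
  if (nrow(X) == 1) W <- matrix(W, nrow = 1)
  colnames(W) <- rownames(source_set$F)
  W
}

#' Match recovered sources to reference profiles
#'
#' Maximum-weight bipartite assignment (Hungarian-style, via igraph) on the
#' cosine-similarity matrix between recovered and reference sources; used by
#' all recovery tests to resolve permutation/scale ambiguity.
#'
#' @param recovered K x L matrix of fitted sources.
#' @param reference K' x L matrix of ground-truth profiles (K' <= K).
#' @return data frame: `reference` index, matched `recovered` index, `cosine`.
#' @export
match_sources <- function(recovered, reference) {
  cos_sim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  S <- outer(seq_len(nrow(reference)), seq_len(nrow(recovered)),
             Vectorize(function(i, j) cos_sim(reference[i, ], recovered[j, ])))
  nr <- nrow(S); nc <- ncol(S)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, nc)),
    edges = as.vector(t(cbind(rep(seq_len(nr), each = nc),
                              nr + rep(seq_len(nc), nr)))))
  # shift weights to be positive for maximum matching
  wts <- as.vector(t(S)) + 2
  m <- igraph::max_bipartite_match(g, weights = wts)$matching
  matched <- m[seq_len(nr)] - nr
  data.frame(reference = seq_len(nr), recovered = as.integer(matched),
             cosine = S[cbind(seq_len(nr), as.integer(matched))])
}
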