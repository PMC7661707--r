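# Nosological certainty maps: per-voxel posterior probability of the
# predicted label, computed from training decision scores, and anatomically
# registered rendering over the T2w background.

#' Score-to-posterior calibration
#'
#' Stores the training score distribution per class. When the classes are
#' score-separable (max control score < min treated score), the posterior of
#' the positive class is the exact piecewise form
#' `P(s) = 0` for `s < max_neg`, `pi` for `max_neg <= s <= min_pos`, `1` for
#' `s > min_pos`. With overlapping scores that middle band collapses, so the
#' calibration falls back to a Platt-style sigmoid fitted on the training
#' scores; which path applies is recorded in `separable`.
#'
#' @param scores training decision scores.
#' @param labels training labels.
#' @param prior positive-class prior `pi`; defaults to the training
#'   treated-class frequency.
#' @return list of class `score_calibration`: `max_neg`, `min_pos`, `prior`,
#'   `separable`, and sigmoid coefficients `platt = c(a, b)` for the
#'   non-separable path.
#' @export
score_calibration <- function(scores, labels, prior = NULL) {
  y <- .encode_labels(labels)
  if (!any(y > 0) || !any(y < 0)) stop("both classes required for calibration")
  max_neg <- max(scores[y < 0])
  min_pos <- min(scores[y > 0])
  if (is.null(prior)) prior <- mean(y > 0)
  stopifnot(prior >= 0, prior <= 1)
  separable <- max_neg < min_pos
  platt <- c(a = NA_real_, b = NA_real_)
  if (!separable) {
    # Platt sigmoid: P(+1 | s) = 1 / (1 + exp(a * s + b)), fitted by
    # unpenalized logistic regression of the class on the score
    fit <- stats::glm((y + 1) / 2 ~ scores, family = stats::binomial())
    platt <- c(a = -unname(stats::coef(fit)[2]),
               b = -unname(stats::coef(fit)[1]))
  }
  structure(list(max_neg = max_neg, min_pos = min_pos, prior = prior,
                 separable = separable, platt = platt),
            class = "score_calibration")
}

#' Posterior probability of the positive class
#'
#' @param s decision score(s).
#' @param calibration a [score_calibration()].
#' @return `P(+1 | s)` in `[0, 1]`; exactly `0`, `pi` or `1` in the separable
#'   case (band edges inclusive), continuous sigmoid otherwise. Non-decreasing
#'   in `s` either way.
#' @export
posterior <- function(s, calibration) {
  stopifnot(inherits(calibration, "score_calibration"))
  if (calibration$separable) {
    out <- ifelse(s < calibration$max_neg, 0,
                  ifelse(s > calibration$min_pos, 1, calibration$prior))
  } else {
    out <- 1 / (1 + exp(calibration$platt["a"] * s + calibration$platt["b"]))
  }
  unname(out)
}

#' Certainty of the predicted label
#'
#' `P` if the prediction is treated (+1), `1 - P` otherwise, so low values
#' mean "unreliable" regardless of the predicted class.
#'
#' @inheritParams posterior
#' @export
label_certainty <- function(s, calibration) {
  p <- posterior(s, calibration)
  ifelse(score_to_label(s) > 0, p, 1 - p)
}

#' Build a nosological map for one slice
#'
#' @param slice a `slice_record` with a grid.
#' @param scores decision scores for the tumor-complete voxels of the slice,
#'   in the row-major order of [select_tumor_spectra()].
#' @param calibration a [score_calibration()] fitted on training scores.
#' @return list of class `nosological_map`: `dims`, per-voxel data frame
#'   `voxels` (row, col, score, predicted, P = posterior of the positive
#'   class, certainty, correct), `true_label`, `pct_treated`, `pct_control`,
#'   `block_map` registration, and the source `slice` key.
#' @export
build_map <- function(slice, scores, calibration) {
  sm <- select_tumor_spectra(slice)
  if (length(scores) != nrow(sm$X)) {
    stop("expected ", nrow(sm$X), " voxel scores, got ", length(scores))
  }
  truth <- if (slice$label == "treated") 1 else -1
  pred <- score_to_label(scores)
  vox <- data.frame(
    row = sm$row_ids$row, col = sm$row_ids$col, score = scores,
    predicted = pred,
    P = posterior(scores, calibration),
    certainty = label_certainty(scores, calibration),
    correct = pred == truth
  )
  n <- nrow(vox)
  structure(list(
    dims = slice$grid$dims, voxels = vox, true_label = truth,
    pct_treated = if (n) 100 * mean(pred > 0) else NA_real_,
    pct_control = if (n) 100 * mean(pred < 0) else NA_real_,
    block_map = slice$grid$block_map,
    slice_key = paste0(slice$subject_id, "_", slice$slice_index)
  ), class = "nosological_map")
}

# viridis-like perceptually ordered ramp (dark = low certainty)
.certainty_ramp <- grDevices::colorRampPalette(
  c("#440154", "#31688E", "#35B779", "#FDE725"))

#' Render a nosological map to PNG
#'
#' Grayscale background image with in-tumor voxel blocks tinted by the
#' label-certainty colormap (lighter = more reliable), red contours around
#' misclassified voxels, a bottom bar colored by the true class and a top bar
#' split by the predicted treated/control voxel percentages.
#'
#' @param map a [build_map()] result.
#' @param background the slice image (matrix in [0,1]).
#' @param file output PNG path.
#' @param alpha tint opacity.
#' @return `file`, invisibly.
#' @export
render_map <- function(map, background, file, alpha = 0.55) {
  n <- nrow(background); p <- ncol(background)
  rgb_img <- array(rep(background, 3), dim = c(n, p, 3))
  ramp <- .certainty_ramp(256)
  bar_h <- max(2L, as.integer(round(n * 0.03)))
  cls_col <- function(lab) if (lab > 0) c(0.85, 0.33, 0.10) else c(0.12, 0.47, 0.71)
  tint <- function(r0, r1, c0, c1, col, a) {
    for (ch in 1:3) {
      rgb_img[r0:r1, c0:c1, ch] <<-
        (1 - a) * rgb_img[r0:r1, c0:c1, ch] + a * col[ch]
    }
  }
  for (i in seq_len(nrow(map$voxels))) {
    v <- map$voxels[i, ]
    bm <- map$block_map
    b <- bm[bm$row == v$row & bm$col == v$col, ]
    col <- grDevices::col2rgb(ramp[1 + round(v$certainty * 255)]) / 255
    tint(b$r0, b$r1 - 1L, b$c0, b$c1 - 1L, col, alpha)
    if (!v$correct) {        # red contour on misclassified voxels
      for (ch in 1:3) {
        red <- c(1, 0, 0)[ch]
        rgb_img[b$r0:(b$r1 - 1L), c(b$c0, b$c1 - 1L), ch] <- red
        rgb_img[c(b$r0, b$r1 - 1L), b$c0:(b$c1 - 1L), ch] <- red
      }
    }
  }
  # bottom bar: true class; top bar: predicted percentage split
  tint(n - bar_h + 1L, n, 1L, p, cls_col(map$true_label), 1)
  if (!is.na(map$pct_treated)) {
    split_at <- max(1L, round(p * map$pct_treated / 100))
    tint(1L, bar_h, 1L, split_at, cls_col(1), 1)
    if (split_at < p) tint(1L, bar_h, split_at + 1L, p, cls_col(-1), 1)
  }
  png::writePNG(rgb_img, file)
  invisible(file)
}
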