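# Synthetic cohort generator: seeded subjects with T2w-like images, tumor
# masks, and registered MRSI grids whose spectra are noisy convex mixtures of
# ground-truth sources.

#' Cohort specification
#'
#' Collects the generator knobs. Defaults reproduce the cohort structure the
#' analysis assumes: 29 control and 34 treated subjects, ~half held out,
#' training subjects acquired with a single slice and holdout subjects with
#' two to four slices.
#'
#' @param n_control,n_treated subject counts per class.
#' @param slices_per_subject length-2 integer range; training subjects get
#'   the minimum, holdout subjects a random count in `[max(2,min), max]`.
#' @param grid_size MRSI grid side, 10 or 12 voxels.
#' @param image_size image side in pixels (square images).
#' @param L spectrum length in points.
#' @param noise_sd Gaussian noise s.d. added to each spectral point, on the
#'   unit-maximum intensity scale of the source profiles.
#' @param class_mixing list with elements `control` and `treated`, each a
#'   length-K vector of Dirichlet-style concentrations over the sources
#'   (entries equal to 0 exclude a source from that class). `NULL` defers to
#'   defaults chosen when the sources are known: treated up-weights source 1
#'   (PUFA/Lac-rich), control up-weights source 2 (Glx/Ala-rich).
#' @param holdout_fraction fraction of subjects (per class, rounded) assigned
#'   to the multi-slice holdout split.
#' @param seed integer master seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 29L, n_treated = 34L,
                        slices_per_subject = c(1L, 4L),
                        grid_size = 10L, image_size = 256L, L = 512L,
                        noise_sd = 0.05, class_mixing = NULL,
                        holdout_fraction = 31 / 63, seed = 1L) {
  stopifnot(n_control >= 1, n_treated >= 1, noise_sd >= 0,
            length(slices_per_subject) == 2,
            slices_per_subject[1] >= 1, slices_per_subject[2] <= 4,
            slices_per_subject[1] <= slices_per_subject[2],
            image_size >= 32, L >= 64,
            holdout_fraction >= 0, holdout_fraction < 1)
  if (!grid_size %in% c(10L, 12L)) stop("grid_size must be 10 or 12")
  if (!is.null(class_mixing)) {
    stopifnot(is.list(class_mixing),
              all(c("control", "treated") %in% names(class_mixing)),
              all(class_mixing$control >= 0), all(class_mixing$treated >= 0),
              sum(class_mixing$control) > 0, sum(class_mixing$treated) > 0)
  }
  structure(list(
    n_control = as.integer(n_control), n_treated = as.integer(n_treated),
    slices_per_subject = as.integer(slices_per_subject),
    grid_size = as.integer(grid_size), image_size = as.integer(image_size),
    L = as.integer(L), noise_sd = noise_sd, class_mixing = class_mixing,
    holdout_fraction = holdout_fraction, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default class mixing concentrations
#'
#' Dirichlet-style concentrations over K sources. The class-typical source
#' (source 1 for treated, the PUFA/Lac-rich responding pattern; source 2 for
#' control, the Glx/Ala-rich pattern) gets concentration 2, the opposite
#' class's source 0.2, and the shared sources 0.4. Sub-unit concentrations on
#' the non-dominant sources make the draws sparse, so most voxels are
#' dominated by a single tissue pattern and a minority by one of the shared
#' patterns: the regime in which sources act as representative signal
#' centroids and stay identifiable to a convex factorization (whose sources
#' live in the cone of observed spectra, and therefore can only be recovered
#' if some voxels are nearly pure).
#'
#' @param K number of sources (>= 2).
#' @return list with `control` and `treated` concentration vectors.
#' @export
default_class_mixing <- function(K) {
  stopifnot(K >= 2)
  base <- rep(0.4, K)
  trt <- base; trt[1] <- 2; trt[2] <- 0.2
  ctrl <- base; ctrl[1] <- 0.2; ctrl[2] <- 2
  list(control = ctrl, treated = trt)
}

# Dirichlet-style draw: independent gammas, normalized. Zero concentrations
# give exact zeros, so disjoint supports across classes stay disjoint.
.rmix <- function(conc) {
  g <- ifelse(conc > 0, stats::rgamma(length(conc), shape = conc, rate = 1), 0)
  if (sum(g) == 0) g[which.max(conc)] <- 1
  g / sum(g)
}

# 3x3 box blur, edges replicated
.blur3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  pad <- matrix(0, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[n + 2, ] <- pad[n + 1, ]
  pad[, 1] <- pad[, 2]; pad[, p + 2] <- pad[, p + 1]
  acc <- matrix(0, n, p)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + pad[(1 + dr):(n + dr), (1 + dc):(p + dc)]
  }
  acc / 9
}

.ellipse_mask <- function(n, cx, cy, rx, ry) {
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((r - cy) / ry)^2 + ((c - cx) / rx)^2 <= 1
}

# One synthetic T2w-like slice: brain ellipse, hyperintense tumor, and (for
# treated cases) hypointense foci inside the tumor mask.
.make_slice_image <- function(label, n) {
  img <- matrix(0.05, n, n)
  brain <- .ellipse_mask(n, n / 2, n / 2, 0.42 * n, 0.36 * n)
  img[brain] <- 0.45
  # tumor: ellipse jittered around center
  cx <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  cy <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  rx <- stats::runif(1, 0.13, 0.20) * n
  ry <- stats::runif(1, 0.13, 0.20) * n
  mask <- .ellipse_mask(n, cx, cy, rx, ry) & brain
  img[mask] <- 0.78
  # hypointense foci: many/dark for treated, rare/faint for control
  if (label == "treated") {
    nf <- 4L + stats::rpois(1, 5)
    mult <- 0.45
  } else {
    nf <- stats::rbinom(1, 1, 0.3)
    mult <- 0.88
  }
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nf)) {
    ctr <- idx[sample.int(nrow(idx), 1), ]
    fr <- stats::runif(1, 0.012, 0.035) * n
    focus <- .ellipse_mask(n, ctr[2], ctr[1], fr, fr) & mask
    img[focus] <- img[focus] * mult
  }
  img <- img + matrix(stats::rnorm(n * n, 0, 0.02), n, n)
  img <- .blur3(img)
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, mask = mask, tumor_center = c(row = cy, col = cx))
}

# "normal tissue" spectrum profile (NAA/Cr/Cho dominated), not in the tumor
# source set
.normal_profile <- function(ppm_axis) {
  y <- .lorentzian(ppm_axis, 2.02, 0.035, 1.0) +
    .lorentzian(ppm_axis, 3.03, 0.030, 0.8) +
    .lorentzian(ppm_axis, 3.21, 0.030, 0.6) +
    .lorentzian(ppm_axis, 3.55, 0.040, 0.4)
  y / max(y)
}

# Register a grid_size x grid_size block grid centered on the tumor.
.make_block_map <- function(image_size, grid_size, tumor_center) {
  b <- max(2L, as.integer(floor(image_size * 0.36 / grid_size)))
  span <- b * grid_size
  if (span > image_size) stop("grid blocks exceed image bounds")
  r0 <- as.integer(round(tumor_center["row"] - span / 2))
  c0 <- as.integer(round(tumor_center["col"] - span / 2))
  r0 <- min(max(r0, 1L), image_size - span + 1L)
  c0 <- min(max(c0, 1L), image_size - span + 1L)
  g <- expand.grid(col = seq_len(grid_size), row = seq_len(grid_size))
  data.frame(
    row = g$row, col = g$col,
    r0 = r0 + (g$row - 1L) * b, r1 = r0 + g$row * b,
    c0 = c0 + (g$col - 1L) * b, c1 = c0 + g$col * b
  )  # half-open [r0, r1) x [c0, c1), row-major voxel order
}

.block_in_mask <- function(mask, bm) {
  vapply(seq_len(nrow(bm)), function(i) {
    all(mask[bm$r0[i]:(bm$r1[i] - 1L), bm$c0[i]:(bm$c1[i] - 1L)])
  }, logical(1))
}

#' Generate a synthetic cohort
#'
#' Produces per-slice records (image, tumor mask, registered MRSI grid) and
#' the ground-truth mixing weights used to synthesize every in-tumor
#' spectrum. In-tumor voxel spectra are `a * (h %*% profiles) + noise` with
#' `h >= 0` drawn from the class mixing distribution and `a` a log-normal
#' amplitude; out-of-tumor voxels carry a distinct normal-tissue profile.
#' Treated images contain seeded hypointense foci inside the mask; control
#' images are smoother. Identical `(spec, sources)` give identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param sources a [make_sources()] result.
#' @return list of class `cohort`: `slices` (list of `slice_record`),
#'   `subjects` (data frame: subject_id, label, split, n_slices),
#'   `mixing` (per-slice ground-truth weight matrices for in-tumor voxels,
#'   rows keyed by voxel row/col), `sources`, `spec`.
#' @export
make_cohort <- function(spec, sources) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(sources, "ground_truth_sources"))
  K <- nrow(sources$profiles)
  L <- ncol(sources$profiles)
  if (L != spec$L) stop("spec$L must match the source profile length")
  mixing <- spec$class_mixing
  if (is.null(mixing)) mixing <- default_class_mixing(K)
  stopifnot(length(mixing$control) == K, length(mixing$treated) == K)

  set.seed(spec$seed)
  n_tot <- spec$n_control + spec$n_treated
  labels <- c(rep("control", spec$n_control), rep("treated", spec$n_treated))
  ids <- sprintf("S%03d", seq_len(n_tot))
  # stratified holdout assignment
  split <- rep("train", n_tot)
  for (lab in c("control", "treated")) {
    i <- which(labels == lab)
    nh <- round(spec$holdout_fraction * length(i))
    if (nh > 0) split[sample(i, nh)] <- "holdout"
  }
  smin <- spec$slices_per_subject[1]; smax <- spec$slices_per_subject[2]
  n_slices <- ifelse(split == "train", smin,
                     if (smax > max(2L, smin)) NA else max(min(2L, smax), smin))
  hold <- which(split == "holdout")
  lo <- min(max(2L, smin), smax)
  n_slices[hold] <- sample(seq(lo, smax), length(hold), replace = TRUE)
  n_slices[split == "train"] <- smin

  normal <- .normal_profile(sources$ppm_axis)
  slices <- list(); mixing_gt <- list()
  for (s in seq_len(n_tot)) {
    for (sl in seq_len(n_slices[s])) {
      im <- .make_slice_image(labels[s], spec$image_size)
      bm <- .make_block_map(spec$image_size, spec$grid_size, im$tumor_center)
      in_tumor <- .block_in_mask(im$mask, bm)
      nvox <- nrow(bm)
      conc <- mixing[[labels[s]]]
      X <- matrix(0, nvox, L)
      H <- matrix(0, nvox, K)
      for (v in seq_len(nvox)) {
        if (in_tumor[v]) {
          h <- .rmix(conc) * stats::rlnorm(1, 0, 0.15)
          H[v, ] <- h
          X[v, ] <- as.numeric(h %*% sources$profiles)
        } else {
          X[v, ] <- stats::rlnorm(1, -0.3, 0.2) * normal
        }
      }
      if (spec$noise_sd > 0) {
        X <- X + matrix(stats::rnorm(nvox * L, 0, spec$noise_sd), nvox, L)
      }
      grid <- list(
        dims = c(spec$grid_size, spec$grid_size),
        spectra = X, ppm_axis = sources$ppm_axis,
        block_map = bm, in_tumor = in_tumor
      )
      class(grid) <- "mrsi_grid"
      rec <- list(subject_id = ids[s], slice_index = sl,
                  label = labels[s], split = split[s],
                  image = im$image, mask = im$mask, grid = grid)
      class(rec) <- "slice_record"
      key <- paste0(ids[s], "_", sl)
      slices[[key]] <- rec
      gt <- cbind(bm[in_tumor, c("row", "col")], H[in_tumor, , drop = FALSE])
      colnames(gt) <- c("row", "col", rownames(sources$profiles))
      mixing_gt[[key]] <- gt
    }
  }
  structure(list(
    slices = slices,
    subjects = data.frame(subject_id = ids, label = labels, split = split,
                          n_slices = n_slices, stringsAsFactors = FALSE),
    mixing = mixing_gt, sources = sources, spec = spec
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$label == "control"), "control /",
      sum(x$subjects$label == "treated"), "treated ),",
      length(x$slices), "slices\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Images and masks as PNG, spectra per grid as CSV (one row per voxel:
#' row, col, in_tumor, then the L ppm columns), a subject manifest CSV and a
#' ground-truth mixing-weight CSV.
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spectra"), showWarnings = FALSE)
  for (key in names(cohort$slices)) {
    rec <- cohort$slices[[key]]
    png::writePNG(rec$image, file.path(dir, "images", paste0(key, ".png")))
    png::writePNG(rec$mask * 1.0,
                  file.path(dir, "images", paste0(key, "_mask.png")))
    g <- rec$grid
    df <- cbind(g$block_map[, c("row", "col")], in_tumor = g$in_tumor,
                as.data.frame(g$spectra))
    names(df)[-(1:3)] <- sprintf("ppm_%.4f", g$ppm_axis)
    utils::write.csv(df, file.path(dir, "spectra", paste0(key, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$subjects, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  gt <- do.call(rbind, lapply(names(cohort$mixing), function(k) {
    m <- cohort$mixing[[k]]
    if (nrow(m) == 0) return(NULL)
    cbind(data.frame(slice_key = k), m)
  }))
  utils::write.csv(gt, file.path(dir, "ground_truth_mixing.csv"),
                   row.names = FALSE)
  invisible(dir)
}
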