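# 2D radiomics: four texture matrices (GLCM, GLRLM, GLSZM, NGTDM) computed on
# the quantized tumor bounding box, plus Minkowski functionals (area,
# perimeter, Euler number) of the mask thresholded at N equally spaced
# intensity levels. Default manifest: 11 + 13 + 13 + 5 = 42 texture features
# and 3 x 16 = 48 Minkowski features, 90 per slice.

#' Texture extraction configuration
#'
#' @param n_gray_levels quantization bins (equal-width over the ROI range).
#' @param offsets list of `(dy, dx)` displacement vectors; defaults to the
#'   four distance-1 directions of 2D practice. GLCM/GLRLM statistics are
#'   averaged over them.
#' @return list of class `texture_config`.
#' @export
texture_config <- function(n_gray_levels = 32L,
                           offsets = list(c(0L, 1L), c(1L, 0L),
                                          c(1L, 1L), c(1L, -1L))) {
  stopifnot(n_gray_levels >= 2, length(offsets) >= 1)
  structure(list(n_gray_levels = as.integer(n_gray_levels), offsets = offsets),
            class = "texture_config")
}

#' Minkowski functional configuration
#'
#' @param n_levels number N of equally spaced thresholds (default 16, giving
#'   3N = 48 features Area1..AreaN, Perimeter1..PerimeterN, Euler1..EulerN).
#' @return list of class `minkowski_config`.
#' @export
minkowski_config <- function(n_levels = 16L) {
  stopifnot(n_levels >= 1)
  structure(list(n_levels = as.integer(n_levels)), class = "minkowski_config")
}

#' Bounding box of a mask
#'
#' Smallest axis-aligned rectangle containing all mask pixels, in the
#' half-open convention `[r0, r1) x [c0, c1)`.
#'
#' @param mask logical or 0/1 matrix.
#' @param id optional identity string used in the error message.
#' @return integer vector `c(r0, r1, c0, c1)`.
#' @export
bounding_box <- function(mask, id = NULL) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop("empty mask", if (!is.null(id)) paste0(" for ", id) else "")
  }
  c(r0 = min(idx[, 1]), r1 = max(idx[, 1]) + 1L,
    c0 = min(idx[, 2]), c1 = max(idx[, 2]) + 1L)
}

#' Quantize intensities to discrete gray levels
#'
#' Equal-width binning of the ROI intensity range into `n_gray_levels` bins,
#' returning integer levels 1..n. A constant image maps entirely to level 1.
#'
#' @param roi numeric matrix of finite intensities.
#' @param n_gray_levels number of bins.
#' @return integer matrix, same shape as `roi`.
#' @export
quantize <- function(roi, n_gray_levels) {
  stopifnot(all(is.finite(roi)), n_gray_levels >= 2)
  lo <- min(roi); hi <- max(roi)
  if (hi == lo) {
    return(matrix(1L, nrow(roi), ncol(roi)))
  }
  q <- pmin(as.integer(floor((roi - lo) / (hi - lo) * n_gray_levels)) + 1L,
            as.integer(n_gray_levels))
  matrix(q, nrow(roi), ncol(roi))
}

# ---- texture matrices -------------------------------------------------------

.glcm_one <- function(q, ng, off) {
  n <- nrow(q); p <- ncol(q)
  dy <- off[1]; dx <- off[2]
  r1 <- max(1, 1 - dy):min(n, n - dy)
  c1 <- max(1, 1 - dx):min(p, p - dx)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dy, c1 + dx, drop = FALSE]
  m <- matrix(0, ng, ng)
  tab <- table(factor(a, levels = 1:ng), factor(b, levels = 1:ng))
  m <- m + tab + t(tab)              # symmetric counts
  m / sum(m)
}

.glrlm_one <- function(q, ng, off) {
  n <- nrow(q); p <- ncol(q)
  m <- matrix(0, ng, max(n, p))
  # group pixels into lines along the offset direction; within each group the
  # column-major traversal order is consistent with a unit step, and run
  # lengths are invariant to traversing a line backwards
  key <- if (all(off == c(0L, 1L))) row(q)
         else if (all(off == c(1L, 0L))) col(q)
         else if (all(off == c(1L, 1L))) col(q) - row(q)
         else if (all(off == c(1L, -1L))) col(q) + row(q)
         else stop("GLRLM offsets must be unit steps in one of 4 directions")
  for (line in split(as.vector(q), as.vector(key))) {
    r <- rle(line)
    for (i in seq_along(r$lengths)) {
      m[r$values[i], r$lengths[i]] <- m[r$values[i], r$lengths[i]] + 1
    }
  }
  m
}

# connected zones of equal gray level, 8-connectivity
.zone_sizes <- function(q, ng) {
  n <- nrow(q); p <- ncol(q)
  id <- matrix(seq_len(n * p), n, p)
  edges <- NULL
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    dy <- s[1]; dx <- s[2]
    r1 <- max(1, 1 - dy):min(n, n - dy)
    c1 <- max(1, 1 - dx):min(p, p - dx)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dy, c1 + dx, drop = FALSE]
    same <- q[r1, c1, drop = FALSE] == q[r1 + dy, c1 + dx, drop = FALSE]
    edges <- rbind(edges, cbind(a[same], b[same]))
  }
  g <- igraph::make_graph(if (is.null(edges)) integer(0) else c(t(edges)),
                          n = n * p, directed = FALSE)
  memb <- igraph::components(g)$membership
  zones <- data.frame(level = as.vector(q), zone = memb)
  agg <- stats::aggregate(rep(1L, nrow(zones)),
                          by = list(level = zones$level, zone = zones$zone),
                          FUN = sum)
  data.frame(level = agg$level, size = agg$x)
}

.glszm <- function(q, ng) {
  zs <- .zone_sizes(q, ng)
  maxsz <- max(zs$size)
  m <- matrix(0, ng, maxsz)
  for (i in seq_len(nrow(zs))) {
    m[zs$level[i], zs$size[i]] <- m[zs$level[i], zs$size[i]] + 1
  }
  m
}

# NGTDM: per-level sum of |value - mean of 8-neighborhood| and occurrence
# probabilities
.ngtdm <- function(q, ng) {
  n <- nrow(q); p <- ncol(q)
  acc <- matrix(0, n, p); cnt <- matrix(0, n, p)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    r1 <- max(1, 1 - dy):min(n, n - dy)
    c1 <- max(1, 1 - dx):min(p, p - dx)
    acc[r1, c1] <- acc[r1, c1] + q[r1 + dy, c1 + dx]
    cnt[r1, c1] <- cnt[r1, c1] + 1
  }
  nbmean <- acc / cnt
  s <- numeric(ng); ni <- numeric(ng)
  for (i in 1:ng) {
    sel <- q == i
    ni[i] <- sum(sel)
    if (ni[i] > 0) s[i] <- sum(abs(i - nbmean[sel]))
  }
  list(s = s, p = ni / sum(ni), n = sum(ni))
}

#' Compute a texture matrix
#'
#' @param q quantized integer ROI (levels 1..n_gray_levels).
#' @param kind one of `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"NGTDM"`.
#' @param config a [texture_config()].
#' @param offset for GLCM/GLRLM, a single `(dy, dx)` offset (defaults to the
#'   first configured one).
#' @return GLCM: normalized symmetric co-occurrence matrix; GLRLM: run-length
#'   count matrix; GLSZM: zone-size count matrix; NGTDM: list with `s`
#'   (gray-tone difference sums), `p` (level probabilities), `n`.
#' @export
texture_matrix <- function(q, kind, config = texture_config(),
                           offset = config$offsets[[1]]) {
  ng <- config$n_gray_levels
  switch(kind,
    GLCM  = .glcm_one(q, ng, offset),
    GLRLM = .glrlm_one(q, ng, offset),
    GLSZM = .glszm(q, ng),
    NGTDM = .ngtdm(q, ng),
    stop("unknown texture matrix kind: ", kind)
  )
}

# ---- texture features -------------------------------------------------------

.glcm_features <- function(P) {
  ng <- nrow(P)
  i <- matrix(1:ng, ng, ng); j <- t(i)
  pnz <- P[P > 0]
  mu_x <- sum(i * P); mu_y <- sum(j * P)
  sd_x <- sqrt(sum((i - mu_x)^2 * P)); sd_y <- sqrt(sum((j - mu_y)^2 * P))
  corr <- if (sd_x > 0 && sd_y > 0) {
    sum((i - mu_x) * (j - mu_y) * P) / (sd_x * sd_y)
  } else 0
  # p_{x+y}
  k <- i + j
  sum_avg <- sum(k * P)
  c(
    glcm_energy        = sum(P^2),
    glcm_contrast      = sum((i - j)^2 * P),
    glcm_correlation   = corr,
    glcm_variance      = sum((i - mu_x)^2 * P),
    glcm_homogeneity   = sum(P / (1 + abs(i - j))),
    glcm_sum_average   = sum_avg,
    glcm_entropy       = if (length(pnz)) -sum(pnz * log2(pnz)) else 0,
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_autocorr      = sum(i * j * P),
    glcm_cluster_shade = sum((i + j - mu_x - mu_y)^3 * P),
    glcm_cluster_prom  = sum((i + j - mu_x - mu_y)^4 * P)
  )
}

# shared by GLRLM (runs) and GLSZM (zones): m[level, size] counts
.rl_features <- function(m, n_pixels, prefix,
                         size_names = c("sre", "lre"),
                         var_names = c("glv", "rlv"),
                         nn_names = c("gln", "rln"), rp_name = "rp") {
  ns <- sum(m)
  ng <- nrow(m); sl <- ncol(m)
  i <- matrix(1:ng, ng, sl); l <- matrix(1:sl, ng, sl, byrow = TRUE)
  p <- m / ns
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  v <- c(
    sum(m / l^2) / ns,                    # short run/zone emphasis
    sum(m * l^2) / ns,                    # long run/zone emphasis
    sum(rowSums(m)^2) / ns,               # gray-level nonuniformity
    sum(colSums(m)^2) / ns,               # run/zone-length nonuniformity
    ns / n_pixels,                        # run/zone percentage
    sum(m / i^2) / ns,                    # low gray-level emphasis
    sum(m * i^2) / ns,                    # high gray-level emphasis
    sum(m / (i^2 * l^2)) / ns,            # short + low
    sum(m * i^2 / l^2) / ns,              # short + high
    sum(m * l^2 / i^2) / ns,              # long + low
    sum(m * i^2 * l^2) / ns,              # long + high
    sum((i - mu_i)^2 * p),                # gray-level variance
    sum((l - mu_l)^2 * p)                 # length/size variance
  )
  names(v) <- paste0(prefix, "_",
                     c(size_names[1], size_names[2], nn_names[1], nn_names[2],
                       rp_name, "lgle", "hgle",
                       paste0(size_names[1], c("_lgle", "_hgle")),
                       paste0(size_names[2], c("_lgle", "_hgle")),
                       var_names[1], var_names[2]))
  v
}

.ngtdm_features <- function(nt) {
  s <- nt$s; p <- nt$p; n <- nt$n
  ng <- length(p)
  nz <- which(p > 0)
  eps <- 1e-12
  coarse <- 1 / (eps + sum(p * s))
  ngp <- length(nz)
  contrast <- if (ngp > 1) {
    (sum(outer(p[nz], p[nz]) * outer(nz, nz, function(a, b) (a - b)^2)) /
       (ngp * (ngp - 1))) * (sum(s) / n)
  } else 0
  busy_den <- sum(abs(outer(nz * p[nz], nz * p[nz], "-")))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  cmplx <- 0; strength <- 0
  for (a in nz) for (b in nz) {
    if (a == b) next
    cmplx <- cmplx + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) /
      (n * (p[a] + p[b]))
    strength <- strength + (p[a] + p[b]) * (a - b)^2
  }
  strength <- if (sum(s) > 0) strength / (eps + sum(s)) else 0
  c(ngtdm_coarseness = coarse, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = cmplx,
    ngtdm_strength = strength)
}

#' Texture feature vector (42 statistics)
#'
#' Computes the default manifest of 42 named texture statistics on a
#' rectangular ROI: 11 GLCM (offset-averaged), 13 GLRLM (direction-averaged),
#' 13 GLSZM and 5 NGTDM. Degenerate inputs yield defined limits (a constant
#' ROI has GLCM energy 1, contrast and entropy 0).
#'
#' @param roi numeric matrix (the bounding-box rectangle), at least 2x2.
#' @param config a [texture_config()].
#' @return named numeric vector of length 42, all finite.
#' @export
texture_features <- function(roi, config = texture_config()) {
  if (nrow(roi) < 2 || ncol(roi) < 2) stop("ROI smaller than 2x2")
  ng <- config$n_gray_levels
  q <- quantize(roi, ng)
  n_px <- length(q)
  glcm_avg <- Reduce(`+`, lapply(config$offsets, function(o) {
    .glcm_features(.glcm_one(q, ng, o))
  })) / length(config$offsets)
  glrlm_avg <- Reduce(`+`, lapply(config$offsets, function(o) {
    .rl_features(.glrlm_one(q, ng, o), n_px, "glrlm",
                 size_names = c("sre", "lre"), var_names = c("glv", "rlv"),
                 nn_names = c("gln", "rln"), rp_name = "rp")
  })) / length(config$offsets)
  glszm_f <- .rl_features(.glszm(q, ng), n_px, "glszm",
                          size_names = c("sze", "lze"),
                          var_names = c("glv", "zsv"),
                          nn_names = c("gln", "zsn"), rp_name = "zp")
  ngtdm_f <- .ngtdm_features(.ngtdm(q, ng))
  out <- c(glcm_avg, glrlm_avg, glszm_f, ngtdm_f)
  stopifnot(length(out) == 42, all(is.finite(out)))
  out
}

# ---- Minkowski functionals --------------------------------------------------

# perimeter: number of 4-neighbor foreground/background pixel edges, image
# exterior counting as background
.perimeter4 <- function(b) {
  n <- nrow(b); p <- ncol(b)
  pad <- matrix(FALSE, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- b
  fg <- which(pad, arr.ind = TRUE)
  tot <- 0L
  for (s in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    tot <- tot + sum(!pad[cbind(fg[, 1] + s[1], fg[, 2] + s[2])])
  }
  tot
}

# Euler number (objects - holes) for 8-connected foreground / 4-connected
# background, by 2x2 quad pattern counts (Gray's formula)
.euler8 <- function(b) {
  n <- nrow(b); p <- ncol(b)
  pad <- matrix(0L, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- b
  a11 <- pad[1:(n + 1), 1:(p + 1)]
  a12 <- pad[1:(n + 1), 2:(p + 2)]
  a21 <- pad[2:(n + 2), 1:(p + 1)]
  a22 <- pad[2:(n + 2), 2:(p + 2)]
  tot <- a11 + a12 + a21 + a22
  c1 <- sum(tot == 1)
  c3 <- sum(tot == 3)
  cd <- sum(tot == 2 & ((a11 & a22) | (a12 & a21)))
  (c1 - c3 - 2 * cd) / 4
}

#' Minkowski functional features
#'
#' Thresholds the masked image at N levels equally spaced (endpoints
#' included) over the intensity range inside the mask. For each binary object
#' `mask & (image >= t_i)` it reports Area (pixel count), Perimeter
#' (4-neighbor foreground/background edge count, mask exterior counting as
#' background) and Euler number (8-connected objects minus 4-connected
#' holes).
#'
#' @param image numeric matrix.
#' @param mask logical matrix, same shape, nonempty.
#' @param config a [minkowski_config()].
#' @return named numeric vector `Area1..AreaN, Perimeter1..PerimeterN,
#'   Euler1..EulerN` (length 3N).
#' @export
minkowski_features <- function(image, mask, config = minkowski_config()) {
  if (!any(mask)) stop("empty mask")
  N <- config$n_levels
  vals <- image[mask]
  ts <- if (N == 1) min(vals) else seq(min(vals), max(vals), length.out = N)
  area <- per <- eul <- numeric(N)
  for (i in seq_len(N)) {
    b <- mask & (image >= ts[i])
    area[i] <- sum(b)
    per[i] <- .perimeter4(b)
    eul[i] <- .euler8(b)
  }
  stats::setNames(c(area, per, eul),
                  c(paste0("Area", 1:N), paste0("Perimeter", 1:N),
                    paste0("Euler", 1:N)))
}

#' Radiomic feature row for one slice
#'
#' Concatenates the 42 texture statistics of the tumor bounding-box rectangle
#' with the 3N Minkowski features of the masked image (default N = 16, for a
#' total of 90 features), and records the mask pixel count used as the SVS
#' slice weight.
#'
#' @param slice a `slice_record` (needs `image`, `mask`, `subject_id`,
#'   `slice_index`).
#' @param texture_cfg a [texture_config()].
#' @param mink_cfg a [minkowski_config()].
#' @return list of class `feature_row`: `subject_id`, `slice_index`,
#'   `values` (named numeric vector), `mask_pixel_count`.
#' @export
extract_slice_features <- function(slice, texture_cfg = texture_config(),
                                   mink_cfg = minkowski_config()) {
  id <- paste0(slice$subject_id, "/", slice$slice_index)
  bb <- bounding_box(slice$mask, id = id)
  roi <- slice$image[bb["r0"]:(bb["r1"] - 1L), bb["c0"]:(bb["c1"] - 1L),
                     drop = FALSE]
  vals <- c(texture_features(roi, texture_cfg),
            minkowski_features(slice$image, slice$mask, mink_cfg))
  structure(list(subject_id = slice$subject_id,
                 slice_index = slice$slice_index,
                 values = vals,
                 mask_pixel_count = sum(slice$mask)),
            class = "feature_row")
}

#' Radiomic feature table for a cohort
#'
#' Applies [extract_slice_features()] to every slice and assembles a
#' `feature_table` data frame: one row per slice with subject metadata, the
#' mask pixel count, and the 90 feature columns (manifest in
#' `attr(, "features")`).
#'
#' @param cohort a [make_cohort()] result (or any list of `slice_record`s in
#'   `$slices` plus a `$subjects` data frame).
#' @inheritParams extract_slice_features
#' @return data frame of class `feature_table`.
#' @export
radiomic_feature_table <- function(cohort, texture_cfg = texture_config(),
                                   mink_cfg = minkowski_config()) {
  rows <- lapply(cohort$slices, extract_slice_features,
                 texture_cfg = texture_cfg, mink_cfg = mink_cfg)
  manifest <- names(rows[[1]]$values)
  for (r in rows) stopifnot(identical(names(r$values), manifest))
  meta <- data.frame(
    subject_id = vapply(rows, `[[`, "", "subject_id"),
    slice_index = vapply(rows, `[[`, 0L, "slice_index"),
    mask_pixel_count = vapply(rows, `[[`, 0L, "mask_pixel_count"),
    stringsAsFactors = FALSE
  )
  sub <- cohort$subjects
  meta$label <- sub$label[match(meta$subject_id, sub$subject_id)]
  meta$split <- sub$split[match(meta$subject_id, sub$subject_id)]
  vals <- do.call(rbind, lapply(rows, `[[`, "values"))
  out <- cbind(meta, as.data.frame(vals))
  rownames(out) <- names(cohort$slices)
  attr(out, "features") <- manifest
  class(out) <- c("feature_table", "data.frame")
  out
}
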