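# Shared fixtures. The small cohort is generated once per test run and
# cached; tests must not mutate it.

.fixture_env <- new.env(parent = emptyenv())

small_spec <- function(seed = 101L, noise_sd = 0.05, ...) {
  cohort_spec(n_control = 6L, n_treated = 6L, image_size = 64L, L = 128L,
              slices_per_subject = c(1L, 3L), grid_size = 10L,
              noise_sd = noise_sd, holdout_fraction = 0.5, seed = seed, ...)
}

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    gs <- make_sources(K = 4, L = 128, seed = 101L)
    .fixture_env$cohort <- make_cohort(small_spec(), gs)
    .fixture_env$sources <- gs
  }
  .fixture_env$cohort
}

small_sources <- function() {
  small_cohort()
  .fixture_env$sources
}

# permute subject labels within each split (keeps per-split class balance so
# grouped stratified folds stay feasible); slices follow their subject
permute_cohort_labels <- function(cohort, seed) {
  set.seed(seed)
  sub <- cohort$subjects
  for (sp in unique(sub$split)) {
    i <- which(sub$split == sp)
    sub$label[i] <- sub$label[i][sample.int(length(i))]
  }
  cohort$subjects <- sub
  lab_of <- stats::setNames(sub$label, sub$subject_id)
  for (k in names(cohort$slices)) {
    cohort$slices[[k]]$label <- lab_of[[cohort$slices[[k]]$subject_id]]
  }
  cohort
}

# tiny deterministic slice_record for unit tests
toy_slice <- function(grid_size = 10L, image_size = 40L, seed = 1L,
                      mask_all = FALSE) {
  set.seed(seed)
  img <- matrix(stats::runif(image_size^2), image_size, image_size)
  mask <- matrix(FALSE, image_size, image_size)
  if (mask_all) {
    mask[] <- TRUE
  } else {
    mask[10:30, 10:30] <- TRUE
  }
  b <- max(2L, as.integer(floor(image_size * 0.36 / grid_size)))
  g <- expand.grid(col = seq_len(grid_size), row = seq_len(grid_size))
  r0 <- (image_size - b * grid_size) %/% 2 + 1L
  bm <- data.frame(row = g$row, col = g$col,
                   r0 = r0 + (g$row - 1L) * b, r1 = r0 + g$row * b,
                   c0 = r0 + (g$col - 1L) * b, c1 = r0 + g$col * b)
  in_tumor <- vapply(seq_len(nrow(bm)), function(i) {
    all(mask[bm$r0[i]:(bm$r1[i] - 1L), bm$c0[i]:(bm$c1[i] - 1L)])
  }, logical(1))
  L <- 64L
  grid <- structure(list(dims = c(grid_size, grid_size),
                         spectra = matrix(stats::runif(grid_size^2 * L),
                                          grid_size^2, L),
                         ppm_axis = seq(4.5, 0.5, length.out = L),
                         block_map = bm, in_tumor = in_tumor),
                    class = "mrsi_grid")
  structure(list(subject_id = "T001", slice_index = 1L, label = "treated",
                 split = "holdout", image = img, mask = mask, grid = grid),
            class = "slice_record")
}
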