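# End-to-end pipelines: radiomics -> selection -> linear classification ->
# SVS on the MRI side; convex-NMF weights -> selection -> classification ->
# VVS + nosological maps on the MRSI side; and a synthetic benchmark that
# runs both on a generated cohort.

.split_rows <- function(tab) {
  list(train = which(tab$split == "train"),
       holdout = which(tab$split == "holdout"))
}

.subject_accuracy <- function(decisions, truth_by_subject) {
  labs <- vapply(decisions, `[[`, 0, "label")
  ids <- vapply(decisions, `[[`, "", "subject_id")
  mean(labs == truth_by_subject[ids])
}

#' Run the MRI (radiomics) pipeline
#'
#' Extracts the 90-feature radiomic table, ranks features on the training
#' split (t-test filter or the hybrid embedded-then-wrapper RFE), then for
#' every subset size in `sweep` trains the linear model on training slices
#' and reports training LOO-CV accuracy, holdout per-slice accuracy and
#' holdout SVS (mask-pixel-weighted slice vote) subject accuracy.
#'
#' @param cohort a [make_cohort()] result (or compatible list).
#' @param model_type `"lr"` (default, the best MRI performer), `"lda"`, `"svm"`.
#' @param scheme `"ttest"` or `"hybrid"`.
#' @param sweep subset sizes to evaluate (default 1..30; capped at the
#'   manifest size and, for the hybrid scheme, at `m`).
#' @param m features retained by the embedded stage of the hybrid scheme.
#' @param k_folds embedded-stage folds.
#' @param seed fold seed.
#' @param feature_table optionally, a precomputed [radiomic_feature_table()].
#' @return list: `feature_table`, `ranking`, `trace` (subset_size,
#'   cv_accuracy, slice_accuracy, svs_accuracy), `decisions` (per-subject SVS
#'   decisions at the best SVS size), `best_size`.
#' @export
run_mri_pipeline <- function(cohort, model_type = "lr",
                             scheme = c("ttest", "hybrid"),
                             sweep = 1:30, m = 30L, k_folds = 5L, seed = 1L,
                             feature_table = NULL) {
  scheme <- match.arg(scheme)
  ft <- if (is.null(feature_table)) radiomic_feature_table(cohort)
        else feature_table
  feats <- attr(ft, "features")
  rows <- .split_rows(ft)
  if (length(rows$train) == 0) stop("no training slices")
  Xtr <- as.matrix(ft[rows$train, feats])
  ytr <- ft$label[rows$train]
  gtr <- ft$subject_id[rows$train]

  m <- min(m, length(feats))
  ranking <- if (scheme == "ttest") {
    ttest_rank(Xtr, ytr)
  } else {
    hybrid_embedded_then_wrapper(Xtr, ytr, gtr, model_type,
                                 k_folds = k_folds, protocol = "loo",
                                 m = m, seed = seed)
  }
  ranked <- if (scheme == "ttest") ranking$features else ranking$ranking
  sweep <- sweep[sweep <= min(length(ranked), m)]

  truth <- stats::setNames(ifelse(cohort$subjects$label == "treated", 1, -1),
                           cohort$subjects$subject_id)
  has_holdout <- length(rows$holdout) > 0
  trace <- data.frame(subset_size = integer(), cv_accuracy = numeric(),
                      slice_accuracy = numeric(), svs_accuracy = numeric())
  best <- list(acc = -1, size = NA_integer_, decisions = NULL)
  for (sz in sweep) {
    sel <- ranked[seq_len(sz)]
    cv <- cv_evaluate(Xtr[, sel, drop = FALSE], ytr, gtr, model_type,
                      protocol = "loo")
    slice_acc <- NA_real_; svs_acc <- NA_real_; dec <- NULL
    if (has_holdout) {
      mod <- train_linear(Xtr[, sel, drop = FALSE], ytr, model_type)
      sho <- predict(mod, as.matrix(ft[rows$holdout, sel, drop = FALSE]))
      pred <- score_to_label(sho)
      yho <- ifelse(ft$label[rows$holdout] == "treated", 1, -1)
      slice_acc <- mean(pred == yho)
      hsub <- split(seq_along(pred), ft$subject_id[rows$holdout])
      dec <- lapply(names(hsub), function(id) {
        i <- hsub[[id]]
        svs_vote((pred[i] + 1) / 2, ft$mask_pixel_count[rows$holdout][i],
                 subject_id = id)
      })
      svs_acc <- .subject_accuracy(dec, truth)
    }
    trace <- rbind(trace, data.frame(subset_size = sz,
                                     cv_accuracy = cv$accuracy,
                                     slice_accuracy = slice_acc,
                                     svs_accuracy = svs_acc))
    score <- if (has_holdout) svs_acc else cv$accuracy
    if (!is.na(score) && score > best$acc) {
      best <- list(acc = score, size = sz, decisions = dec)
    }
  }
  list(feature_table = ft, ranking = ranking, trace = trace,
       decisions = best$decisions, best_size = best$size,
       scheme = scheme, model_type = model_type)
}

#' Run the MRSI (convex-NMF) pipeline
#'
#' Pools tumor-complete voxel spectra, fits convex NMF with `K` sources on
#' the training spectra (or on all spectra when `paper_mode = TRUE`,
#' reproducing the original joint fit), projects every spectrum onto the
#' sources by nonnegative least squares, ranks the source-weight features
#' (t-test filter or wrapper RFE under grouped k-fold CV), and for every
#' subset size reports training CV accuracy, holdout per-voxel accuracy and
#' holdout VVS subject accuracy. Nosological maps are built for every holdout
#' slice at the best VVS size.
#'
#' @param cohort a [make_cohort()] result.
#' @param K number of sources (default 20).
#' @param model_type `"svm"` (default, the best MRSI performer), `"lr"`, `"lda"`.
#' @param scheme `"ttest"` or `"wrapper"`.
#' @param sweep subset sizes (default 1..K).
#' @param k CV folds (default 20, capped at the number of training subjects).
#' @param paper_mode fit the factorization on training + holdout jointly.
#' @param seed seed for the factorization and folds.
#' @param map_dir if non-NULL, renders a PNG map per holdout slice there.
#' @return list: `source_set`, `weight_table`, `ranking`, `trace`
#'   (subset_size, cv_accuracy, voxel_accuracy, vvs_accuracy), `decisions`,
#'   `maps`, `best_size`.
#' @export
run_mrsi_pipeline <- function(cohort, K = 20L, model_type = "svm",
                              scheme = c("ttest", "wrapper"),
                              sweep = NULL, k = 20L, paper_mode = FALSE,
                              seed = 1L, map_dir = NULL) {
  scheme <- match.arg(scheme)
  sub <- cohort$subjects
  split_of <- stats::setNames(sub$split, sub$subject_id)
  pooled <- pool_tumor_spectra(cohort$slices)
  ids <- pooled$row_ids
  is_train <- split_of[ids$subject_id] == "train"

  fitX <- if (paper_mode) pooled$X else pooled$X[is_train, , drop = FALSE]
  if (nrow(fitX) < K) stop("fewer training spectra than sources (K)")
  ss <- fit_convex_nmf(fitX, K = K, seed = seed, ppm_axis = pooled$ppm_axis)
  Wall <- project_spectra(pooled$X, ss)

  labs <- stats::setNames(sub$label, sub$subject_id)[ids$subject_id]
  Xtr <- Wall[is_train, , drop = FALSE]
  ytr <- labs[is_train]
  gtr <- ids$subject_id[is_train]
  kk <- min(k, length(unique(gtr)))

  ranking <- if (scheme == "ttest") {
    ttest_rank(Xtr, ytr)
  } else {
    wrapper_rfe(Xtr, ytr, gtr, model_type, protocol = "kfold", k = kk,
                seed = seed)
  }
  ranked <- if (scheme == "ttest") ranking$features else ranking$ranking
  if (is.null(sweep)) sweep <- seq_len(K)
  sweep <- sweep[sweep <= length(ranked)]

  truth <- stats::setNames(ifelse(sub$label == "treated", 1, -1),
                           sub$subject_id)
  has_holdout <- any(!is_train)
  trace <- data.frame(); best <- list(acc = -1, size = NA_integer_)
  for (sz in sweep) {
    sel <- ranked[seq_len(sz)]
    cv <- cv_evaluate(Xtr[, sel, drop = FALSE], ytr, gtr, model_type,
                      protocol = "kfold", k = kk, seed = seed)
    vox_acc <- NA_real_; vvs_acc <- NA_real_
    if (has_holdout) {
      mod <- train_linear(Xtr[, sel, drop = FALSE], ytr, model_type)
      sho <- predict(mod, Wall[!is_train, sel, drop = FALSE])
      pred <- score_to_label(sho)
      yho <- ifelse(labs[!is_train] == "treated", 1, -1)
      vox_acc <- mean(pred == yho)
      hsub <- split(seq_along(pred), ids$subject_id[!is_train])
      dec <- lapply(names(hsub), function(id) {
        vvs_vote(pred[hsub[[id]]], subject_id = id)
      })
      vvs_acc <- .subject_accuracy(dec, truth)
    }
    trace <- rbind(trace, data.frame(subset_size = sz,
                                     cv_accuracy = cv$accuracy,
                                     voxel_accuracy = vox_acc,
                                     vvs_accuracy = vvs_acc))
    score <- if (has_holdout) vvs_acc else cv$accuracy
    if (!is.na(score) && score > best$acc) best <- list(acc = score, size = sz)
  }

  # final model at the best size: decisions, calibration, maps
  sel <- ranked[seq_len(best$size)]
  mod <- train_linear(Xtr[, sel, drop = FALSE], ytr, model_type)
  str_scores <- predict(mod, Xtr[, sel, drop = FALSE])
  calib <- score_calibration(str_scores, ytr)
  decisions <- NULL; maps <- list()
  if (has_holdout) {
    sho <- predict(mod, Wall[!is_train, sel, drop = FALSE])
    pred <- score_to_label(sho)
    hids <- ids[!is_train, ]
    decisions <- lapply(split(seq_along(pred), hids$subject_id),
                        function(i) vvs_vote(pred[i],
                                             subject_id = hids$subject_id[i[1]]))
    names(decisions) <- vapply(decisions, `[[`, "", "subject_id")
    # one map per holdout slice with >= 1 tumor voxel
    key_of <- paste0(hids$subject_id, "_", hids$slice_index)
    for (key in unique(key_of)) {
      slice <- cohort$slices[[key]]
      maps[[key]] <- build_map(slice, sho[key_of == key], calib)
      if (!is.null(map_dir)) {
        dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
        render_map(maps[[key]], slice$image,
                   file.path(map_dir, paste0(key, ".png")))
      }
    }
  }
  list(source_set = ss, weight_table = Wall, row_ids = ids,
       ranking = ranking, trace = trace, decisions = decisions,
       maps = maps, calibration = calib, best_size = best$size,
       scheme = scheme, model_type = model_type)
}

#' Synthetic end-to-end benchmark
#'
#' Generates a seeded cohort, runs both pipelines, and returns (optionally
#' writes) a report of the accuracy traces and subject decisions.
#'
#' @param spec a [cohort_spec()].
#' @param K_truth number of ground-truth sources to simulate.
#' @param K_fit number of sources extracted by convex NMF.
#' @param mri_scheme,mrsi_scheme selection schemes per pipeline.
#' @param seed master seed (overrides `spec$seed`).
#' @param out_dir if non-NULL, writes `report.json` and `report.md` there.
#' @return list: `cohort`, `mri`, `mrsi`, `report` (summary list).
#' @export
run_synthetic_benchmark <- function(spec = cohort_spec(), K_truth = 4L,
                                    K_fit = 20L, mri_scheme = "ttest",
                                    mrsi_scheme = "ttest", seed = NULL,
                                    out_dir = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  gs <- make_sources(K = K_truth, L = spec$L, seed = spec$seed)
  cohort <- make_cohort(spec, gs)
  mri <- run_mri_pipeline(cohort, scheme = mri_scheme, seed = spec$seed)
  mrsi <- run_mrsi_pipeline(cohort, K = K_fit, scheme = mrsi_scheme,
                            seed = spec$seed)
  report <- list(
    seed = spec$seed,
    n_subjects = nrow(cohort$subjects),
    n_slices = length(cohort$slices),
    mri_trace = mri$trace,
    mrsi_trace = mrsi$trace,
    mri_best = list(size = mri$best_size,
                    svs_accuracy = max(mri$trace$svs_accuracy, na.rm = TRUE)),
    mrsi_best = list(size = mrsi$best_size,
                     vvs_accuracy = max(mrsi$trace$vvs_accuracy, na.rm = TRUE))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    md <- c("# Synthetic benchmark report", "",
            sprintf("- seed: %d", report$seed),
            sprintf("- subjects: %d, slices: %d", report$n_subjects,
                    report$n_slices),
            sprintf("- best SVS holdout accuracy: %.3f (%d features)",
                    report$mri_best$svs_accuracy, report$mri_best$size),
            sprintf("- best VVS holdout accuracy: %.3f (%d sources)",
                    report$mrsi_best$vvs_accuracy, report$mrsi_best$size))
    writeLines(md, file.path(out_dir, "report.md"))
  }
  list(cohort = cohort, mri = mri, mrsi = mrsi, report = report)
}
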