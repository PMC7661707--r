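# Subject-level fusion of per-slice (SVS) and per-voxel (VVS) classifier
# outputs. Fused values live in [0, 1] toward "treated"; the documented tie
# rule maps a fused value of exactly 0.5 to treated.

#' Slice-voting system (SVS)
#'
#' Weighted average of per-slice responses, the weight of a slice being the
#' pixel count of its tumor mask, so slices showing more tumor (central
#' slices) count more.
#'
#' @param responses per-slice responses in `[0, 1]` (default use: the binary
#'   predicted label, 1 = treated).
#' @param weights positive slice weights (mask pixel counts).
#' @param subject_id optional id carried into the result.
#' @return list of class `subject_decision`: `method = "SVS"`, `fused`
#'   (weighted mean in [0,1]), `label` (+1 treated iff fused >= 0.5, else -1),
#'   `tallies`.
#' @export
svs_vote <- function(responses, weights, subject_id = NA_character_) {
  stopifnot(length(responses) >= 1, length(weights) == length(responses),
            all(responses >= 0 & responses <= 1))
  if (all(weights == 0)) stop("all-zero slice weights")
  stopifnot(all(weights > 0))
  fused <- sum(weights * responses) / sum(weights)
  structure(list(subject_id = subject_id, method = "SVS", fused = fused,
                 label = if (fused >= 0.5) 1 else -1,
                 tallies = data.frame(response = responses, weight = weights)),
            class = "subject_decision")
}

#' Voxel-voting system (VVS)
#'
#' Majority vote over the predicted labels of all classified voxels of a
#' subject, pooled across slices (every voxel covers the same tissue volume,
#' so votes are unweighted).
#'
#' @param voxel_labels vector of predicted voxel labels in {-1, +1} (or
#'   {0, 1}), pooled over all slices of the subject.
#' @param subject_id optional id.
#' @return `subject_decision` with `method = "VVS"`, `fused` = fraction of
#'   voxels voting treated, `label` = majority (tie to treated), and
#'   `tallies` (`n_treated`, `n_control`) used for the map's top bar.
#' @export
vvs_vote <- function(voxel_labels, subject_id = NA_character_) {
  if (length(voxel_labels) == 0) stop("no classified voxels")
  v <- ifelse(voxel_labels > 0, 1, 0)
  fused <- mean(v)
  structure(list(subject_id = subject_id, method = "VVS", fused = fused,
                 label = if (fused >= 0.5) 1 else -1,
                 tallies = c(n_treated = sum(v == 1),
                             n_control = sum(v == 0))),
            class = "subject_decision")
}

#' @export
print.subject_decision <- function(x, ...) {
  cat(sprintf("%s decision for %s: fused = %.3f -> %s\n", x$method,
              x$subject_id, x$fused,
              if (x$label > 0) "treated" else "control"))
  invisible(x)
}
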