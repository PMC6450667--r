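#' Classify trial-level retrieval success from wrapped errors
#'
#' A feature counts as successfully retrieved when its absolute wrapped
#' error is at or below the feature's success threshold (the posterior-0.5
#' boundary of the mixture fit, or a fixed value). The boundary is
#' inclusive: an error exactly at the threshold is "correct". Emotion
#' memory is coded 0 (incorrect), 0.5 (correct, low confidence) or 1
#' (correct, high confidence). Trials with a missing response are scored
#' unsuccessful and flagged.
#'
#' @param trials Trial table with `err_color_deg`, `err_scene_deg`,
#'   `emotion_correct`, `emotion_confidence`.
#' @param thresholds Named numeric vector `c(color = ..., scene = ...)` in
#'   degrees, each in (0, 180].
#' @return The table with added columns `success_color`, `success_scene`
#'   (0/1), `emotion_score` (0/0.5/1), and `missing_color`/`missing_scene`
#'   flags.
#' @export
classify_trials <- function(trials, thresholds) {
  stopifnot(all(c("color", "scene") %in% names(thresholds)))
  if (any(thresholds <= 0 | thresholds > 180)) {
    stop("thresholds must lie in (0, 180]")
  }
  miss_c <- is.na(trials$err_color_deg)
  miss_s <- is.na(trials$err_scene_deg)
  trials$success_color <- as.integer(!miss_c &
                                       abs(trials$err_color_deg) <= thresholds[["color"]])
  trials$success_scene <- as.integer(!miss_s &
                                       abs(trials$err_scene_deg) <= thresholds[["scene"]])
  trials$missing_color <- miss_c
  trials$missing_scene <- miss_s
  emo_corr <- !is.na(trials$emotion_correct) & trials$emotion_correct == 1L
  high <- !is.na(trials$emotion_confidence) & trials$emotion_confidence == "high"
  trials$emotion_score <- ifelse(emo_corr, ifelse(high, 1, 0.5), 0)
  trials
}

#' Per-trial precision of successfully retrieved features
#'
#' Precision is the reversed absolute error, `180 - |error|`, defined only
#' on trials where the feature was successfully retrieved; it is missing
#' (`NA`) on unsuccessful trials. Higher values mean more precise memory;
#' an error of 0 gives the maximum of 180.
#'
#' @param scores Output of [classify_trials()].
#' @return The table with `precision_color` and `precision_scene` added.
#' @export
precision_scores <- function(scores) {
  stopifnot(all(c("success_color", "success_scene") %in% names(scores)))
  scores$precision_color <- ifelse(scores$success_color == 1L,
                                   180 - abs(scores$err_color_deg), NA_real_)
  scores$precision_scene <- ifelse(scores$success_scene == 1L,
                                   180 - abs(scores$err_scene_deg), NA_real_)
  scores
}

#' Composite multidimensional memory-quality score (0 to 3)
#'
#' Sums, per trial, the emotion score (0 / 0.5 / 1) and a scaled memory
#' score for each visual feature: 0 when retrieval failed, and otherwise
#' the precision of the retrieved feature scaled to (0, 1\] so that an
#' error of 0 contributes 1 (perfect feature memory). Two scalings are
#' available: `"threshold"` (default) maps the error range \[0, threshold\]
#' linearly onto \[1, 0\], which is continuous at the success boundary;
#' `"half_circle"` maps \[0, 180\] onto \[1, 0\] regardless of threshold.
#'
#' @param scores Output of [precision_scores()].
#' @param thresholds Named vector `c(color=, scene=)` in degrees.
#' @param scaling `"threshold"` or `"half_circle"`.
#' @return The table with a `quality` column in \[0, 3\].
#' @export
memory_quality <- function(scores, thresholds,
                           scaling = c("threshold", "half_circle")) {
  scaling <- match.arg(scaling)
  q_feat <- function(success, err, thr) {
    denom <- if (scaling == "threshold") thr else 180
    ifelse(success == 1L, pmax(0, 1 - abs(err) / denom), 0)
  }
  scores$quality <- scores$emotion_score +
    q_feat(scores$success_color, scores$err_color_deg, thresholds[["color"]]) +
    q_feat(scores$success_scene, scores$err_scene_deg, thresholds[["scene"]])
  scores
}

#' Flag subjects with chance-level continuous-report performance
#'
#' Subjects whose mean absolute wrapped error is 75 degrees or more on the
#' color or the scene question are excluded from all analyses (uniform
#' guessing has an expected mean absolute error of 90 degrees, so such
#' performance is indistinguishable from chance and mixture estimates
#' become unreliable). The boundary is inclusive: exactly 75 excludes.
#'
#' @param trials Trial table with `subject`, `err_color_deg`,
#'   `err_scene_deg`.
#' @param cutoff_deg Exclusion cutoff (default 75).
#' @return A data.frame with one row per subject: `subject`,
#'   `mean_abs_err_color`, `mean_abs_err_scene`, `included` (logical).
#' @export
exclude_subjects <- function(trials, cutoff_deg = 75) {
  subs <- sort(unique(trials$subject))
  out <- lapply(subs, function(s) {
    tr <- trials[trials$subject == s, ]
    mc <- mean(abs(tr$err_color_deg), na.rm = TRUE)
    ms <- mean(abs(tr$err_scene_deg), na.rm = TRUE)
    data.frame(subject = s, mean_abs_err_color = mc, mean_abs_err_scene = ms,
               included = mc < cutoff_deg & ms < cutoff_deg)
  })
  do.call(rbind, out)
}

#' Score a trial table end to end
#'
#' Convenience wrapper: classification, precision, and quality in one call.
#'
#' @inheritParams classify_trials
#' @inheritParams memory_quality
#' @return Scored trial table with all columns added.
#' @export
score_trials <- function(trials, thresholds,
                         scaling = c("threshold", "half_circle")) {
  scaling <- match.arg(scaling)
  s <- classify_trials(trials, thresholds)
  s <- precision_scores(s)
  memory_quality(s, thresholds, scaling)
}
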