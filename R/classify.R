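#' Classifier configuration
#'
#' Thresholds and combination rule for the three-way screening call. The
#' default thresholds are the published separation lines (27.3 on the FT2
#' area, -0.1 on the ramp feature, 33.8 as the healthy-young floor); they
#' were calibrated on a clinical cohort under that study's feature scaling
#' and are not transferable across normalizations, so recalibration with
#' [calibrate_thresholds()] is recommended for any new feature pipeline.
#'
#' @param ft2_threshold Pathological vote when `ft2_area` falls *below*
#'   this value.
#' @param ramp_threshold Pathological vote when `ramp_feature` rises
#'   *above* this value.
#' @param young_ft2_floor Minimum `ft2_area` for a healthy-young-like call.
#' @param combine_rule How the two per-feature votes combine into the
#'   pathological call: `"either_positive"` (either vote suffices),
#'   `"either_agrees"` (both must vote pathological), `"single_ft2"` or
#'   `"single_ramp"`.
#' @param suspect_margin Optional half-width of a "suspected" band around
#'   each threshold (0 disables the intermediate category).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(ft2_threshold = 27.3, ramp_threshold = -0.1,
                              young_ft2_floor = 33.8,
                              combine_rule = c("either_positive",
                                               "either_agrees",
                                               "single_ft2", "single_ramp"),
                              suspect_margin = 0) {
  combine_rule <- match.arg(combine_rule)
  stopifnot(is.finite(ft2_threshold), is.finite(ramp_threshold),
            is.finite(young_ft2_floor), suspect_margin >= 0)
  structure(list(ft2_threshold = ft2_threshold,
                 ramp_threshold = ramp_threshold,
                 young_ft2_floor = young_ft2_floor,
                 combine_rule = combine_rule,
                 suspect_margin = suspect_margin),
            class = "classifier_config")
}

#' Classify a case from its spectral features
#'
#' Applies the threshold rules: the FT2 vote is pathological iff
#' `ft2_area < ft2_threshold` (pathological cases lie below the separation
#' line), the ramp vote is pathological iff
#' `ramp_feature > ramp_threshold` (they lie above that line); ties at a
#' threshold resolve to healthy. The votes combine per the configured rule;
#' a non-pathological case is healthy-young-like iff its `ft2_area` reaches
#' the young floor and the ramp vote is negative, otherwise
#' healthy-elderly-like. With a positive `suspect_margin`, cases whose
#' deciding features fall within the margin of a threshold are labelled
#' `"suspected"`.
#'
#' @param features A [case_features()] object or a list with `ft2_area`
#'   and `ramp_feature`.
#' @param config A [classifier_config()].
#' @return An object of class `case_call`: list with `label` (one of
#'   `"pathological"`, `"healthy_elderly_like"`, `"healthy_young_like"`,
#'   `"suspected"`) and `per_feature_calls` (named logical pathological
#'   votes).
#' @export
call_case <- function(features, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  ft2 <- features$ft2_area
  ramp <- features$ramp_feature
  if (is.null(ft2) || is.null(ramp) || !is.finite(ft2) || !is.finite(ramp))
    stop("both `ft2_area` and `ramp_feature` must be present and finite",
         call. = FALSE)
  ft2_vote <- ft2 < config$ft2_threshold
  ramp_vote <- ramp > config$ramp_threshold
  path <- switch(config$combine_rule,
                 either_positive = ft2_vote || ramp_vote,
                 either_agrees = ft2_vote && ramp_vote,
                 single_ft2 = ft2_vote,
                 single_ramp = ramp_vote)
  label <- if (path) {
    "pathological"
  } else if (ft2 >= config$young_ft2_floor && !ramp_vote) {
    "healthy_young_like"
  } else {
    "healthy_elderly_like"
  }
  if (config$suspect_margin > 0 &&
      (abs(ft2 - config$ft2_threshold) < config$suspect_margin ||
       abs(ramp - config$ramp_threshold) < config$suspect_margin)) {
    label <- "suspected"
  }
  structure(list(label = label,
                 per_feature_calls = c(ft2 = ft2_vote, ramp = ramp_vote)),
            class = "case_call")
}

#' @export
print.case_call <- function(x, ...) {
  cat(sprintf("<case_call> %s (votes: ft2 %s, ramp %s)\n", x$label,
              x$per_feature_calls["ft2"], x$per_feature_calls["ramp"]))
  invisible(x)
}

#' Sensitivity and specificity of a set of calls
#'
#' Confusion counts and rates with pathological as the positive class.
#' A rate with a zero denominator is reported as `NA` with a warning.
#'
#' @param calls Character vector of labels (or list of `case_call`
#'   objects); anything other than `"pathological"` counts as negative.
#' @param truth Character vector of true labels, same convention.
#' @return An object of class `cohort_metrics`: list with `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`.
#' @export
cohort_metrics <- function(calls, truth) {
  if (is.list(calls))
    calls <- vapply(calls, function(x) x$label, "")
  if (length(calls) != length(truth))
    stop("`calls` and `truth` must have the same length", call. = FALSE)
  cp <- calls == "pathological"
  tp_ <- truth == "pathological"
  tp <- sum(cp & tp_); fn <- sum(!cp & tp_)
  fp <- sum(cp & !tp_); tn <- sum(!cp & !tp_)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive cases in truth; sensitivity undefined"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no negative cases in truth; specificity undefined"); NA_real_
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec),
            class = "cohort_metrics")
}

#' @export
print.cohort_metrics <- function(x, ...) {
  cat(sprintf("<cohort_metrics> tp %d fp %d tn %d fn %d | sensitivity %.3f specificity %.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity))
  invisible(x)
}

#' Best single-threshold classification accuracy
#'
#' Exhaustive scan over the midpoints of sorted unique feature values plus
#' the two extreme values themselves; for each candidate threshold both
#' polarities (positive above or below) are considered and the best accuracy
#' kept. Because the comparisons are strict, the extreme values cover the
#' degenerate all-negative split, which can beat every interior split when
#' one class dominates. Ties break toward the lowest threshold. With all
#' values identical the accuracy is the majority-class fraction.
#'
#' @param values Numeric feature values.
#' @param truth Logical (or 0/1) class labels, same length; both classes
#'   must be present.
#' @return List with `threshold` and `accuracy`.
#' @export
#' @examples
#' best_threshold_accuracy(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE))
best_threshold_accuracy <- function(values, truth) {
  truth <- as.logical(truth)
  stopifnot(length(values) == length(truth), !anyNA(values), !anyNA(truth))
  if (all(truth) || !any(truth))
    stop("both classes must be present", call. = FALSE)
  u <- sort(unique(values))
  if (length(u) == 1)
    return(list(threshold = u, accuracy = max(mean(truth), mean(!truth))))
  cand <- unique(c(u[1], (u[-1] + u[-length(u)]) / 2, u[length(u)]))
  best <- list(threshold = cand[1], accuracy = -1)
  for (th in cand) {
    acc <- max(mean((values > th) == truth), mean((values < th) == truth))
    if (acc > best$accuracy) best <- list(threshold = th, accuracy = acc)
  }
  best
}

# Best threshold under a fixed vote direction. Candidates are the midpoints
# of sorted unique values plus both extremes; because the vote inequalities
# are strict (`< th` for "below", `> th` for "above"), the extremes give the
# degenerate always-negative vote, which is the correct calibration when the
# feature carries no signal in the configured direction. Ties break toward
# the lowest threshold.
directional_threshold <- function(values, positive,
                                  direction = c("below", "above")) {
  direction <- match.arg(direction)
  u <- sort(unique(values))
  cand <- unique(c(u[1], (u[-1] + u[-length(u)]) / 2, u[length(u)]))
  best <- NULL
  for (th in cand) {
    vote <- if (direction == "below") values < th else values > th
    acc <- mean(vote == positive)
    if (is.null(best) || acc > best$accuracy)
      best <- list(threshold = th, accuracy = acc)
  }
  best
}

#' Calibrate classifier thresholds on a labelled cohort
#'
#' Fits the FT2 and ramp thresholds by maximizing the accuracy of each
#' per-feature pathological vote *under the classifier's fixed vote
#' direction* (FT2 votes pathological below its threshold, ramp above), and
#' the young floor for the young-vs-rest split of the non-pathological
#' cases. Fitting under the actual vote polarity matters: if a feature does
#' not order pathological cases in the configured direction on the
#' calibration cohort, the fitted threshold neutralizes its vote rather than
#' inverting the decision.
#'
#' @param features List of [case_features()] objects (or a data frame with
#'   columns `ft2_area`, `ramp_feature`).
#' @param truth Character vector of true labels (`"pathological"`,
#'   `"healthy_elderly_like"`, `"healthy_young_like"`).
#' @param ... Passed to [classifier_config()].
#' @return A calibrated [classifier_config()].
#' @export
calibrate_thresholds <- function(features, truth, ...) {
  if (is.list(features) && !is.data.frame(features))
    features <- data.frame(
      ft2_area = vapply(features, function(x) x$ft2_area, 0),
      ramp_feature = vapply(features, function(x) x$ramp_feature, 0))
  path <- truth == "pathological"
  if (all(path) || !any(path))
    stop("calibration needs pathological and non-pathological cases",
         call. = FALSE)
  ft2_th <- directional_threshold(features$ft2_area, path, "below")$threshold
  ramp_th <- directional_threshold(features$ramp_feature, path,
                                   "above")$threshold
  healthy <- !path
  floor_th <- if (any(truth[healthy] == "healthy_young_like") &&
                  any(truth[healthy] != "healthy_young_like")) {
    best_threshold_accuracy(features$ft2_area[healthy],
                            truth[healthy] == "healthy_young_like")$threshold
  } else {
    ft2_th
  }
  classifier_config(ft2_threshold = ft2_th, ramp_threshold = ramp_th,
                    young_ft2_floor = floor_th, ...)
}
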