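test_that("classifier_config validates and defaults to paper thresholds", {
  cfg <- classifier_config()
  expect_equal(cfg$ft2_threshold, 27.3)
  expect_equal(cfg$ramp_threshold, -0.1)
  expect_equal(cfg$young_ft2_floor, 33.8)
  expect_equal(cfg$combine_rule, "either_positive")
  expect_error(classifier_config(ft2_threshold = NA))
  expect_error(classifier_config(combine_rule = "bogus"))
})

test_that("call_case applies the threshold rules", {
  cfg <- classifier_config()
  # paper's pathological minimum, ramp above its line
  p <- call_case(list(ft2_area = 21.5, ramp_feature = 0.5), cfg)
  expect_equal(p$label, "pathological")
  expect_true(p$per_feature_calls[["ft2"]])
  # high ft2, negative ramp vote: reaches the young floor
  y <- call_case(list(ft2_area = 45, ramp_feature = -1), cfg)
  expect_equal(y$label, "healthy_young_like")
  # healthy but below the young floor
  e <- call_case(list(ft2_area = 30, ramp_feature = -1), cfg)
  expect_equal(e$label, "healthy_elderly_like")
  # ties at a threshold resolve to healthy
  t1 <- call_case(list(ft2_area = 27.3, ramp_feature = -0.1), cfg)
  expect_false(any(t1$per_feature_calls))
  expect_error(call_case(list(ft2_area = 1), cfg), "finite")
})

test_that("combine rules and the suspect margin behave as configured", {
  ft <- list(ft2_area = 20, ramp_feature = -1)  # only the ft2 vote fires
  expect_equal(call_case(ft, classifier_config())$label, "pathological")
  expect_equal(call_case(
    ft, classifier_config(combine_rule = "either_agrees"))$label,
    "healthy_elderly_like")
  expect_equal(call_case(
    ft, classifier_config(combine_rule = "single_ramp"))$label,
    "healthy_elderly_like")
  expect_equal(call_case(
    ft, classifier_config(combine_rule = "single_ft2"))$label,
    "pathological")
  s <- call_case(list(ft2_area = 27.0, ramp_feature = -3),
                 classifier_config(suspect_margin = 1))
  expect_equal(s$label, "suspected")
})

test_that("cohort_metrics counts the confusion table", {
  all_ok <- cohort_metrics(c("pathological", "healthy_young_like"),
                           c("pathological", "healthy_young_like"))
  expect_equal(all_ok$sensitivity, 1)
  expect_equal(all_ok$specificity, 1)
  m <- cohort_metrics(c("pathological", "healthy_elderly_like",
                        "healthy_elderly_like", "pathological"),
                      c("pathological", "pathological",
                        "healthy_elderly_like", "healthy_elderly_like"))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_warning(nd <- cohort_metrics(rep("healthy_elderly_like", 3),
                                      rep("healthy_elderly_like", 3)),
                 "sensitivity")
  expect_true(is.na(nd$sensitivity))
  expect_error(cohort_metrics("pathological", c("a", "b")), "length")
})

test_that("either_positive dominates single-feature sensitivity", {
  set.seed(12)
  for (i in 1:10) {
    feats <- data.frame(ft2_area = runif(30, 10, 60),
                        ramp_feature = runif(30, -2, 2))
    truth <- ifelse(runif(30) < 0.5, "pathological", "healthy_elderly_like")
    if (!any(truth == "pathological")) truth[1] <- "pathological"
    calls <- function(rule) {
      cfg <- classifier_config(combine_rule = rule)
      vapply(seq_len(30), function(r)
        call_case(feats[r, ], cfg)$label, "")
    }
    sens <- function(rule)
      suppressWarnings(cohort_metrics(calls(rule), truth)$sensitivity)
    expect_gte(sens("either_positive"),
               max(sens("single_ft2"), sens("single_ramp")))
  }
})

test_that("best_threshold_accuracy matches its examples", {
  b1 <- best_threshold_accuracy(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(b1$accuracy, 1)
  expect_equal(b1$threshold, 5.5)
  # a positive buried mid-sequence: every interior split scores 0.6 at
  # best, so the degenerate all-negative split (threshold at an extreme
  # value, strict comparison) must win with the majority fraction 0.8
  b2 <- best_threshold_accuracy(1:5, c(0, 0, 1, 0, 0))
  expect_equal(b2$accuracy, 0.8)
  expect_equal(b2$threshold, 1)
  b3 <- best_threshold_accuracy(rep(3, 5), c(1, 1, 1, 0, 0))
  expect_equal(b3$accuracy, 0.6)
  expect_error(best_threshold_accuracy(1:4, rep(TRUE, 4)), "both classes")
  # invariant under case reordering
  set.seed(13)
  v <- rnorm(15); tr <- runif(15) < 0.4
  if (!any(tr)) tr[1] <- TRUE
  if (all(tr)) tr[1] <- FALSE
  p <- sample(15)
  expect_equal(best_threshold_accuracy(v, tr),
               best_threshold_accuracy(v[p], tr[p]))
})

test_that("calibrate_thresholds separates a separable cohort", {
  feats <- data.frame(ft2_area = c(40, 45, 50, 10, 12, 15),
                      ramp_feature = c(-1, -1.2, -0.9, 1, 1.3, 0.8))
  truth <- rep(c("healthy_young_like", "pathological"), each = 3)
  cfg <- calibrate_thresholds(feats, truth)
  labels <- vapply(1:6, function(i) call_case(feats[i, ], cfg)$label, "")
  expect_equal(labels[4:6], rep("pathological", 3))
  expect_false(any(labels[1:3] == "pathological"))
  expect_error(calibrate_thresholds(feats, rep("pathological", 6)),
               "non-pathological")
})

test_that("calibration neutralizes a feature ordered against its polarity", {
  # ramp values here run *lower* for pathological cases, opposite to the
  # classifier's fixed pathological-above polarity: the fitted threshold
  # must disable the ramp vote rather than invert the decision
  feats <- data.frame(ft2_area = c(40, 45, 50, 10, 12, 15),
                      ramp_feature = c(1, 1.2, 0.9, -1, -1.3, -0.8))
  truth <- rep(c("healthy_young_like", "pathological"), each = 3)
  cfg <- calibrate_thresholds(feats, truth)
  votes <- vapply(1:6, function(i)
    call_case(feats[i, ], cfg)$per_feature_calls[["ramp"]], TRUE)
  expect_false(any(votes))
})
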