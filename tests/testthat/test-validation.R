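test_that("validation sampling is reproducible, stratified, and clamped", {
  season <- simulate_season(small_config(), seed = 21)
  det <- dplyr::select(season$detections, -truth, -source_species)

  s1 <- sample_for_validation(det, "Species alpha", "c10", n = 60, seed = 1)
  s2 <- sample_for_validation(det, "Species alpha", "c10", n = 60, seed = 2)
  s1b <- sample_for_validation(det, "Species alpha", "c10", n = 60, seed = 1)
  expect_identical(s1$detections, s1b$detections)
  expect_false(identical(s1$detections, s2$detections))

  pool <- det[det$scientific_name == "Species alpha" & det$confidence >= 0.10, ]
  key <- function(d) paste(d$recording_id, d$segment_start_s)
  expect_true(all(key(s1$detections) %in% key(pool)))
  expect_true(all(key(s2$detections) %in% key(pool)))
  expect_identical(nrow(s1$detections), 60L)
  expect_false(anyDuplicated(key(s1$detections)) > 0)

  s25 <- sample_for_validation(det, "Species alpha", "c25", n = 60, seed = 1)
  expect_true(all(s25$detections$confidence >= 0.25))

  # pool exactly n: returned whole regardless of seed
  tiny <- pool[1:10, ]
  t1 <- sample_for_validation(tiny, "Species alpha", "c10", n = 10, seed = 1)
  t2 <- sample_for_validation(tiny, "Species alpha", "c10", n = 10, seed = 99)
  expect_identical(t1$detections[names(tiny)], t2$detections[names(tiny)])

  expect_warning(sample_for_validation(tiny, "Species alpha", "c10",
                                       n = 60, seed = 1),
                 "only 10")
  expect_error(sample_for_validation(det, "Nonexistent bird", "c10", seed = 1),
               "no eligible")

  # clip window around an offset-zero segment is clamped at the start
  d0 <- toy_detections(0.9, start_s = 0)
  cl <- sample_for_validation(d0, "Species alpha", "c10", n = 1, seed = 1)
  expect_identical(cl$detections$clip_start_s, 0)
  expect_identical(cl$detections$clip_end_s, 4)
})

test_that("precision is the confirmed fraction of reviewed detections", {
  ann <- tibble::tibble(label = rep("true_positive", 60), confidence = 0.9)
  expect_equal(compute_precision(ann), 1.000)

  ann$label[1:53] <- "false_positive"
  expect_equal(round(compute_precision(ann), 3), 0.117)  # 7 of 60 confirmed

  ann$label <- "false_positive"
  expect_equal(compute_precision(ann), 0)
  expect_error(compute_precision(ann[0, ]), "undefined")
  expect_error(compute_precision(tibble::tibble(label = "maybe")), "maybe")
})

test_that("max false-positive confidence pools labelled strata", {
  ann <- tibble::tibble(
    label = c("false_positive", "true_positive", "false_positive",
              "false_positive"),
    confidence = c(0.21, 0.99, 0.448, 0.13))
  expect_equal(compute_max_fp_confidence(ann), 0.448)
  expect_true(is.na(compute_max_fp_confidence(
    tibble::tibble(label = "true_positive", confidence = 0.9))))

  set.seed(8)
  sim <- tibble::tibble(
    label = sample(c("true_positive", "false_positive"), 200, replace = TRUE),
    confidence = runif(200, 0.1, 1))
  expect_equal(compute_max_fp_confidence(sim),
               max(sim$confidence[sim$label == "false_positive"]))
})

test_that("segment sampling stays inside recordings and is seed-stable", {
  sched <- simulate_schedule(small_config())
  seg <- sample_segments(sched, n = 50, length_s = 120, seed = 4)
  expect_identical(nrow(seg), 50L)
  idx <- match(seg$recording_id, sched$recording_id)
  expect_true(all(seg$start_s >= 0))
  expect_true(all(seg$end_s <= sched$duration_s[idx]))
  expect_identical(seg, sample_segments(sched, n = 50, length_s = 120, seed = 4))

  one <- tibble::tibble(recording_id = "r", site_id = "s",
                        start = as.POSIXct("2022-05-19 05:00:00", tz = "UTC"),
                        duration_s = 120)
  forced <- sample_segments(one, n = 1, length_s = 120, seed = 1)
  expect_identical(forced$start_s, 0)
  expect_identical(forced$end_s, 120)
  expect_error(sample_segments(one, n = 1, length_s = 600, seed = 1),
               "no recording")
})

test_that("segment recall counts manually-confirmed segments the classifier matched", {
  seg <- tibble::tibble(
    segment_id = c("a", "b", "c"),
    manual_species = list("sp1", "sp1", character()),
    classifier_species = list("sp1", character(), "sp2"))
  expect_equal(compute_recall(seg, "sp1"), 0.500)
  expect_true(is.na(compute_recall(seg, "sp3")))  # never manually detected
  expect_equal(compute_recall(seg, "sp2"), NA_real_)

  all_match <- tibble::tibble(
    segment_id = "a", manual_species = list("sp1"),
    classifier_species = list(c("sp1", "sp2")))
  expect_equal(compute_recall(all_match, "sp1"), 1)

  # detected manually but never by the classifier: 0 by default,
  # missing under the stricter published exclusion
  never <- tibble::tibble(
    segment_id = c("a", "b"), manual_species = list("sp1", "sp1"),
    classifier_species = list(character(), character()))
  expect_equal(compute_recall(never, "sp1"), 0)
  expect_true(is.na(compute_recall(never, "sp1", missing_if_undetected = TRUE)))
})

test_that("F-score is the harmonic mean with missing-recall propagation", {
  expect_equal(round(compute_f_score(0.867, 1.000), 3), 0.929)
  expect_equal(round(compute_f_score(0.567, 0.500), 3), 0.531)
  expect_equal(compute_f_score(0.7, 0.7), 0.7)
  expect_equal(compute_f_score(0, 0), 0)
  expect_true(is.na(compute_f_score(0.9, NA)))
  expect_error(compute_f_score(1.2, 0.5), "\\[0, 1\\]")

  # harmonic-mean bounds: min(P, R) <= F <= max(P, R)
  set.seed(2)
  p <- runif(100); r <- runif(100)
  f <- compute_f_score(p, r)
  expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
})

test_that("the SSC decision rule selects among 0.10, 0.25, and the FP maximum", {
  expect_equal(assign_ssc(0.967, 1.000, 0.186), 0.100)
  expect_equal(assign_ssc(0.683, 0.879, 0.914), 0.250)
  expect_equal(assign_ssc(0.117, 0.333, 0.505), 0.505)
  # boundary is inclusive at 0.85
  expect_equal(assign_ssc(0.85, 0.2), 0.10)
  expect_equal(assign_ssc(0.2, 0.85, 0.9), 0.25)
  expect_error(assign_ssc(0.2, 0.2, NA), "missing")
  expect_equal(assign_ssc(c(0.9, 0.2), c(0.9, 0.9), c(NA, NA)),
               c(0.10, 0.25))
})

test_that("performance summaries reduce to the species' own values for one row", {
  perf <- tibble::tibble(scientific_name = "sp1", precision_c10 = 0.9,
                         precision_c25 = 0.95, max_fp_confidence = 0.3,
                         recall = 0.8)
  out <- summarize_performance(perf)
  expect_equal(out$table$f_score, round(compute_f_score(0.9, 0.8), 3))
  expect_equal(out$table$ssc, 0.1)
  expect_equal(out$column_summary$mean[out$column_summary$metric == "recall"],
               0.8)
  expect_identical(out$`n_precision_c10_gt_0.85`, 1L)
  expect_identical(out$`n_max_fp_lt_0.50`, 1L)
})
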