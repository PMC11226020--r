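## Classifier performance evaluation: validation-sample drawing, precision
## at the 0.10 and 0.25 confidence strata, maximum false-positive confidence,
## segment-level recall, F-score, and the species-specific confidence (SSC)
## decision rule.

.stratum_thresholds <- c(c10 = 0.10, c25 = 0.25)

#' Draw a validation sample of detections for one species
#'
#' Samples `n` detections of `species` without replacement from the stratum's
#' eligible pool (confidence at least 0.10 for `"c10"`, 0.25 for `"c25"`),
#' reproducibly under `seed`. Each sampled detection gets a review clip
#' window spanning its 3-s segment plus `pad_s` seconds before and after,
#' clamped to the recording bounds, so an external cutter can extract audio
#' for manual review.
#'
#' @param detections a detection tibble.
#' @param species scientific name to validate.
#' @param stratum `"c10"` (default run threshold 0.10) or `"c25"`.
#' @param n target sample size (60 by default). If fewer detections are
#'   eligible the full pool is returned with a shortfall warning.
#' @param seed integer seed recorded in the sample for auditability.
#' @param recordings optional recording-file tibble used to clamp clip
#'   windows to each recording's duration.
#' @param pad_s seconds of context on each side of the segment (default 1).
#'
#' @return A list of class `validation_sample` with elements `species`,
#'   `stratum`, `seed`, `n_requested`, and `detections` (the sampled rows
#'   plus `clip_start_s`/`clip_end_s`).
#' @export
sample_for_validation <- function(detections, species,
                                  stratum = c("c10", "c25"), n = 60, seed,
                                  recordings = NULL, pad_s = 1) {
  stratum <- match.arg(stratum)
  pool <- filter_by_confidence(detections, .stratum_thresholds[[stratum]])
  pool <- pool[pool$scientific_name == species, , drop = FALSE]
  if (nrow(pool) == 0) {
    abort(sprintf("no eligible detections of %s in stratum %s", species, stratum))
  }
  if (nrow(pool) <= n) {
    if (nrow(pool) < n) {
      warn(sprintf("only %d eligible detections of %s (requested %d); returning all",
                   nrow(pool), species, n))
    }
    picked <- pool
  } else {
    idx <- with_seed(seed, sample.int(nrow(pool), n))
    picked <- pool[idx, , drop = FALSE]
  }
  picked$clip_start_s <- pmax(picked$segment_start_s - pad_s, 0)
  picked$clip_end_s <- picked$segment_end_s + pad_s
  if (!is.null(recordings)) {
    dur <- setNames(recordings$duration_s, recordings$recording_id)
    picked$clip_end_s <- pmin(picked$clip_end_s,
                              unname(dur[picked$recording_id]))
  }
  structure(
    list(species = species, stratum = stratum, seed = seed, n_requested = n,
         detections = picked),
    class = "validation_sample"
  )
}

#' Compute precision from annotated detections
#'
#' Precision is the fraction of validated detections confirmed correct,
#' TP / (TP + FP). Values are returned at full precision; round to 3
#' decimals for reporting.
#'
#' @param annotations tibble with a `label` column of
#'   `"true_positive"`/`"false_positive"` values, one row per reviewed
#'   detection.
#' @return Precision in `[0, 1]`.
#' @export
compute_precision <- function(annotations) {
  check_labels(annotations)
  if (nrow(annotations) == 0) abort("precision is undefined for zero annotations")
  mean(annotations$label == "true_positive")
}

#' Maximum confidence among false-positive detections
#'
#' The highest classifier confidence observed on any detection annotated as
#' a false positive — an empirical upper bound used as a conservative
#' species-specific threshold. Annotations from both validation strata are
#' pooled by passing them together.
#'
#' @param annotations tibble with `label` and `confidence` columns.
#' @return The maximum false-positive confidence, or `NA` if no false
#'   positives were observed.
#' @export
compute_max_fp_confidence <- function(annotations) {
  check_labels(annotations)
  fp <- annotations$confidence[annotations$label == "false_positive"]
  if (length(fp) == 0) NA_real_ else max(fp)
}

check_labels <- function(annotations, call = rlang::caller_env()) {
  bad <- setdiff(unique(annotations$label),
                 c("true_positive", "false_positive"))
  if (length(bad) > 0) {
    abort(sprintf("unknown annotation label(s): %s",
                  paste(bad, collapse = ", ")), call = call)
  }
}

#' Sample fixed-length acoustic segments for recall estimation
#'
#' Draws `n` segments of `length_s` seconds uniformly over the pooled
#' eligible recording time (each segment lies fully inside one recording),
#' reproducibly under `seed`.
#'
#' @param recordings recording-file tibble (`recording_id`, `site_id`,
#'   `start`, `duration_s`).
#' @param n number of segments (50 by default).
#' @param length_s segment length in seconds (120 by default).
#' @param seed integer seed recorded on the result.
#' @return A tibble with `segment_id`, `recording_id`, `site_id`,
#'   `start_s`, `end_s`; the seed is stored in attribute `"seed"`.
#' @export
sample_segments <- function(recordings, n = 50, length_s = 120, seed) {
  eligible <- recordings[recordings$duration_s >= length_s, , drop = FALSE]
  if (nrow(eligible) == 0) abort("no recording can hold a segment of that length")
  slack <- eligible$duration_s - length_s
  starts <- with_seed(seed, {
    if (sum(slack) == 0) {
      idx <- sample.int(nrow(eligible), n, replace = TRUE)
      cbind(idx, 0)
    } else {
      idx <- sample.int(nrow(eligible), n, replace = TRUE, prob = slack)
      cbind(idx, runif(n) * slack[idx])
    }
  })
  out <- tibble(
    segment_id = sprintf("seg%03d", seq_len(n)),
    recording_id = eligible$recording_id[starts[, 1]],
    site_id = eligible$site_id[starts[, 1]],
    start_s = unname(starts[, 2]),
    end_s = unname(starts[, 2]) + length_s
  )
  attr(out, "seed") <- seed
  out
}

#' Species the classifier reported within each segment
#'
#' A detection belongs to a segment when its 3-s window overlaps the segment
#' by any amount and its confidence is at least `min_confidence`.
#'
#' @param segments segment tibble from [sample_segments()].
#' @param detections a detection tibble.
#' @param min_confidence retention threshold (0.10, the default run setting).
#' @return `segments` with a list-column `classifier_species`.
#' @export
segment_classifier_species <- function(segments, detections,
                                       min_confidence = 0.10) {
  det <- filter_by_confidence(detections, min_confidence)
  segments$classifier_species <- pmap(
    list(segments$recording_id, segments$start_s, segments$end_s),
    function(rec, s, e) {
      hit <- det$recording_id == rec & det$segment_start_s < e &
        det$segment_end_s > s
      sort(unique(det$scientific_name[hit]))
    }
  )
  segments
}

#' Segment-level recall for one species
#'
#' True positives are segments with at least one manual detection and at
#' least one classifier detection of the species; false negatives are
#' segments with a manual detection but no classifier detection. Recall is
#' TP / (TP + FN), i.e. the fraction of manually-confirmed segments the
#' classifier also flagged.
#'
#' @param segment_annotations tibble with list-columns `manual_species` and
#'   `classifier_species`, one row per reviewed segment.
#' @param species scientific name.
#' @param missing_if_undetected if `TRUE`, a species with manual detections
#'   but zero classifier detections across all segments yields `NA` instead
#'   of 0 (the stricter published exclusion); the default follows the
#'   TP/(TP+FN) definition and yields 0.
#' @return Recall in `[0, 1]`, or `NA` when the species was never manually
#'   detected (zero denominator).
#' @export
compute_recall <- function(segment_annotations, species,
                           missing_if_undetected = FALSE) {
  if (nrow(segment_annotations) == 0) abort("no segment annotations")
  manual <- map_dbl(segment_annotations$manual_species,
                    ~ as.numeric(species %in% .x))
  machine <- map_dbl(segment_annotations$classifier_species,
                     ~ as.numeric(species %in% .x))
  if (sum(manual) == 0) return(NA_real_)
  if (missing_if_undetected && sum(machine) == 0) return(NA_real_)
  sum(manual * machine) / sum(manual)
}

#' F-score: harmonic mean of precision and recall
#'
#' `2PR / (P + R)`, conventionally 0 when both are 0; a missing recall
#' propagates to a missing F. The published convention pairs recall with the
#' 0.10-stratum precision.
#'
#' @param precision,recall numeric vectors in `[0, 1]` (recycled).
#' @return The F-score(s) at full precision.
#' @export
compute_f_score <- function(precision, recall) {
  bad <- !is.na(precision) & (precision < 0 | precision > 1)
  bad <- bad | (!is.na(recall) & (recall < 0 | recall > 1))
  if (any(bad)) abort("precision and recall must lie in [0, 1]")
  dplyr::case_when(
    is.na(recall) | is.na(precision) ~ NA_real_,
    precision == 0 & recall == 0 ~ 0,
    TRUE ~ 2 * precision * recall / (precision + recall)
  )
}

#' Assign a species-specific confidence (SSC) threshold
#'
#' Decision rule calibrated on the two validation precisions: keep the
#' default 0.10 threshold when the default-stratum precision is already at
#' least 0.85; otherwise fall back to 0.25 when precision at that stratum
#' reaches 0.85; otherwise use the species' maximum false-positive
#' confidence as an empirical cutoff.
#'
#' @param precision_c10,precision_c25 precisions at the 0.10 and 0.25
#'   strata, in `[0, 1]` (vectors recycled).
#' @param max_fp_confidence maximum false-positive confidence; required only
#'   when both precisions fall below 0.85.
#' @return The SSC threshold(s).
#' @export
assign_ssc <- function(precision_c10, precision_c25, max_fp_confidence = NA) {
  n <- max(length(precision_c10), length(precision_c25),
           length(max_fp_confidence))
  p10 <- rep_len(precision_c10, n)
  p25 <- rep_len(precision_c25, n)
  mfp <- rep_len(max_fp_confidence, n)
  needs_mfp <- p10 < 0.85 & p25 < 0.85
  if (any(needs_mfp & is.na(mfp))) {
    abort("both precisions below 0.85 but max_fp_confidence is missing")
  }
  if_else(p10 >= 0.85, 0.10, if_else(p25 >= 0.85, 0.25, mfp))
}

#' Summarize per-species performance
#'
#' Builds the per-species performance table (3-decimal reporting convention)
#' and column summaries: mean, range, and count of non-missing entries per
#' metric, plus the two headline exceedance counts (species with
#' default-stratum precision above 0.85, and with maximum false-positive
#' confidence below 0.50).
#'
#' @param perf tibble with columns `scientific_name`, `precision_c10`,
#'   `precision_c25`, `max_fp_confidence`, `recall`, and optionally a
#'   precomputed `f_score` (recomputed from `precision_c10` and `recall`
#'   when absent) and `ssc` (recomputed via [assign_ssc()] when absent).
#' @return A list with `table` (rounded per-species tibble),
#'   `column_summary` (metric, n, mean, min, max over non-missing entries),
#'   `n_precision_c10_gt_0.85`, and `n_max_fp_lt_0.50`.
#' @export
summarize_performance <- function(perf) {
  perf <- as_tibble(perf)
  if (!"f_score" %in% names(perf)) {
    perf$f_score <- compute_f_score(perf$precision_c10, perf$recall)
  }
  if (!"ssc" %in% names(perf)) {
    perf$ssc <- assign_ssc(perf$precision_c10, perf$precision_c25,
                           perf$max_fp_confidence)
  }
  metrics <- c("precision_c10", "precision_c25", "max_fp_confidence",
               "recall", "f_score", "ssc")
  tab <- mutate(perf, across(all_of(metrics), ~ round(.x, 3)))
  col_summary <- purrr::map(metrics, function(m) {
    v <- perf[[m]][!is.na(perf[[m]])]
    tibble(metric = m, n = length(v), mean = mean(v),
           min = min(v), max = max(v))
  }) |> list_rbind()
  list(
    table = tab,
    column_summary = col_summary,
    `n_precision_c10_gt_0.85` = sum(perf$precision_c10 > 0.85, na.rm = TRUE),
    `n_max_fp_lt_0.50` = sum(perf$max_fp_confidence < 0.50, na.rm = TRUE)
  )
}
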