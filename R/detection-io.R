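## Reading, writing, and filtering classifier detection tables.
##
## Detections are fixed-length (3-s) classifier prediction segments with a
## species label and a confidence score in [0, 1]. Two tab-delimited dialects
## are accepted: the per-recording result table emitted by the classifier
## (columns "Start (s)", "End (s)", "Scientific name", "Common name",
## "Confidence") and a combined long table that additionally carries
## site_id, recording_id, and recording_start (ISO 8601). The combined
## form is the package's canonical interchange file.

# required measurement columns of the classifier dialect
.birdnet_cols <- c("Start (s)", "End (s)", "Scientific name", "Common name",
                   "Confidence")
.combined_cols <- c("site_id", "recording_id", "recording_start")

#' Build a detection tibble
#'
#' Constructs the canonical detection table used throughout the package and
#' validates its invariants. All timestamps are naive local civil time stored
#' as UTC-labelled `POSIXct`; no timezone conversion is ever applied.
#'
#' @param site_id,recording_id character identifiers (recycled to length).
#' @param recording_start `POSIXct` start of the source recording.
#' @param segment_start_s,segment_end_s numeric offsets in seconds from
#'   `recording_start`; segments are `window_s` long.
#' @param scientific_name,common_name species labels; the scientific name is
#'   the species identity key, the common name is display-only.
#' @param confidence classifier confidence in `[0, 1]`.
#' @param window_s expected prediction window length in seconds (default 3).
#'
#' @return A tibble with one row per detection and an absolute `timestamp`
#'   column (`recording_start + segment_start_s`).
#' @export
detection_tbl <- function(site_id, recording_id, recording_start,
                          segment_start_s, segment_end_s,
                          scientific_name, common_name, confidence,
                          window_s = 3) {
  out <- tibble(
    site_id = as.character(site_id),
    recording_id = as.character(recording_id),
    recording_start = recording_start,
    segment_start_s = as.numeric(segment_start_s),
    segment_end_s = as.numeric(segment_end_s),
    scientific_name = as.character(scientific_name),
    common_name = as.character(common_name),
    confidence = as.numeric(confidence)
  )
  validate_detections(out, window_s = window_s)
  mutate(out, timestamp = .data$recording_start + .data$segment_start_s)
}

validate_detections <- function(x, window_s = NULL, call = rlang::caller_env()) {
  bad_conf <- which(!is.finite(x$confidence) | x$confidence < 0 | x$confidence > 1)
  if (length(bad_conf) > 0) {
    abort(sprintf("confidence outside [0, 1] at row(s) %s",
                  paste(utils::head(bad_conf, 5), collapse = ", ")),
          call = call)
  }
  if (any(x$segment_start_s < 0)) {
    abort("segment_start_s must be >= 0", call = call)
  }
  if (!is.null(window_s)) {
    len <- x$segment_end_s - x$segment_start_s
    if (any(abs(len - window_s) > 1e-9)) {
      abort(sprintf("segment length differs from the %g-s prediction window",
                    window_s), call = call)
    }
  }
  invisible(x)
}

#' Read a classifier detection table
#'
#' Reads either classifier dialect. Per-recording tables need `site_id` and
#' `recording_start` supplied (and optionally `recording_id`, which defaults
#' to the file name); the combined dialect carries them as columns. Rows are
#' preserved in file order and absolute timestamps are resolved.
#'
#' @param path file path to a tab-delimited detection table.
#' @param site_id,recording_id,recording_start provenance for the
#'   per-recording dialect; ignored when the file is a combined table.
#' @param on_error `"fail"` (default) aborts on the first malformed row;
#'   `"skip"` drops malformed rows with a warning naming how many were lost.
#'   Silent row loss biases richness, so skipping is opt-in.
#'
#' @return A detection tibble (see [detection_tbl()]).
#' @export
read_detection_table <- function(path, site_id = NULL, recording_id = NULL,
                                 recording_start = NULL,
                                 on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(.birdnet_cols, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("detection table %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  combined <- all(.combined_cols %in% names(raw))
  if (!combined) {
    if (is.null(site_id) || is.null(recording_start)) {
      abort("per-recording tables need `site_id` and `recording_start`")
    }
    recording_id <- recording_id %||% basename(path)
  }

  conf <- suppressWarnings(as.numeric(raw$Confidence))
  seg_start <- suppressWarnings(as.numeric(raw$`Start (s)`))
  seg_end <- suppressWarnings(as.numeric(raw$`End (s)`))
  bad <- !is.finite(conf) | conf < 0 | conf > 1 | !is.finite(seg_start) |
    !is.finite(seg_end)
  if (any(bad)) {
    if (on_error == "fail") {
      abort(sprintf("malformed or out-of-range values at row(s) %s of %s",
                    paste(utils::head(which(bad), 5), collapse = ", "), path))
    }
    warn(sprintf("skipped %d malformed row(s) while reading %s",
                 sum(bad), path))
  }
  keep <- !bad

  if (combined) {
    rec_start <- parse_naive_datetime(raw$recording_start)
    site <- raw$site_id
    rec <- raw$recording_id
  } else {
    rec_start <- rep(as_naive_datetime(recording_start), nrow(raw))
    site <- rep(as.character(site_id), nrow(raw))
    rec <- rep(as.character(recording_id), nrow(raw))
  }

  detection_tbl(
    site_id = site[keep], recording_id = rec[keep],
    recording_start = rec_start[keep],
    segment_start_s = seg_start[keep], segment_end_s = seg_end[keep],
    scientific_name = raw$`Scientific name`[keep],
    common_name = raw$`Common name`[keep],
    confidence = conf[keep],
    window_s = NULL
  )
}

#' Write a detection table in the combined dialect
#'
#' Emits the tab-delimited combined dialect that [read_detection_table()]
#' accepts; reading a written file recovers all detection fields exactly.
#' Confidences are printed at full double precision.
#'
#' @param detections a detection tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(detections, path) {
  out <- tibble(
    site_id = detections$site_id,
    recording_id = detections$recording_id,
    recording_start = format_naive_datetime(detections$recording_start),
    `Start (s)` = detections$segment_start_s,
    `End (s)` = detections$segment_end_s,
    `Scientific name` = detections$scientific_name,
    `Common name` = detections$common_name,
    Confidence = detections$confidence
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter detections by a static confidence threshold
#'
#' Retains detections with `confidence >= threshold` (inclusive, so the
#' classifier's own minimum-confidence run setting of 0.10 retains
#' detections reported at exactly 0.10). Row order is preserved.
#'
#' @param detections a detection tibble.
#' @param threshold a single confidence threshold in `[0, 1]`.
#' @return The retained detections.
#' @export
filter_by_confidence <- function(detections, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single value in [0, 1]")
  }
  detections[detections$confidence >= threshold, , drop = FALSE]
}

#' Filter detections by species-specific confidence thresholds
#'
#' Each detection is retained iff its confidence is at least its species'
#' threshold. Equivalent to applying [filter_by_confidence()] per species.
#'
#' @param detections a detection tibble.
#' @param ssc_map species-specific thresholds: a named numeric vector keyed
#'   by scientific name, or a data frame with columns `scientific_name` and
#'   `ssc`.
#' @param default threshold applied to species absent from `ssc_map`;
#'   `NULL` (strict, the default) makes an absent species an error.
#' @return The retained detections, order preserved.
#' @export
filter_by_ssc <- function(detections, ssc_map, default = NULL) {
  map <- as_ssc_map(ssc_map)
  thr <- unname(map[detections$scientific_name])
  if (anyNA(thr)) {
    missing <- unique(detections$scientific_name[is.na(thr)])
    if (is.null(default)) {
      abort(sprintf("no species-specific threshold for: %s",
                    paste(missing, collapse = ", ")))
    }
    thr[is.na(thr)] <- default
  }
  detections[detections$confidence >= thr, , drop = FALSE]
}

as_ssc_map <- function(ssc_map) {
  if (is.data.frame(ssc_map)) {
    ssc_map <- setNames(ssc_map$ssc, ssc_map$scientific_name)
  }
  if (!is.numeric(ssc_map) || is.null(names(ssc_map))) {
    abort("`ssc_map` must be a named numeric vector or a data frame with `scientific_name` and `ssc`")
  }
  if (any(ssc_map < 0 | ssc_map > 1)) abort("thresholds must lie in [0, 1]")
  ssc_map
}

#' Canonicalize species names against an alias catalog
#'
#' Joins free-form species names (case/diacritic variants, common or
#' scientific) to canonical (scientific, common) pairs so point-count
#' records and classifier output share one species identity key. Canonical
#' names resolve to themselves; unknown names are flagged, never silently
#' dropped.
#'
#' @param name character vector of species names to resolve.
#' @param catalog data frame with columns `alias`, `scientific`, `common`.
#'   The catalog's own scientific and common names are implicitly aliases.
#' @param strict if `TRUE` (default) an unresolvable name is an error;
#'   otherwise it yields `NA` names with `matched = FALSE`.
#' @return A tibble with columns `input`, `scientific_name`, `common_name`,
#'   `matched`.
#' @export
canonicalize_species <- function(name, catalog, strict = TRUE) {
  need <- c("alias", "scientific", "common")
  if (!all(need %in% names(catalog))) {
    abort("`catalog` needs columns alias, scientific, common")
  }
  lut <- bind_rows(
    tibble(key = catalog$alias, scientific = catalog$scientific,
           common = catalog$common),
    tibble(key = catalog$scientific, scientific = catalog$scientific,
           common = catalog$common),
    tibble(key = catalog$common, scientific = catalog$scientific,
           common = catalog$common)
  )
  lut$key <- normalize_name(lut$key)
  lut <- distinct(lut, .data$key, .keep_all = TRUE)
  idx <- match(normalize_name(name), lut$key)
  if (strict && anyNA(idx)) {
    abort(sprintf("unknown species name(s): %s",
                  paste(unique(name[is.na(idx)]), collapse = ", ")))
  }
  tibble(
    input = name,
    scientific_name = lut$scientific[idx],
    common_name = lut$common[idx],
    matched = !is.na(idx)
  )
}

normalize_name <- function(x) {
  x <- trimws(tolower(x))
  # strip diacritics; keep original where transliteration fails
  y <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  ifelse(is.na(y), x, y)
}

## ---- schedule and point-count CSV I/O -------------------------------------

#' Read a recording schedule
#'
#' @param path CSV with columns `recording_id`, `site_id`, `start`
#'   (ISO 8601), `duration_s`.
#' @return A tibble of recording files; recordings of one site must not
#'   overlap in time.
#' @export
read_recording_schedule <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    recording_id = "c", site_id = "c", start = "c", duration_s = "d"
  ), progress = FALSE)
  x$start <- parse_naive_datetime(x$start)
  validate_schedule(x)
}

#' Write a recording schedule
#' @param schedule a recording-file tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_schedule <- function(schedule, path) {
  out <- mutate(schedule, start = format_naive_datetime(.data$start))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_schedule <- function(x, call = rlang::caller_env()) {
  if (any(x$duration_s <= 0)) abort("recording durations must be > 0", call = call)
  overlap <- x |>
    arrange(.data$site_id, .data$start) |>
    group_by(.data$site_id) |>
    summarise(bad = any(diff_overlaps(.data$start, .data$duration_s)),
              .groups = "drop")
  if (any(overlap$bad)) {
    abort(sprintf("overlapping recordings at site(s): %s",
                  paste(overlap$site_id[overlap$bad], collapse = ", ")),
          call = call)
  }
  x
}

diff_overlaps <- function(start, duration_s) {
  if (length(start) < 2) return(FALSE)
  end <- start + duration_s
  utils::head(end, -1) > utils::tail(start, -1) + 1e-9
}

#' Read point-count observations
#'
#' @param path CSV with columns `site_id`, `visit_start` (ISO 8601),
#'   `species`, `behavior` (singing/calling/observed) and optionally
#'   `distance_m`, `sex`.
#' @return A tibble of observations.
#' @export
read_point_counts <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("site_id", "visit_start", "species", "behavior")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("point-count file missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x$visit_start <- parse_naive_datetime(x$visit_start)
  if ("distance_m" %in% names(x)) x$distance_m <- as.numeric(x$distance_m)
  x
}

## ---- naive civil-time helpers ---------------------------------------------

# All datetimes in this package are naive local civil time. They are stored
# as POSIXct labelled UTC purely so arithmetic works; the recorder's actual
# UTC offset is metadata and is never applied.
as_naive_datetime <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  parse_naive_datetime(as.character(x))
}

parse_naive_datetime <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) abort("unparseable ISO 8601 datetime(s)")
  out
}

format_naive_datetime <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}
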