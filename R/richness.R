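## Species richness from filtered detections and from point counts, at the
## short (within 1 h of a survey) and long (whole season) temporal scales,
## plus species accumulation curves and the top-N confirmation review.

#' Apply a static or species-specific threshold
#'
#' Dispatches to [filter_by_confidence()] for a numeric threshold or
#' [filter_by_ssc()] for the label `"ssc"`.
#'
#' @param detections a detection tibble.
#' @param threshold a numeric confidence in `[0, 1]`, or `"ssc"`.
#' @param ssc_map species-specific thresholds, required when
#'   `threshold == "ssc"`.
#' @return The retained detections.
#' @export
apply_threshold <- function(detections, threshold, ssc_map = NULL) {
  if (is.character(threshold) && identical(tolower(threshold), "ssc")) {
    if (is.null(ssc_map)) abort("threshold \"ssc\" needs an `ssc_map`")
    filter_by_ssc(detections, ssc_map)
  } else {
    filter_by_confidence(detections, threshold)
  }
}

threshold_label <- function(threshold) {
  if (is.character(threshold)) "SSC" else format(threshold)
}

#' Pair point-count visits with recordings made within a time window
#'
#' A visit is paired with every same-site recording whose interval
#' intersects the visit interval widened by `window_min` minutes on each
#' side. Visits with no such recording are returned as exclusions (and are
#' dropped from paired short-duration comparisons).
#'
#' @param visits tibble with `site_id`, `visit_start`, and optionally
#'   `duration_min` (default 10).
#' @param recordings recording-file tibble.
#' @param window_min half-width of the pairing window in minutes (60).
#' @return A list with `pairs` (visit fields + `recording_id`) and
#'   `exclusions` (unpaired visit rows).
#' @export
pair_surveys_with_recordings <- function(visits, recordings, window_min = 60) {
  visits <- as_tibble(visits)
  if (!"duration_min" %in% names(visits)) visits$duration_min <- 10
  if (!"visit_id" %in% names(visits)) {
    visits$visit_id <- paste(visits$site_id,
                             format_naive_datetime(visits$visit_start),
                             sep = "/")
  }
  win_lo <- visits$visit_start - window_min * 60
  win_hi <- visits$visit_start + (visits$duration_min + window_min) * 60
  pairs <- purrr::map(seq_len(nrow(visits)), function(i) {
    hit <- recordings$site_id == visits$site_id[i] &
      recordings$start < win_hi[i] &
      recordings$start + recordings$duration_s > win_lo[i]
    if (!any(hit)) return(NULL)
    bind_cols(visits[rep(i, sum(hit)), ],
              tibble(recording_id = recordings$recording_id[hit]))
  }) |> list_rbind()
  paired_ids <- if (nrow(pairs) > 0) unique(pairs$visit_id) else character()
  list(
    pairs = pairs,
    exclusions = visits[!visits$visit_id %in% paired_ids, , drop = FALSE]
  )
}

richness_record <- function(site_id, method, threshold_label, period,
                            visit_id, species_set) {
  tibble(
    site_id = site_id, method = method, threshold_label = threshold_label,
    period = period, visit_id = visit_id,
    richness = length(species_set), species_set = list(sort(species_set))
  )
}

#' Short-duration ARU richness per paired visit
#'
#' For each paired visit, the number of unique (focal) species among the
#' threshold-filtered detections on the recordings paired with that visit.
#'
#' @param pairs the `pairs` element of [pair_surveys_with_recordings()].
#' @param detections a detection tibble.
#' @param threshold static numeric threshold or `"ssc"`.
#' @param focal optional character vector restricting species scope.
#' @param ssc_map species-specific thresholds when `threshold == "ssc"`.
#' @return A tibble of richness records, one per paired visit.
#' @export
short_duration_richness <- function(pairs, detections, threshold,
                                    focal = NULL, ssc_map = NULL) {
  det <- apply_threshold(detections, threshold, ssc_map)
  if (!is.null(focal)) det <- det[det$scientific_name %in% focal, , drop = FALSE]
  visits <- distinct(pairs, .data$site_id, .data$visit_id)
  purrr::map(seq_len(nrow(visits)), function(i) {
    recs <- pairs$recording_id[pairs$visit_id == visits$visit_id[i]]
    sp <- unique(det$scientific_name[det$recording_id %in% recs])
    richness_record(visits$site_id[i], "aru", threshold_label(threshold),
                    "short", visits$visit_id[i], sp)
  }) |> list_rbind()
}

#' Long-duration ARU richness per site
#'
#' Unique (focal) species among threshold-filtered detections timestamped
#' within the period (inclusive calendar-date bounds), per site.
#'
#' @inheritParams short_duration_richness
#' @param period length-2 `Date` (or coercible) vector, inclusive bounds.
#' @param sites optional site list so sites with zero retained detections
#'   still yield a record; defaults to sites present in `detections`.
#' @return A tibble of richness records, one per site.
#' @export
long_duration_richness <- function(detections, period, threshold,
                                   focal = NULL, ssc_map = NULL,
                                   sites = NULL) {
  period <- as.Date(period)
  if (length(period) != 2 || anyNA(period) || period[1] > period[2]) {
    abort("`period` must be two ordered dates")
  }
  sites <- sites %||% sort(unique(detections$site_id))
  det <- apply_threshold(detections, threshold, ssc_map)
  if (!is.null(focal)) det <- det[det$scientific_name %in% focal, , drop = FALSE]
  day <- as.Date(det$timestamp)
  det <- det[day >= period[1] & day <= period[2], , drop = FALSE]
  purrr::map(sites, function(s) {
    sp <- unique(det$scientific_name[det$site_id == s])
    richness_record(s, "aru", threshold_label(threshold), "long", NA_character_, sp)
  }) |> list_rbind()
}

#' Point-count richness per visit or per site
#'
#' Unique species seen or heard, per visit or pooled over a site's visits
#' within the period.
#'
#' @param observations tibble with `site_id`, `visit_start`, `species`
#'   (canonical scientific names).
#' @param scope `"focal"` (restrict to `focal`) or `"all"`.
#' @param focal character vector of focal scientific names.
#' @param period optional length-2 date bounds (inclusive).
#' @param per `"visit"` or `"site"` grouping unit.
#' @param visits optional visit tibble so surveyed units with zero
#'   observations still yield a record.
#' @return A tibble of richness records.
#' @export
point_count_richness <- function(observations, scope = c("focal", "all"),
                                 focal = NULL, period = NULL,
                                 per = c("site", "visit"), visits = NULL) {
  scope <- match.arg(scope)
  per <- match.arg(per)
  obs <- as_tibble(observations)
  if (!is.null(period)) {
    period <- as.Date(period)
    day <- as.Date(obs$visit_start)
    obs <- obs[day >= period[1] & day <= period[2], , drop = FALSE]
  }
  if (scope == "focal") {
    if (is.null(focal)) abort("scope \"focal\" needs a `focal` species list")
    obs <- obs[obs$species %in% focal, , drop = FALSE]
  }
  obs$visit_id <- paste(obs$site_id, format_naive_datetime(obs$visit_start),
                        sep = "/")
  if (is.null(visits)) {
    units <- distinct(obs, .data$site_id, .data$visit_id)
  } else {
    units <- as_tibble(visits)
    if (!"visit_id" %in% names(units)) {
      units$visit_id <- paste(units$site_id,
                              format_naive_datetime(units$visit_start),
                              sep = "/")
    }
    units <- distinct(units, .data$site_id, .data$visit_id)
  }
  if (per == "site") {
    units <- distinct(units, .data$site_id)
    purrr::map(units$site_id, function(s) {
      sp <- unique(obs$species[obs$site_id == s])
      richness_record(s, "point_count", NA_character_, "long", NA_character_, sp)
    }) |> list_rbind()
  } else {
    purrr::map(seq_len(nrow(units)), function(i) {
      sp <- unique(obs$species[obs$visit_id == units$visit_id[i]])
      richness_record(units$site_id[i], "point_count", NA_character_, "short",
                      units$visit_id[i], sp)
    }) |> list_rbind()
  }
}

#' Species accumulation curve
#'
#' Cumulative count of unique species whose first qualifying observation
#' falls on or before each calendar day of the period, pooled across sites.
#' Day 1 is the period start date.
#'
#' @param events tibble of dated species observations with columns `species`
#'   and either `date` or `timestamp` (any method's events can be passed).
#' @param period length-2 inclusive date bounds.
#' @param pool optional species pool restricting which species accumulate.
#' @return A tibble with `day_index`, `date`, `cumulative_richness`,
#'   non-decreasing in `day_index`.
#' @export
accumulation_curve <- function(events, period, pool = NULL) {
  period <- as.Date(period)
  ev <- as_tibble(events)
  ev$date <- if ("date" %in% names(ev)) as.Date(ev$date) else as.Date(ev$timestamp)
  outside <- ev$date < period[1] | ev$date > period[2]
  if (any(outside)) {
    inform(sprintf("accumulation_curve: excluded %d event(s) outside the period",
                   sum(outside)))
    ev <- ev[!outside, , drop = FALSE]
  }
  if (!is.null(pool)) ev <- ev[ev$species %in% pool, , drop = FALSE]
  days <- seq(period[1], period[2], by = "day")
  if (nrow(ev) == 0) {
    first_day <- tibble(species = character(), first = as.Date(character()))
  } else {
    first_day <- ev |>
      group_by(.data$species) |>
      summarise(first = min(.data$date), .groups = "drop")
  }
  tibble(
    day_index = seq_along(days),
    date = days,
    cumulative_richness = map_int(days, ~ sum(first_day$first <= .x))
  )
}

#' Top-confidence detections per species for confirmation review
#'
#' For each detected species, the `n` highest-confidence detections, ranked
#' by confidence descending with ties broken by earlier timestamp then
#' lexicographic recording id (deterministic for audit).
#'
#' @param detections a detection tibble.
#' @param n detections to review per species (10 by default).
#' @return The selected detections with a per-species `rank` column.
#' @export
top_confidence_review <- function(detections, n = 10) {
  detections |>
    arrange(.data$scientific_name, desc(.data$confidence), .data$timestamp,
            .data$recording_id) |>
    group_by(.data$scientific_name) |>
    mutate(rank = row_number()) |>
    filter(.data$rank <= n) |>
    ungroup()
}

#' Confirmed total richness from a top-confidence review
#'
#' A species counts toward richness iff at least one of its reviewed
#' detections was confirmed.
#'
#' @param reviews output of [top_confidence_review()].
#' @param confirmed logical vector aligned with `reviews` rows (review
#'   labels from a human or a truth oracle); defaults to a `confirmed`
#'   column on `reviews`.
#' @return The number of confirmed species.
#' @export
confirmed_total_richness <- function(reviews, confirmed = reviews$confirmed) {
  if (is.null(confirmed)) abort("review labels are required")
  length(unique(reviews$scientific_name[confirmed]))
}
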