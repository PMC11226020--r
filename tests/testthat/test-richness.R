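test_that("visits pair with recordings intersecting the 1-h window", {
  fx <- pairing_fixture()
  out <- pair_surveys_with_recordings(fx$visits, fx$recordings)
  expect_identical(nrow(out$pairs), 24L)
  expect_identical(nrow(out$exclusions), 6L)
  expect_true(all(out$exclusions$site_id %in% sprintf("site%02d", 1:6)))

  # a recording overlapping the visit itself is paired
  v <- tibble::tibble(site_id = "s1",
                      visit_start = as.POSIXct("2022-06-01 08:00:00",
                                               tz = "UTC"))
  r_over <- tibble::tibble(recording_id = "a", site_id = "s1",
                           start = as.POSIXct("2022-06-01 08:05:00",
                                              tz = "UTC"),
                           duration_s = 600)
  expect_identical(nrow(pair_surveys_with_recordings(v, r_over)$pairs), 1L)

  # a recording ending 2 h before the visit is excluded
  r_old <- dplyr::mutate(r_over,
                         start = as.POSIXct("2022-06-01 04:00:00", tz = "UTC"),
                         duration_s = 7200)
  out2 <- pair_surveys_with_recordings(v, r_old)
  expect_identical(nrow(out2$pairs), 0L)
  expect_identical(nrow(out2$exclusions), 1L)
})

test_that("short-duration richness is the unique-species union over paired recordings", {
  season <- simulate_season(small_config(), seed = 31)
  pairing <- pair_surveys_with_recordings(season$visits, season$schedule)
  rec <- short_duration_richness(pairing$pairs, season$detections,
                                 threshold = 0.1)
  expect_identical(sort(unique(rec$visit_id)),
                   sort(unique(pairing$pairs$visit_id)))
  # brute-force oracle per visit
  for (i in seq_len(nrow(rec))) {
    recs <- pairing$pairs$recording_id[pairing$pairs$visit_id == rec$visit_id[i]]
    det <- season$detections
    sp <- unique(det$scientific_name[det$recording_id %in% recs &
                                       det$confidence >= 0.1])
    expect_identical(rec$richness[i], length(sp))
  }
  # same species detected many times counts once
  dup <- toy_detections(rep(0.9, 50))
  pairs <- tibble::tibble(site_id = "site01", visit_id = "v1",
                          recording_id = "rec01")
  expect_identical(short_duration_richness(pairs, dup, 0.1)$richness, 1L)
  # no detections on the paired recordings: richness 0
  expect_identical(short_duration_richness(
    dplyr::mutate(pairs, recording_id = "other"), dup, 0.1)$richness, 0L)
})

test_that("long-duration richness matches brute force and shrinks with threshold", {
  season <- simulate_season(small_config(n_sites = 5), seed = 32)
  period <- as.Date(c("2022-05-19", "2022-05-23"))
  for (thr in c(0.1, 0.9)) {
    rec <- long_duration_richness(season$detections, period, thr)
    for (i in seq_len(nrow(rec))) {
      det <- season$detections
      sp <- unique(det$scientific_name[det$site_id == rec$site_id[i] &
                                         det$confidence >= thr])
      expect_identical(rec$richness[i], length(sp))
    }
  }
  r01 <- long_duration_richness(season$detections, period, 0.1)
  r09 <- long_duration_richness(season$detections, period, 0.9)
  expect_true(all(r09$richness <= r01$richness))
  # long-duration >= any same-site short-duration richness at the threshold
  pairing <- pair_surveys_with_recordings(season$visits, season$schedule)
  short <- short_duration_richness(pairing$pairs, season$detections, 0.1)
  per_site_max <- tapply(short$richness, short$site_id, max)
  expect_true(all(r01$richness[match(names(per_site_max), r01$site_id)] >=
                    per_site_max))

  none <- long_duration_richness(season$detections,
                                 as.Date(c("2023-01-01", "2023-01-02")), 0.1)
  expect_true(all(none$richness == 0L))
  expect_error(long_duration_richness(season$detections,
                                      as.Date(c("2022-06-01", "2022-05-01")),
                                      0.1),
               "ordered")
})

test_that("point-count richness pools unique species per grouping unit", {
  obs <- tibble::tibble(
    site_id = "s1",
    visit_start = as.POSIXct("2022-05-20 07:00:00", tz = "UTC") +
      c(0, 86400, 2 * 86400),
    species = "Sturnella neglecta", behavior = "singing")
  expect_identical(point_count_richness(obs, scope = "all",
                                        per = "site")$richness, 1L)

  obs$species <- c("sp1", "sp2", "sp3")
  per_visit <- point_count_richness(obs, scope = "all", per = "visit")
  per_site <- point_count_richness(obs, scope = "all", per = "site")
  expect_identical(per_site$richness, sum(per_visit$richness))

  season <- simulate_season(small_config(), seed = 33)
  rec <- point_count_richness(season$observations, scope = "all", per = "site",
                              visits = season$visits)
  for (i in seq_len(nrow(rec))) {
    sp <- unique(season$observations$species[
      season$observations$site_id == rec$site_id[i]])
    expect_identical(rec$richness[i], length(sp))
  }
})

test_that("accumulation curves step at first observations and end at total richness", {
  period <- as.Date(c("2022-06-01", "2022-06-10"))
  events <- tibble::tibble(
    species = c("spA", "spB", "spB", "spC", "spD"),
    date = period[1] + c(0, 2, 4, 4, 8))
  curve <- accumulation_curve(events, period)
  expect_identical(curve$cumulative_richness,
                   c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 4L))

  one <- accumulation_curve(tibble::tibble(species = "spA", date = period[1]),
                            period)
  expect_true(all(one$cumulative_richness == 1L))

  season <- simulate_season(small_config(), seed = 34)
  det <- filter_by_confidence(season$detections, 0.25)
  curve <- accumulation_curve(
    tibble::tibble(species = det$scientific_name, timestamp = det$timestamp),
    as.Date(c("2022-05-19", "2022-05-23")))
  expect_true(all(diff(curve$cumulative_richness) >= 0))
  expect_identical(curve$cumulative_richness[nrow(curve)],
                   length(unique(det$scientific_name)))

  expect_message(
    accumulation_curve(tibble::tibble(species = "x",
                                      date = as.Date("2021-01-01")),
                       period),
    "excluded 1")
})

test_that("top-confidence review ranks deterministically and gates richness", {
  det <- toy_detections(c(0.9, 0.9, 0.8, 0.7), start_s = c(9, 3, 0, 6))
  top <- top_confidence_review(det, n = 3)
  expect_identical(nrow(top), 3L)
  # tie at 0.9 broken by the earlier timestamp
  expect_identical(top$segment_start_s[1:2], c(3, 9))

  small <- toy_detections(c(0.5, 0.6, 0.7))
  expect_identical(nrow(top_confidence_review(small, n = 10)), 3L)

  season <- simulate_season(small_config(), seed = 35)
  top <- top_confidence_review(season$detections, n = 10)
  top$confirmed <- top$truth == "true_positive"
  got <- confirmed_total_richness(top)
  oracle <- sum(vapply(
    split(top, top$scientific_name),
    function(d) any(d$truth == "true_positive"), logical(1)))
  expect_identical(got, oracle)
  expect_lte(got, length(unique(season$detections$scientific_name)))

  top$confirmed <- FALSE
  expect_identical(confirmed_total_richness(top), 0L)
})
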