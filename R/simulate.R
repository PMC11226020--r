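## Synthetic detection-stream generator. Emits ground-truth-labelled
## classifier detection tables, recording schedules, and point-count
## outcomes with the statistical structure the analysis assumes, so every
## pipeline stage runs and is validated without field audio.
##
## Noise model (the package's own, stated here and in the methods
## vignette): per recording block, true detections of an occupied species
## are homogeneous Poisson with mean vocal_rate * hours and confidences
## i.i.d. Beta(a, b) rescaled to [0.10, 1]; false detections are Poisson
## with mean fp_rate * hours at every site with confidences Beta(a', b')
## rescaled to [0.10, fp_cap]. Segments occupy the classifier's 3-s
## zero-overlap grid, placed without replacement per species within a
## block.

#' Simulation configuration
#'
#' Bundles the ground-truth community, rate, and confidence-distribution
#' parameters for the synthetic generator. Defaults emulate the study
#' conditions of the Nebraska deployment: 10 sites (5 grassland, 5
#' row-crop), a 19 May-19 July season, four recorded hours per day as two
#' fixed 2-h clock blocks, and three 10-min point-count visits per site.
#'
#' @param n_sites number of sites; habitats alternate grassland/row_crop.
#' @param species species-pool tibble; see [default_species_pool()] for the
#'   required columns.
#' @param season length-2 inclusive `Date` bounds.
#' @param blocks tibble with `start_hms` (character, "HH:MM:SS") and
#'   `duration_s` giving the daily recording blocks.
#' @param n_visits point-count visits per site per season.
#' @param visit_duration_min point-count duration in minutes.
#' @param window_s classifier prediction window in seconds.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 10,
                       species = default_species_pool(),
                       season = as.Date(c("2022-05-19", "2022-07-19")),
                       blocks = tibble(start_hms = c("05:00:00", "19:00:00"),
                                       duration_s = c(7200, 7200)),
                       n_visits = 3,
                       visit_duration_min = 10,
                       window_s = 3) {
  stopifnot(n_sites >= 1, n_visits >= 1, window_s > 0)
  season <- as.Date(season)
  if (length(season) != 2 || season[1] > season[2]) {
    abort("`season` must be two ordered dates")
  }
  need <- c("scientific_name", "common_name", "psi_grassland", "psi_row_crop",
            "vocal_rate", "tp_shape1", "tp_shape2", "fp_rate", "fp_shape1",
            "fp_shape2", "fp_cap", "p_pc")
  missing <- setdiff(need, names(species))
  if (length(missing) > 0) {
    abort(sprintf("species pool missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  probs <- c(species$psi_grassland, species$psi_row_crop, species$p_pc)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (any(species$vocal_rate < 0 | species$fp_rate < 0)) {
    abort("rates must be >= 0")
  }
  if (any(species$fp_cap <= 0.10 | species$fp_cap > 1)) {
    abort("`fp_cap` must lie in (0.10, 1]")
  }
  structure(
    list(
      n_sites = n_sites,
      sites = tibble(
        site_id = sprintf("site%02d", seq_len(n_sites)),
        habitat = rep(c("grassland", "row_crop"), length.out = n_sites)
      ),
      species = species, season = season, blocks = blocks,
      n_visits = n_visits, visit_duration_min = visit_duration_min,
      window_s = window_s
    ),
    class = "sim_config"
  )
}

#' Default synthetic species pool
#'
#' Twenty grassland species whose detection-stream rates are anchored to
#' the bundled benchmark: each species' combined per-hour detection rate is
#' its season-total detection count over the 5,189 recorded hours of the
#' benchmark deployment, split into true and false streams by its measured
#' default-stratum precision, and its false-positive confidence cap is its
#' published maximum false-positive confidence. True-detection confidences
#' lean high (Beta(2, 0.8) on [0.10, 1]); false-positive confidences lean
#' low (Beta(1, 3) on [0.10, fp_cap]).
#'
#' @param rate_scale multiplier on both detection rates, for scaled-down
#'   runs (1 reproduces the benchmark-scale stream).
#' @return A species-pool tibble accepted by [sim_config()].
#' @export
default_species_pool <- function(rate_scale = 1) {
  b <- benchmark_performance()
  total_rate <- b$n_detections_total / 5189 * rate_scale
  tibble(
    scientific_name = b$scientific_name,
    common_name = b$common_name,
    psi_grassland = 0.85,
    psi_row_crop = 0.55,
    vocal_rate = total_rate * b$precision_c10,
    tp_shape1 = 2, tp_shape2 = 0.8,
    fp_rate = total_rate * (1 - b$precision_c10),
    fp_shape1 = 1, fp_shape2 = 3,
    fp_cap = pmax(b$max_fp_confidence, 0.101),
    p_pc = 0.5
  )
}

#' Simulate the recording schedule
#'
#' One recording per site, day, and configured clock block. Deterministic
#' (the schedule carries no randomness); recordings never overlap within a
#' site.
#'
#' @param config a [sim_config()].
#' @return A recording-file tibble (`recording_id`, `site_id`, `start`,
#'   `duration_s`).
#' @export
simulate_schedule <- function(config) {
  days <- seq(config$season[1], config$season[2], by = "day")
  grid <- tidyr::expand_grid(
    site_id = config$sites$site_id,
    date = days,
    block = seq_len(nrow(config$blocks))
  )
  start <- parse_naive_datetime(paste(grid$date,
                                      config$blocks$start_hms[grid$block]))
  out <- tibble(
    recording_id = sprintf("%s_%s_b%d", grid$site_id, format(grid$date),
                           grid$block),
    site_id = grid$site_id,
    start = start,
    duration_s = config$blocks$duration_s[grid$block]
  )
  validate_schedule(out)
}

#' Simulate site occupancy
#'
#' Each species occupies each site independently with its habitat-specific
#' occupancy probability.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A tibble with `site_id`, `scientific_name`, `occupied`.
#' @export
simulate_occupancy <- function(config, seed) {
  grid <- tidyr::expand_grid(
    site_id = config$sites$site_id,
    scientific_name = config$species$scientific_name
  )
  habitat <- config$sites$habitat[match(grid$site_id, config$sites$site_id)]
  sp <- config$species[match(grid$scientific_name,
                             config$species$scientific_name), ]
  psi <- if_else(habitat == "grassland", sp$psi_grassland, sp$psi_row_crop)
  grid$occupied <- with_seed(seed, runif(nrow(grid)) < psi)
  grid
}

#' Simulate ground-truth-labelled classifier detections
#'
#' True detections arise only at occupied sites at rate `vocal_rate` per
#' recorded hour; false detections arise everywhere at rate `fp_rate`.
#' Segments are placed uniformly without replacement on the 3-s
#' zero-overlap grid of each block, so one species never overlaps itself.
#' Stripping the `truth` column leaves a valid detection table.
#'
#' @param config a [sim_config()].
#' @param schedule recording-file tibble from [simulate_schedule()].
#' @param occupancy occupancy tibble from [simulate_occupancy()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A detection tibble with extra columns `truth`
#'   (`"true_positive"`/`"false_positive"`) and `source_species` (`NA`
#'   unless a confusion source is configured).
#' @export
simulate_detections <- function(config, schedule, occupancy, seed) {
  sp <- config$species
  grid <- tidyr::expand_grid(rec = seq_len(nrow(schedule)),
                             isp = seq_len(nrow(sp)))
  hours <- schedule$duration_s[grid$rec] / 3600
  occ_key <- paste(occupancy$site_id, occupancy$scientific_name)
  occ <- occupancy$occupied[match(
    paste(schedule$site_id[grid$rec], sp$scientific_name[grid$isp]), occ_key)]
  slots <- floor(schedule$duration_s[grid$rec] / config$window_s)

  with_seed(seed, {
    n_tp <- rpois(nrow(grid), sp$vocal_rate[grid$isp] * hours * occ)
    n_fp <- rpois(nrow(grid), sp$fp_rate[grid$isp] * hours)
    n_all <- n_tp + n_fp
    over <- n_all > slots
    if (any(over)) {
      abort(sprintf(
        "demanded %d detections exceed the %d-slot capacity of recording %s",
        n_all[which(over)[1]], slots[which(over)[1]],
        schedule$recording_id[grid$rec[which(over)[1]]]))
    }
    keep <- which(n_all > 0)
    parts <- purrr::map(keep, function(k) {
      i <- grid$isp[k]
      r <- grid$rec[k]
      slot <- sort(sample.int(slots[k], n_all[k]))
      truth <- sample(rep(c("true_positive", "false_positive"),
                          c(n_tp[k], n_fp[k])))
      conf <- numeric(n_all[k])
      is_tp <- truth == "true_positive"
      conf[is_tp] <- 0.10 + 0.90 * rbeta(sum(is_tp), sp$tp_shape1[i],
                                         sp$tp_shape2[i])
      conf[!is_tp] <- 0.10 + (sp$fp_cap[i] - 0.10) *
        rbeta(sum(!is_tp), sp$fp_shape1[i], sp$fp_shape2[i])
      tibble(
        site_id = schedule$site_id[r],
        recording_id = schedule$recording_id[r],
        recording_start = schedule$start[r],
        segment_start_s = (slot - 1) * config$window_s,
        scientific_name = sp$scientific_name[i],
        common_name = sp$common_name[i],
        confidence = conf,
        truth = truth
      )
    })
    out <- list_rbind(parts)
    if (nrow(out) == 0) {
      out <- tibble(site_id = character(), recording_id = character(),
                    recording_start = as.POSIXct(character(), tz = "UTC"),
                    segment_start_s = numeric(),
                    scientific_name = character(), common_name = character(),
                    confidence = numeric(), truth = character())
    }
    out |>
      mutate(
        segment_end_s = .data$segment_start_s + config$window_s,
        timestamp = .data$recording_start + .data$segment_start_s,
        source_species = NA_character_
      ) |>
      select("site_id", "recording_id", "recording_start", "segment_start_s",
             "segment_end_s", "scientific_name", "common_name", "confidence",
             "timestamp", "truth", "source_species") |>
      arrange(.data$recording_id, .data$segment_start_s, .data$scientific_name)
  })
}

#' Simulate point-count visits and observations
#'
#' Each site receives `n_visits` surveys on random season days (morning
#' start times, 06:00-10:00). At an occupied site each species is recorded
#' on each visit independently with its `p_pc`.
#'
#' @param config a [sim_config()].
#' @param occupancy occupancy tibble from [simulate_occupancy()].
#' @param seed integer seed.
#' @return A list with `visits` (site_id, visit_start, duration_min,
#'   visit_id) and `observations` (site_id, visit_start, visit_id, species,
#'   behavior, distance_m).
#' @export
simulate_point_counts <- function(config, occupancy, seed) {
  days <- seq(config$season[1], config$season[2], by = "day")
  with_seed(seed, {
    visits <- purrr::map(config$sites$site_id, function(s) {
      d <- sort(sample(days, config$n_visits))
      hh <- runif(config$n_visits, 6, 10 - config$visit_duration_min / 60)
      tibble(
        site_id = s,
        visit_start = parse_naive_datetime(format(d)) + round(hh * 3600),
        duration_min = config$visit_duration_min
      )
    }) |> list_rbind()
    visits$visit_id <- paste(visits$site_id,
                             format_naive_datetime(visits$visit_start),
                             sep = "/")
    occ <- occupancy[occupancy$occupied, , drop = FALSE]
    obs <- purrr::map(seq_len(nrow(visits)), function(i) {
      sp_here <- occ$scientific_name[occ$site_id == visits$site_id[i]]
      p <- config$species$p_pc[match(sp_here, config$species$scientific_name)]
      seen <- runif(length(sp_here)) < p
      if (!any(seen)) return(NULL)
      k <- sum(seen)
      tibble(
        site_id = visits$site_id[i],
        visit_start = visits$visit_start[i],
        visit_id = visits$visit_id[i],
        species = sp_here[seen],
        behavior = sample(c("singing", "calling", "observed"), k,
                          replace = TRUE, prob = c(0.6, 0.3, 0.1)),
        distance_m = round(runif(k, 5, 200), 1)
      )
    }) |> list_rbind()
    if (is.null(obs) || nrow(obs) == 0) {
      obs <- tibble(site_id = character(),
                    visit_start = as.POSIXct(character(), tz = "UTC"),
                    visit_id = character(), species = character(),
                    behavior = character(), distance_m = numeric())
    }
    list(visits = visits, observations = obs)
  })
}

#' Simulate a whole season
#'
#' Convenience wrapper deriving deterministic sub-seeds from `seed` and
#' returning every artifact the pipeline consumes.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @return A list with `schedule`, `occupancy`, `detections` (labelled),
#'   `visits`, `observations`, and `seed`.
#' @export
simulate_season <- function(config, seed) {
  sub <- (as.integer(seed) + c(101L, 211L, 307L)) %% 2147483587L
  schedule <- simulate_schedule(config)
  occupancy <- simulate_occupancy(config, sub[1])
  detections <- simulate_detections(config, schedule, occupancy, sub[2])
  pc <- simulate_point_counts(config, occupancy, sub[3])
  list(schedule = schedule, occupancy = occupancy, detections = detections,
       visits = pc$visits, observations = pc$observations, seed = seed)
}

#' Oracle annotation of a validation sample
#'
#' Stands in for expert review: labels are copied from the generator's
#' ground truth, matched on (recording, segment start, species).
#'
#' @param sample a `validation_sample` from [sample_for_validation()].
#' @param labeled_detections the labelled detection tibble the sample was
#'   drawn from.
#' @return An annotation tibble (sampled detections plus `label` and
#'   `annotator`).
#' @export
oracle_annotate_sample <- function(sample, labeled_detections) {
  key <- function(d) paste(d$recording_id, d$segment_start_s,
                           d$scientific_name)
  idx <- match(key(sample$detections), key(labeled_detections))
  if (anyNA(idx)) abort("sampled detection not found in the labelled table")
  out <- sample$detections
  out$label <- labeled_detections$truth[idx]
  out$annotator <- "oracle"
  out
}

#' Oracle annotation of recall segments
#'
#' Manual species per segment are those with at least one *true*
#' vocalization overlapping it, optionally thinned per species-segment with
#' probability `manual_p` to emulate an imperfect listener. Classifier
#' species come from the detection table alone at the default 0.10
#' threshold.
#'
#' @param segments segment tibble from [sample_segments()].
#' @param labeled_detections labelled detection tibble.
#' @param manual_p probability a truly present species is heard by the
#'   annotator (1 = perfect listener).
#' @param seed seed for the thinning draws (required when `manual_p < 1`).
#' @param min_confidence classifier retention threshold (0.10).
#' @return `segments` with list-columns `manual_species` and
#'   `classifier_species`.
#' @export
oracle_annotate_segments <- function(segments, labeled_detections,
                                     manual_p = 1, seed = NULL,
                                     min_confidence = 0.10) {
  truth <- labeled_detections[labeled_detections$truth == "true_positive", ,
                              drop = FALSE]
  manual <- pmap(
    list(segments$recording_id, segments$start_s, segments$end_s),
    function(rec, s, e) {
      hit <- truth$recording_id == rec & truth$segment_start_s < e &
        truth$segment_end_s > s
      sort(unique(truth$scientific_name[hit]))
    }
  )
  if (manual_p < 1) {
    if (is.null(seed)) abort("`seed` is required when `manual_p` < 1")
    manual <- with_seed(seed, {
      purrr::map(manual, function(sp) sp[runif(length(sp)) < manual_p])
    })
  }
  segments$manual_species <- manual
  segment_classifier_species(segments, labeled_detections, min_confidence)
}
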