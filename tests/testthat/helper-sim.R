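# Small fixtures built in code for the test suite.

# minimal custom species pool with explicit stream parameters
make_pool <- function(scientific_name, vocal_rate, fp_rate,
                      fp_cap = 0.5, psi = 1, p_pc = 0.5,
                      tp_shape1 = 2, tp_shape2 = 0.8,
                      fp_shape1 = 1, fp_shape2 = 3) {
  tibble::tibble(
    scientific_name = scientific_name,
    common_name = scientific_name,
    psi_grassland = psi, psi_row_crop = psi,
    vocal_rate = vocal_rate, tp_shape1 = tp_shape1, tp_shape2 = tp_shape2,
    fp_rate = fp_rate, fp_shape1 = fp_shape1, fp_shape2 = fp_shape2,
    fp_cap = fp_cap, p_pc = p_pc
  )
}

# a small, fast season: 2 sites, 5 days, 3 moderately vocal species
small_config <- function(n_sites = 2, n_days = 5, psi = 1,
                         vocal_rate = c(4, 2, 1), fp_rate = c(1, 0.5, 0.25)) {
  sim_config(
    n_sites = n_sites,
    species = make_pool(c("Species alpha", "Species beta", "Species gamma"),
                        vocal_rate = vocal_rate, fp_rate = fp_rate, psi = psi),
    season = as.Date("2022-05-19") + c(0, n_days - 1)
  )
}

# deterministic 30-visit fixture: 10 sites x 3 visits at 08:00, with a
# 07:00-09:00 recording on the same day except for 6 chosen visits
pairing_fixture <- function() {
  sites <- sprintf("site%02d", 1:10)
  days <- as.Date("2022-05-20") + c(0, 10, 20)
  visits <- tidyr::expand_grid(site_id = sites, day = days)
  visits$visit_start <- as.POSIXct(paste(visits$day, "08:00:00"), tz = "UTC")
  visits$duration_min <- 10
  drop <- c("site01 2022-05-20", "site02 2022-05-30", "site03 2022-06-09",
            "site04 2022-05-20", "site05 2022-05-30", "site06 2022-06-09")
  keep <- !paste(visits$site_id, visits$day) %in% drop
  recordings <- tibble::tibble(
    recording_id = sprintf("rec%02d", seq_len(sum(keep))),
    site_id = visits$site_id[keep],
    start = as.POSIXct(paste(visits$day[keep], "07:00:00"), tz = "UTC"),
    duration_s = 7200)
  list(visits = dplyr::select(visits, -day), recordings = recordings)
}

# hand-built detection tibble for filter/order tests
toy_detections <- function(confidence,
                           species = rep("Species alpha", length(confidence)),
                           start_s = seq(0, by = 3,
                                         length.out = length(confidence))) {
  detection_tbl(
    site_id = "site01", recording_id = "rec01",
    recording_start = as.POSIXct("2022-05-19 06:00:00", tz = "UTC"),
    segment_start_s = start_s, segment_end_s = start_s + 3,
    scientific_name = species, common_name = species,
    confidence = confidence
  )
}
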