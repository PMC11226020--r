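## Bundled benchmark: published validation metrics for 20 grassland focal
## species from a Nebraska ARU deployment. Used as the reference fixture for
## the SSC decision rule and F-score round-trip checks, and as the default
## focal list and species catalog.

#' Benchmark validation metrics for 20 grassland focal species
#'
#' Per-species classifier performance measured against expert annotation in
#' a Nebraska grassland/row-crop ARU study: total detections over the season,
#' maximum confidence, precision from 60-detection validation samples at the
#' 0.10 (default) and 0.25 confidence strata, maximum confidence observed on
#' a false-positive detection, segment-level recall from 50 random 120-s
#' clips, the F-score (harmonic mean of the 0.10-stratum precision and
#' recall), and the species-specific confidence (SSC) threshold published
#' alongside them. Recall and F are `NA` for the three species never
#' manually detected in the recall segments.
#'
#' @return A tibble with one row per focal species.
#' @export
benchmark_performance <- function() {
  tibble::tribble(
    ~scientific_name, ~common_name, ~n_detections_total, ~max_confidence,
    ~precision_c10, ~precision_c25, ~max_fp_confidence, ~recall, ~f_score, ~ssc,
    "Spinus tristis", "American Goldfinch", 4004L, 0.999, 0.967, 1.000, 0.186, 1.000, 0.983, 0.100,
    "Turdus migratorius", "American Robin", 75153L, 0.999, 0.933, 0.939, 0.551, 0.500, 0.651, 0.100,
    "Hirundo rustica", "Barn Swallow", 9046L, 0.999, 0.950, 1.000, 0.195, NA, NA, 0.100,
    "Passerina caerulea", "Blue Grosbeak", 26670L, 0.999, 0.683, 0.879, 0.914, 1.000, 0.812, 0.250,
    "Cyanocitta cristata", "Blue Jay", 6539L, 0.999, 0.983, 1.000, 0.206, 0.667, 0.795, 0.100,
    "Quiscalus quiscula", "Common Grackle", 8407L, 0.998, 0.867, 0.939, 0.574, 1.000, 0.929, 0.100,
    "Chordeiles minor", "Common Nighthawk", 26179L, 0.998, 1.000, 1.000, 0.100, 1.000, 1.000, 0.100,
    "Spiza americana", "Dickcissel", 397405L, 0.997, 0.933, 1.000, 0.200, 0.588, 0.722, 0.100,
    "Tyrannus tyrannus", "Eastern Kingbird", 28748L, 0.997, 1.000, 1.000, 0.100, 1.000, 1.000, 0.100,
    "Ammodramus savannarum", "Grasshopper Sparrow", 956111L, 0.996, 0.533, 0.652, 0.448, 0.800, 0.640, 0.448,
    "Eremophila alpestris", "Horned Lark", 581287L, 0.996, 0.817, 0.955, 0.628, 0.833, 0.825, 0.250,
    "Zenaida macroura", "Mourning Dove", 31117L, 0.995, 0.867, 0.974, 0.293, 0.500, 0.634, 0.100,
    "Colinus virginianus", "Northern Bobwhite", 34608L, 0.995, 0.817, 1.000, 0.227, 1.000, 0.899, 0.250,
    "Agelaius phoeniceus", "Red-winged Blackbird", 148573L, 0.997, 0.967, 1.000, 0.129, 0.600, 0.740, 0.100,
    "Phasianus colchicus", "Ring-necked Pheasant", 13152L, 0.999, 0.967, 0.962, 0.717, 0.760, 0.851, 0.100,
    "Passerculus sandwichensis", "Savannah Sparrow", 4439L, 0.998, 0.567, 0.889, 0.494, 0.500, 0.531, 0.250,
    "Tachycineta bicolor", "Tree Swallow", 7637L, 0.996, 0.117, 0.333, 0.505, NA, NA, 0.505,
    "Tyrannus verticalis", "Western Kingbird", 4958L, 0.999, 0.917, 0.959, 0.711, NA, NA, 0.100,
    "Sturnella neglecta", "Western Meadowlark", 1331498L, 0.999, 0.650, 0.821, 0.598, 0.867, 0.743, 0.250,
    "Meleagris gallopavo", "Wild Turkey", 4083L, 0.999, 0.800, 0.923, 0.653, 1.000, 0.889, 0.250
  )
}

#' Default focal species list
#'
#' Scientific names of the 20 grassland focal species of
#' [benchmark_performance()].
#'
#' @return A character vector of 20 scientific names.
#' @export
focal_species <- function() {
  benchmark_performance()$scientific_name
}

#' Species alias catalog for the focal list
#'
#' A minimal catalog mapping the focal species' scientific and common names
#' (any case) onto canonical pairs, suitable for
#' [canonicalize_species()].
#'
#' @return A tibble with columns `alias`, `scientific`, `common`.
#' @export
focal_species_catalog <- function() {
  b <- benchmark_performance()
  tibble(alias = b$common_name, scientific = b$scientific_name,
         common = b$common_name)
}
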