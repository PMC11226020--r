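## Paired comparison of ARU-derived and point-count richness: Student
## paired two-tailed t-tests per threshold and period, delta-table assembly.

#' Paired two-tailed Student t-test
#'
#' Computed in closed form on the differences `y - x` with `n - 1` degrees
#' of freedom. Degenerate zero-variance differences follow fixed
#' conventions rather than erroring (small simulated fixtures hit them
#' routinely): all-zero differences give `t = 0, p = 1`; zero variance with
#' nonzero mean gives `t = +/-Inf, p = 0`.
#'
#' @param x,y paired numeric vectors, aligned by analysis unit (for method
#'   comparison: `x` = point-count richness, `y` = ARU richness, so the
#'   mean difference is ARU minus point count).
#' @return A list with `t_statistic`, `df`, `p_value`, `mean_delta`, `n`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must be the same length")
  if (length(x) < 2) abort("need at least 2 pairs")
  d <- y - x
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  list(t_statistic = t_stat, df = n - 1, p_value = p, mean_delta = m, n = n)
}

#' Build the threshold-by-period paired comparison table
#'
#' One paired t-test per (threshold, period) cell comparing ARU richness
#' against point-count richness on matched analysis units: visits for the
#' short duration, sites for the long duration. Positive `mean_delta` means
#' the ARUs yielded more species.
#'
#' @param aru_richness richness records with `method == "aru"` covering the
#'   requested thresholds and periods.
#' @param pc_richness point-count richness records (`method ==
#'   "point_count"`) with both periods.
#' @param thresholds threshold labels to compare (default the study set).
#' @param periods periods to compare (default short and long).
#' @param alpha significance level for the `significant` flag (0.05).
#' @return A tibble with one row per (period, threshold): `n_pairs`,
#'   `mean_delta`, `t_statistic`, `df`, `p_value`, `significant`.
#' @export
build_delta_table <- function(aru_richness, pc_richness,
                              thresholds = c("SSC", "0.1", "0.25", "0.5",
                                             "0.75", "0.9"),
                              periods = c("short", "long"),
                              alpha = 0.05) {
  grid <- tidyr::expand_grid(period = periods, threshold_label = thresholds)
  purrr::map(seq_len(nrow(grid)), function(i) {
    per <- grid$period[i]
    thr <- grid$threshold_label[i]
    key <- if (per == "short") "visit_id" else "site_id"
    a <- aru_richness[aru_richness$period == per &
                        aru_richness$threshold_label == thr, , drop = FALSE]
    p <- pc_richness[pc_richness$period == per, , drop = FALSE]
    if (nrow(a) == 0) abort(sprintf("no ARU richness for period %s threshold %s",
                                    per, thr))
    joined <- inner_join(
      select(a, unit = all_of(key), aru = "richness"),
      select(p, unit = all_of(key), pc = "richness"),
      by = "unit"
    )
    unmatched_a <- setdiff(a[[key]], joined$unit)
    unmatched_p <- setdiff(p[[key]], joined$unit)
    if (length(unmatched_a) > 0 || length(unmatched_p) > 0) {
      abort(sprintf("unmatched analysis unit(s) between methods: %s",
                    paste(c(unmatched_a, unmatched_p), collapse = ", ")))
    }
    joined <- arrange(joined, .data$unit)
    tt <- paired_t_test(joined$pc, joined$aru)
    tibble(
      period = per, threshold_label = thr, n_pairs = tt$n,
      mean_delta = tt$mean_delta, t_statistic = tt$t_statistic,
      df = tt$df, p_value = tt$p_value,
      significant = tt$p_value < alpha
    )
  }) |> list_rbind()
}
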