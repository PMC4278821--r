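#' Acoustic analysis time of a sampling campaign
#'
#' The dominant cost of passive acoustic inventories is not the fieldwork
#' but identifying the recorded sequences. With `N_n` nights at `N_p` plots,
#' a mean of `X_s` sequences per night and plot, and `A` hours of analyst
#' time per sequence, the analysis workload is `T_a = N_n * N_p * X_s * A`.
#' The result is rounded half-up to 0.1 h, the resolution at which such
#' workloads are reported and costed.
#'
#' @param n_nights,n_plots campaign size.
#' @param seq_per_night_plot mean sequences recorded per night and plot
#'   (`X_s`).
#' @param analysis_time_per_seq analyst hours per sequence (`A`); default
#'   20 seconds, the package-wide default for semi-automated identification
#'   (see the vignette for its provenance).
#' @return analysis hours, rounded to 0.1 h.
#' @export
analysis_time <- function(n_nights, n_plots, seq_per_night_plot,
                          analysis_time_per_seq = 1 / 180) {
  stopifnot(all(n_nights >= 0), all(n_plots >= 0),
            all(seq_per_night_plot >= 0), all(analysis_time_per_seq >= 0))
  round_half_up(n_nights * n_plots * seq_per_night_plot * analysis_time_per_seq, 1)
}

#' Total time invested in a campaign
#'
#' `T_t = T_f + T_a`: field-management hours plus analysis hours.
#'
#' @param field_hours fieldwork time `T_f` (an input: travel, deployment,
#'   rotation and retrieval of detectors).
#' @param analysis_hours analysis time `T_a`, see [analysis_time()].
#' @return total hours.
#' @export
total_time <- function(field_hours, analysis_hours) {
  stopifnot(all(field_hours >= 0), all(analysis_hours >= 0))
  field_hours + analysis_hours
}

#' Labor and equipment costs of cost scenarios
#'
#' For each scenario row: analysis time from [analysis_time()] (already
#' rounded to 0.1 h before any cost arithmetic), labor cost
#' `T_f * field_rate + T_a * analysis_rate`, equipment cost
#' `n_plots * detectors_per_plot * detector_unit_price`, and their sum.
#' Fieldwork is costed at a technician rate and analysis at an expert rate,
#' reflecting who performs each task.
#'
#' @param scenarios data frame with columns `n_plots`, `n_nights`,
#'   `field_hours`, `seq_per_night_plot`, `analysis_time_per_seq`,
#'   `field_rate`, `analysis_rate`, `detector_unit_price`,
#'   `detectors_per_plot` (the number of microhabitats in the design), and
#'   optionally `scheme`; see [example_cost_scenarios()].
#' @return the scenarios with appended columns `analysis_hours`,
#'   `total_hours`, `labor_cost`, `detector_cost`, `total_cost`.
#' @export
cost_breakdown <- function(scenarios) {
  need <- c("n_plots", "n_nights", "field_hours", "seq_per_night_plot",
            "analysis_time_per_seq", "field_rate", "analysis_rate",
            "detector_unit_price", "detectors_per_plot")
  missing_cols <- setdiff(need, names(scenarios))
  if (length(missing_cols) > 0) {
    abort("scenario table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  out <- scenarios
  out$analysis_hours <- analysis_time(out$n_nights, out$n_plots,
                                      out$seq_per_night_plot,
                                      out$analysis_time_per_seq)
  out$total_hours <- total_time(out$field_hours, out$analysis_hours)
  out$labor_cost <- out$field_hours * out$field_rate +
    out$analysis_hours * out$analysis_rate
  out$detector_cost <- out$n_plots * out$detectors_per_plot * out$detector_unit_price
  out$total_cost <- out$labor_cost + out$detector_cost
  out
}

#' Scenario cost table with per-scheme dispersion
#'
#' Computes [cost_breakdown()] for every scenario and summarises, per
#' scheme, the mean and sample standard deviation (n - 1 denominator) of
#' total cost across its scenarios - the "about X (+/- sd)" figure used to
#' compare schemes whose plot counts differ. A scheme with a single
#' scenario reports `NA` dispersion (undefined, not zero).
#'
#' @param scenarios as for [cost_breakdown()]; a `scheme` column groups the
#'   dispersion summary (a single group is assumed if absent).
#' @return list with `breakdown` (per-scenario costs) and `dispersion`
#'   (scheme, n_scenarios, mean_total_cost, sd_total_cost).
#' @export
scenario_table <- function(scenarios) {
  bd <- cost_breakdown(scenarios)
  scheme <- if ("scheme" %in% names(bd)) bd$scheme else rep("all", nrow(bd))
  disp <- do.call(rbind, lapply(split(seq_len(nrow(bd)), scheme), function(idx) {
    tc <- bd$total_cost[idx]
    data.frame(scheme = scheme[idx[1]], n_scenarios = length(idx),
               mean_total_cost = mean(tc),
               sd_total_cost = if (length(tc) > 1) stats::sd(tc) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(disp) <- NULL
  list(breakdown = bd, dispersion = disp)
}
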