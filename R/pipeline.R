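#' Run the full sampling-scheme evaluation pipeline
#'
#' End-to-end orchestration: ingest (or simulate) detection records,
#' collapse indistinguishable taxa, build per-plot incidence matrices for
#' every requested scheme, estimate accumulation curves by permutation,
#' fit the Clench model per plot, average parameters per scheme, solve for
#' the effort reaching the target completeness fraction, optionally cost
#' the supplied scenarios, and write every table (delimited text) plus a
#' run manifest to `out_dir`. Identical configuration and seed give
#' identical outputs.
#'
#' @param records a `bat_records` data frame or a path to a records file
#'   ([read_records()]); `NULL` to simulate instead.
#' @param community,layout simulation inputs used when `records` is `NULL`;
#'   default [default_community()] and [survey_layout()].
#' @param schemes `"all"` (the 21 candidates) or a list of
#'   [sampling_scheme()] objects.
#' @param n_perm permutations per accumulation curve.
#' @param q completeness fraction for the effort target (default 0.9).
#' @param seed integer seed governing every stochastic stage.
#' @param cost_scenarios optional scenario data frame for [scenario_table()].
#' @param out_dir output directory, created if needed.
#' @param config optional path to a YAML file (or a named list) supplying
#'   any of the above fields; explicit arguments win over config values.
#' @return (invisibly) list with the computed tables and output paths.
#' @export
run_pipeline <- function(records = NULL, community = NULL, layout = NULL,
                         schemes = "all", n_perm = 1000, q = 0.9, seed = 1,
                         cost_scenarios = NULL, out_dir, config = NULL) {
  if (!is.null(config)) {
    cfg <- if (is.character(config)) yaml::read_yaml(config) else config
    if (is.null(records) && !is.null(cfg$records)) records <- cfg$records
    if (!is.null(cfg$n_perm) && missing(n_perm)) n_perm <- cfg$n_perm
    if (!is.null(cfg$q) && missing(q)) q <- cfg$q
    if (!is.null(cfg$seed) && missing(seed)) seed <- cfg$seed
    if (!is.null(cfg$cost_scenarios) && is.null(cost_scenarios)) {
      cost_scenarios <- utils::read.csv(cfg$cost_scenarios, stringsAsFactors = FALSE)
    }
  }
  if (q <= 0 || q >= 1) abort("stage config: `q` must lie in (0, 1)")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("stage %s: %s", name, conditionMessage(e))
    })
  }

  # --- input ---------------------------------------------------------------
  recs <- stage("input", {
    if (is.character(records)) {
      if (!file.exists(records)) abort("records file not found: %s", records)
      read_records(records)
    } else if (is.null(records)) {
      simulate_survey(community %||% default_community(),
                      layout %||% survey_layout(), seed = seed)
    } else {
      as_bat_records(records)
    }
  })
  n_in <- nrow(recs)
  recs <- stage("collapse", collapse_taxa(recs))

  scheme_list <- stage("schemes", {
    if (identical(schemes, "all")) enumerate_schemes() else schemes
  })
  if (length(scheme_list) == 0) abort("stage schemes: empty scheme list")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set_seed_if(seed + 1L) # accumulation RNG stream, distinct from simulation

  units <- unique(recs[, c("cell_id", "plot_id")])
  units <- units[order(units$cell_id, units$plot_id), , drop = FALSE]

  curves <- list(); fits <- list(); efforts <- list()
  for (sch in scheme_list) {
    lab <- scheme_label(sch)
    unit_fits <- list()
    for (i in seq_len(nrow(units))) {
      ulab <- paste(units$cell_id[i], units$plot_id[i], sep = "/")
      inc <- stage("accumulate", build_incidence(recs, sch, cell = units$cell_id[i],
                                                 plot = units$plot_id[i]))
      cur <- stage("accumulate", accumulation_permuted(inc, n_perm = n_perm))
      curves[[length(curves) + 1L]] <- data.frame(
        scheme = lab, unit = ulab, effort = cur$effort,
        mean_richness = cur$mean_richness, sd_richness = cur$sd_richness,
        stringsAsFactors = FALSE)
      if (nrow(cur) >= 3 && cur$mean_richness[nrow(cur)] > 0) {
        f <- stage("fit", fit_clench(cur))
        fits[[length(fits) + 1L]] <- data.frame(
          scheme = lab, unit = ulab, a = f$a, b = f$b, asymptote = f$asymptote,
          residual_sse = f$residual_sse, converged = f$converged,
          stringsAsFactors = FALSE)
        if (isTRUE(f$converged)) unit_fits[[ulab]] <- f
      }
    }
    if (length(unit_fits) > 0) {
      avg <- stage("fit", average_fits(unit_fits))
      eff <- stage("effort", effort_to_fraction(avg, q))
      efforts[[length(efforts) + 1L]] <- data.frame(
        scheme = lab, n_units = length(unit_fits), a = avg$a, b = avg$b,
        asymptote = avg$asymptote, q = q, effort = eff$effort,
        nights = eff$nights, stringsAsFactors = FALSE)
    }
  }
  curve_tab <- do.call(rbind, curves)
  fit_tab <- if (length(fits) > 0) do.call(rbind, fits) else NULL
  effort_tab <- if (length(efforts) > 0) do.call(rbind, efforts) else NULL

  cost_tab <- if (!is.null(cost_scenarios)) stage("cost", scenario_table(cost_scenarios)) else NULL

  # --- report --------------------------------------------------------------
  paths <- c(curves = file.path(out_dir, "curves.csv"),
             fits = file.path(out_dir, "fits.csv"),
             effort = file.path(out_dir, "effort.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  stage("report", {
    utils::write.csv(curve_tab, paths["curves"], row.names = FALSE)
    if (!is.null(fit_tab)) utils::write.csv(fit_tab, paths["fits"], row.names = FALSE)
    if (!is.null(effort_tab)) utils::write.csv(effort_tab, paths["effort"], row.names = FALSE)
    if (!is.null(cost_tab)) {
      utils::write.csv(cost_tab$breakdown, file.path(out_dir, "costs.csv"),
                       row.names = FALSE)
      utils::write.csv(cost_tab$dispersion, file.path(out_dir, "cost_dispersion.csv"),
                       row.names = FALSE)
    }
    manifest <- list(
      package = "forestbats",
      version = as.character(utils::packageVersion("forestbats")),
      seed = seed, n_perm = n_perm, q = q,
      n_records_in = n_in,
      n_schemes = length(scheme_list),
      schemes = vapply(scheme_list, scheme_label, character(1))
    )
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(list(records = recs, curves = curve_tab, fits = fit_tab,
                 effort = effort_tab, costs = cost_tab, paths = paths))
}
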