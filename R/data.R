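#' Bundled reference sequence counts from a temperate forest bat survey
#'
#' Per-taxon sequence counts by microhabitat from an intensive passive
#' acoustic campaign in mixed European lowland forest (8 one-km2 cells, four
#' plots each, three microhabitats per plot, full-night recording), together
#' with the counts per identification level for the whole campaign. These
#' counts anchor the package defaults: the dominance structure and
#' microhabitat affinities of [default_community()] and the worked
#' identification-summary examples.
#'
#' @return list with elements `taxa` (taxon, level, guild, and sequence
#'   counts in gap / ground / canopy plus `total`) and `levels` (sequence
#'   counts per identification level).
#' @export
survey_reference_counts <- function() {
  taxa <- utils::read.csv(system.file("extdata", "survey_taxon_counts.csv",
                                      package = "forestbats"),
                          stringsAsFactors = FALSE)
  taxa$total <- taxa$gap + taxa$ground + taxa$canopy
  levels <- utils::read.csv(system.file("extdata", "survey_identification_levels.csv",
                                        package = "forestbats"),
                            stringsAsFactors = FALSE)
  list(taxa = taxa, levels = levels)
}

#' Reference counts as weighted pseudo-records
#'
#' Expands [survey_reference_counts()] into a data frame with one row per
#' (taxon, microhabitat) and a multiplicity column `n`, suitable for
#' [summarize_identification()]. Sequences counted in the level totals but
#' not attributable to a guild-assignable taxon (species complexes, genus-
#' and order-level identifications) are carried as `guild = "UNKNOWN"` rows,
#' so both the level percentages and the within-guild-assignable taxon
#' percentages reproduce from a single input.
#'
#' @return data frame with columns `taxon`, `taxon_level`, `guild`,
#'   `microhabitat`, `n`.
#' @export
survey_reference_records <- function() {
  ref <- survey_reference_counts()
  taxa <- ref$taxa
  mh <- c(gap = "GAP", ground = "GROUND", canopy = "CANOPY")
  rows <- do.call(rbind, lapply(names(mh), function(col) {
    data.frame(taxon = taxa$taxon, taxon_level = taxa$level, guild = taxa$guild,
               microhabitat = mh[[col]], n = taxa[[col]], stringsAsFactors = FALSE)
  }))
  rows <- rows[rows$n > 0, , drop = FALSE]

  # level totals not accounted for by the guild-assignable taxon table
  assigned <- stats::aggregate(n ~ taxon_level, data = rows, FUN = sum)
  rem <- ref$levels
  rem$assigned <- assigned$n[match(rem$level, assigned$taxon_level)]
  rem$assigned[is.na(rem$assigned)] <- 0
  rem$n <- rem$n - rem$assigned
  if (any(rem$n < 0)) abort("reference level counts are inconsistent with the taxon table")
  rem <- rem[rem$n > 0, , drop = FALSE]
  extra <- data.frame(
    taxon = ifelse(rem$level == "ORDER", "Chiroptera",
                   paste0("unassigned (", tolower(rem$level), ")")),
    taxon_level = rem$level, guild = "UNKNOWN",
    microhabitat = NA_character_, n = rem$n, stringsAsFactors = FALSE
  )
  out <- rbind(rows, extra)
  rownames(out) <- NULL
  out
}

#' Default taxon-to-guild lookup
#'
#' Guilds of the reference community plus the individual members of the
#' default species groups (see [default_taxon_groups()]), so raw records
#' identified to either a group or its member species resolve to a guild.
#'
#' @return named character vector `taxon -> guild`.
#' @export
default_guild_table <- function() {
  taxa <- survey_reference_counts()$taxa
  tab <- stats::setNames(taxa$guild, taxa$taxon)
  groups <- default_taxon_groups()
  for (g in names(groups)) {
    if (g %in% names(tab)) {
      tab[groups[[g]]] <- tab[[g]]
    }
  }
  c(tab, Chiroptera = "UNKNOWN")
}

#' Bundled cost scenarios for a 1-km2 forest inventory
#'
#' Six ready-made [cost model][cost_breakdown] scenarios for the two sampling
#' schemes that reach 90% of asymptotic plot-level richness under full-night
#' recording - all three microhabitats, or forest gap + forest ground - each
#' implemented at 2, 3 or 4 plots per square kilometre. Nights required,
#' field-management hours and mean sequences recorded per night and plot are
#' the published reference values for those schemes; rates default to 50
#' currency units/h for fieldwork, 100/h for acoustic analysis, 1645 per
#' detector, and 20 s of analysis per recorded sequence.
#'
#' @return data frame of scenarios, one row each, ready for [cost_breakdown()].
#' @export
example_cost_scenarios <- function() {
  sc <- utils::read.csv(system.file("extdata", "cost_scenarios.csv",
                                    package = "forestbats"),
                        stringsAsFactors = FALSE)
  design_size <- lengths(strsplit(sc$design, "+", fixed = TRUE))
  data.frame(
    scheme = sc$scheme,
    n_plots = sc$n_plots,
    n_nights = sc$n_nights,
    field_hours = sc$field_hours,
    seq_per_night_plot = sc$seq_per_night_plot,
    analysis_time_per_seq = 1 / 180,
    field_rate = 50,
    analysis_rate = 100,
    detector_unit_price = 1645,
    detectors_per_plot = design_size,
    stringsAsFactors = FALSE
  )
}
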