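#' Nightly activity index of a taxon or guild
#'
#' Activity is quantified as the number of distinct 5-minute intervals of a
#' night containing at least one matching sequence, a measure robust to a
#' single bat foraging around the microphone for long spells. Bins are
#' anchored at 21:30 and half-open (`bin k = [5k, 5(k+1))`), so the maximum
#' per night is 96 (8 h x 60 min / 5 min).
#'
#' @param records `bat_records` from a single site-night.
#' @param taxon optional taxon selector (character vector).
#' @param guild optional guild selector; guild matching uses records of all
#'   identification levels assignable to that guild.
#' @return integer in `[0, 96]`.
#' @export
activity_index <- function(records, taxon = NULL, guild = NULL) {
  if (nrow(records) > 0) {
    if (length(unique(records$site_id)) > 1 || length(unique(records$night_id)) > 1) {
      abort("activity_index expects records from a single site-night")
    }
  }
  keep <- rep(TRUE, nrow(records))
  if (!is.null(taxon)) keep <- keep & records$taxon %in% taxon
  if (!is.null(guild)) keep <- keep & records$guild %in% guild
  length(unique(records$timestamp[keep] %/% 5))
}

#' Per-night guild activity table
#'
#' Activity indices per guild for every site-night in `records`, with the
#' option to exclude hyperabundant taxa (a dominant species can swamp its
#' guild's index and mask the behaviour of the rarer members). Site-nights
#' are taken from the full record set before exclusion, so a night emptied
#' by the exclusion still appears with index 0. Guild-unassignable records
#' (`UNKNOWN`) never contribute.
#'
#' @param records `bat_records`.
#' @param exclude_taxa taxa whose records are dropped before counting.
#' @param guilds guilds to tabulate.
#' @return data frame (guild, microhabitat, cell_id, plot_id, site_id,
#'   night_id, index).
#' @export
guild_activity_table <- function(records, exclude_taxa = character(),
                                 guilds = c("SRE", "MRE", "LRE")) {
  site_nights <- unique(records[, c("site_id", "night_id", "microhabitat",
                                    "cell_id", "plot_id")])
  if (nrow(site_nights) == 0) {
    return(data.frame(guild = character(), microhabitat = character(),
                      cell_id = character(), plot_id = character(),
                      site_id = character(), night_id = character(),
                      index = integer(), stringsAsFactors = FALSE))
  }
  use <- records[!(records$taxon %in% exclude_taxa) & records$guild %in% guilds, ,
                 drop = FALSE]
  # one row per occupied (guild, site, night, bin)
  occ <- unique(data.frame(guild = use$guild, site_id = use$site_id,
                           night_id = use$night_id,
                           bin = use$timestamp %/% 5, stringsAsFactors = FALSE))
  counts <- if (nrow(occ) > 0) {
    stats::aggregate(list(index = occ$bin),
                     by = occ[, c("guild", "site_id", "night_id")], FUN = length)
  } else {
    data.frame(guild = character(), site_id = character(),
               night_id = character(), index = integer())
  }
  grid <- merge(site_nights, data.frame(guild = guilds, stringsAsFactors = FALSE))
  out <- merge(grid, counts, by = c("guild", "site_id", "night_id"), all.x = TRUE)
  out$index[is.na(out$index)] <- 0L
  out$index <- as.integer(out$index)
  out <- out[order(out$guild, out$site_id, out$night_id),
             c("guild", "microhabitat", "cell_id", "plot_id", "site_id",
               "night_id", "index")]
  rownames(out) <- NULL
  out
}

#' Mean and spread of guild activity per microhabitat
#'
#' @param activity_table output of [guild_activity_table()].
#' @return data frame (guild, microhabitat, mean_index, sd_index, n_nights).
#' @export
guild_activity_summary <- function(activity_table) {
  out <- stats::aggregate(
    index ~ guild + microhabitat, data = activity_table,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x))
  )
  data.frame(guild = out$guild, microhabitat = out$microhabitat,
             mean_index = out$index[, "mean"], sd_index = out$index[, "sd"],
             n_nights = as.integer(out$index[, "n"]), stringsAsFactors = FALSE)
}
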