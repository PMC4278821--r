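#' Define a simulated bat community
#'
#' The generator draws, for every (site, night, species), a Poisson number of
#' echolocation sequences with mean
#' `base_rate * abundance_weight * affinity(species, microhabitat)`, and
#' places each sequence in the night by a two-component truncated-Gaussian
#' mixture, reflecting the bimodal (post-dusk / pre-dawn) shape of bat
#' activity.
#'
#' @param taxa character vector of taxon labels.
#' @param abundance_weights nonnegative relative rates, summing to 1.
#' @param guilds guild per taxon (`SRE`/`MRE`/`LRE`).
#' @param affinity taxa x 3 matrix of nonnegative microhabitat multipliers,
#'   columns `GROUND`, `CANOPY`, `GAP`. A row averaging 1 leaves the
#'   species' overall rate unchanged; a zero entry is a structural absence.
#' @param activity data frame with one row per taxon and columns
#'   `peak1_time`, `peak1_sd`, `peak2_time`, `peak2_sd` (minutes from 21:30,
#'   peak times in `[0, 480)`) and `peak1_weight` (mixture weight of the
#'   first peak, in `[0, 1]`).
#' @param base_rate expected sequences per unit abundance weight per site
#'   and night (so with row-mean-1 affinities, the expected total per
#'   site-night across the community is `base_rate`).
#' @param taxon_levels identification level per taxon; defaults to
#'   `SPECIES`.
#' @return object of class `community_config`.
#' @export
community_config <- function(taxa, abundance_weights, guilds, affinity,
                             activity, base_rate,
                             taxon_levels = rep("SPECIES", length(taxa))) {
  k <- length(taxa)
  stopifnot(length(abundance_weights) == k, length(guilds) == k,
            nrow(affinity) == k, ncol(affinity) == 3,
            nrow(activity) == k, length(taxon_levels) == k)
  if (any(abundance_weights < 0)) abort("abundance weights must be nonnegative")
  if (abs(sum(abundance_weights) - 1) > 1e-9) {
    abort("abundance weights must sum to 1 (got %.12f)", sum(abundance_weights))
  }
  if (any(affinity < 0)) abort("affinity entries must be nonnegative")
  if (is.null(colnames(affinity))) colnames(affinity) <- BAT_MICROHABITATS
  affinity <- affinity[, BAT_MICROHABITATS, drop = FALSE]
  need <- c("peak1_time", "peak1_sd", "peak2_time", "peak2_sd", "peak1_weight")
  if (!all(need %in% names(activity))) {
    abort("activity profile must have columns %s", paste(need, collapse = ", "))
  }
  pk <- c(activity$peak1_time, activity$peak2_time)
  if (any(pk < 0 | pk >= NIGHT_MINUTES)) abort("activity peak times must lie in [0, 480)")
  if (any(activity$peak1_weight < 0 | activity$peak1_weight > 1)) {
    abort("peak1_weight must lie in [0, 1]")
  }
  if (base_rate < 0) abort("base_rate must be nonnegative")
  if (!all(guilds %in% c("SRE", "MRE", "LRE"))) abort("guilds must be SRE, MRE or LRE")
  out <- list(taxa = as.character(taxa), abundance_weights = abundance_weights,
              guilds = as.character(guilds), affinity = affinity,
              activity = activity, base_rate = base_rate,
              taxon_levels = as.character(taxon_levels))
  class(out) <- "community_config"
  out
}

#' Define a survey layout
#'
#' Defaults mirror the reference campaign: 8 one-km2 cells, 4 plots per
#' cell, the three fixed microhabitats per plot, and 6-12 recording nights
#' per cell (drawn uniformly).
#'
#' @param n_cells,plots_per_cell positive integers.
#' @param nights_min,nights_max inclusive range of nights per cell.
#' @return object of class `survey_layout`.
#' @export
survey_layout <- function(n_cells = 8, plots_per_cell = 4,
                          nights_min = 6, nights_max = 12) {
  stopifnot(n_cells >= 1, plots_per_cell >= 1,
            nights_min >= 1, nights_max >= nights_min)
  out <- list(n_cells = as.integer(n_cells),
              plots_per_cell = as.integer(plots_per_cell),
              nights_min = as.integer(nights_min),
              nights_max = as.integer(nights_max))
  class(out) <- "survey_layout"
  out
}

#' Default community: the reference survey's shape
#'
#' Sixteen taxa in three guilds with the reference survey's dominance
#' structure (the commonest species carries ~87% of the abundance weight)
#' and microhabitat affinities proportional to each taxon's observed
#' distribution over gap / ground / canopy (scaled to row mean 1, so zeros
#' are preserved as structural absences). Activity profiles are bimodal with
#' a dominant post-dusk peak and a secondary pre-dawn peak, varied slightly
#' across taxa; they are illustrative defaults, not estimates.
#'
#' @param base_rate expected community-wide sequences per site-night;
#'   default 170, the reference campaign's mean per detector-night.
#' @return a [community_config()].
#' @export
default_community <- function(base_rate = 170) {
  taxa <- survey_reference_counts()$taxa
  w <- taxa$total / sum(taxa$total)
  w <- w / sum(w)
  aff <- 3 * cbind(GROUND = taxa$ground, CANOPY = taxa$canopy, GAP = taxa$gap) / taxa$total
  rownames(aff) <- taxa$taxon
  k <- nrow(taxa)
  jitter <- (seq_len(k) - 1) %% 4 * 5
  guild_peak1 <- c(SRE = 90, MRE = 45, LRE = 60)[taxa$guild]
  guild_peak2 <- c(SRE = 360, MRE = 400, LRE = 380)[taxa$guild]
  activity <- data.frame(
    peak1_time = guild_peak1 + jitter,
    peak1_sd = 55,
    peak2_time = guild_peak2 + jitter,
    peak2_sd = 60,
    peak1_weight = c(SRE = 0.60, MRE = 0.70, LRE = 0.65)[taxa$guild]
  )
  community_config(taxa = taxa$taxon, abundance_weights = w, guilds = taxa$guild,
                   affinity = aff, activity = activity, base_rate = base_rate,
                   taxon_levels = taxa$level)
}

# truncated-normal draw on [0, 480) via inverse-CDF
rtrunc_night <- function(n, mu, sd) {
  lo <- stats::pnorm(0, mu, sd)
  hi <- stats::pnorm(NIGHT_MINUTES, mu, sd)
  x <- stats::qnorm(stats::runif(n, lo, hi), mu, sd)
  pmin(pmax(x, 0), NIGHT_MINUTES - 1e-6)
}

#' Expected sequence counts per site-night
#'
#' Closed-form means of the generator - the oracle against which
#' [simulate_survey()] is checked. For species `s` at microhabitat `m` the
#' per-site-night expectation is
#' `base_rate * abundance_weight[s] * affinity[s, m]`, independent of night.
#'
#' @param community a [community_config()].
#' @param layout optional [survey_layout()]; when given, the attribute
#'   `plot_night_total` holds the expected sequences per plot and night
#'   (summed over the plot's three microhabitat sites), the quantity that
#'   plays the role of the cost model's mean sequences per night-plot.
#' @return data frame (taxon, guild, microhabitat, expected) with attribute
#'   `plot_night_total`.
#' @export
expected_counts <- function(community, layout = NULL) {
  lam <- community$base_rate * community$abundance_weights * community$affinity
  out <- data.frame(
    taxon = rep(community$taxa, times = 3),
    guild = rep(community$guilds, times = 3),
    microhabitat = rep(BAT_MICROHABITATS, each = length(community$taxa)),
    expected = c(lam[, "GROUND"], lam[, "CANOPY"], lam[, "GAP"]),
    stringsAsFactors = FALSE
  )
  attr(out, "plot_night_total") <- sum(lam)
  out
}

#' Simulate a passive acoustic survey
#'
#' Draws detection records for every site (cell x plot x microhabitat) and
#' night under the community's Poisson rate model; timestamps follow each
#' species' two-peak truncated-Gaussian night profile. Byte-identical output
#' for identical seed and configuration.
#'
#' @param community a [community_config()].
#' @param layout a [survey_layout()].
#' @param seed RNG seed; `NULL` uses the session RNG state.
#' @param night_effect optional function `(cell_id, night_index) -> rate
#'   multiplier`, a hook for night-level covariates such as temperature;
#'   default none.
#' @return a `bat_records` data frame.
#' @export
simulate_survey <- function(community, layout = survey_layout(), seed = NULL,
                            night_effect = NULL) {
  set_seed_if(seed)
  cells <- sprintf("cell%02d", seq_len(layout$n_cells))
  night_choices <- seq(layout$nights_min, layout$nights_max)
  nights_per_cell <- if (length(night_choices) == 1) {
    rep(night_choices, layout$n_cells) # guard against sample()'s scalar trap
  } else {
    sample(night_choices, layout$n_cells, replace = TRUE)
  }
  plots <- sprintf("p%d", seq_len(layout$plots_per_cell))

  grid <- do.call(rbind, lapply(seq_along(cells), function(ci) {
    nights <- sprintf("%s_n%02d", cells[ci], seq_len(nights_per_cell[ci]))
    g <- expand.grid(night_id = nights, plot_id = plots,
                     microhabitat = BAT_MICROHABITATS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$cell_id <- cells[ci]
    g$night_index <- as.integer(sub(".*_n", "", g$night_id))
    g
  }))
  grid$site_id <- paste(grid$cell_id, grid$plot_id,
                        tolower(.mh_code[grid$microhabitat]), sep = "_")
  mult <- if (is.null(night_effect)) {
    rep(1, nrow(grid))
  } else {
    mapply(night_effect, grid$cell_id, grid$night_index)
  }

  pieces <- vector("list", length(community$taxa))
  mh_idx <- match(grid$microhabitat, BAT_MICROHABITATS)
  for (s in seq_along(community$taxa)) {
    lam <- community$base_rate * community$abundance_weights[s] *
      community$affinity[s, ][mh_idx] * mult
    counts <- stats::rpois(nrow(grid), lam)
    tot <- sum(counts)
    if (tot == 0) next
    idx <- rep.int(seq_len(nrow(grid)), counts)
    act <- community$activity[s, ]
    first <- stats::runif(tot) < act$peak1_weight
    ts <- numeric(tot)
    ts[first] <- rtrunc_night(sum(first), act$peak1_time, act$peak1_sd)
    ts[!first] <- rtrunc_night(sum(!first), act$peak2_time, act$peak2_sd)
    pieces[[s]] <- data.frame(
      night_id = grid$night_id[idx], timestamp = ts,
      cell_id = grid$cell_id[idx], plot_id = grid$plot_id[idx],
      site_id = grid$site_id[idx], microhabitat = grid$microhabitat[idx],
      taxon = community$taxa[s], taxon_level = community$taxon_levels[s],
      guild = community$guilds[s],
      n_calls = 1L + stats::rpois(tot, 13),
      stringsAsFactors = FALSE
    )
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) {
    df <- data.frame(night_id = character(), timestamp = numeric(),
                     cell_id = character(), plot_id = character(),
                     site_id = character(), microhabitat = character(),
                     taxon = character(), taxon_level = character(),
                     guild = character(), n_calls = integer(),
                     stringsAsFactors = FALSE)
    return(as_bat_records(df))
  }
  df <- do.call(rbind, pieces)
  ord <- order(df$cell_id, df$night_id, df$plot_id, df$microhabitat,
               df$timestamp, df$taxon, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df <- as_bat_records(df)
  attr(df, "nights_per_cell") <- stats::setNames(nights_per_cell, cells)
  df
}
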