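#' Vocabulary used throughout the package
#'
#' Canonical category labels for detection records. Every recording night is
#' an 8-h window (21:30 to 05:30) indexed in minutes from its start, so valid
#' timestamps lie in `[0, 480)`.
#'
#' * `BAT_MICROHABITATS`: the three sampling strata of a forest plot -
#'   forest ground (`GROUND`), upper canopy (`CANOPY`), forest gap (`GAP`).
#' * `BAT_PATTERNS`: within-night recording patterns - the full 8-h night
#'   (`FULL_NIGHT`), the first 4 h after sunset (`FIRST_4H`), or 2 h after
#'   sunset plus 2 h before sunrise (`SPLIT_2H_2H`).
#' * `BAT_TAXON_LEVELS`: identification levels, best to coarsest.
#' * `BAT_GUILDS`: echolocation guilds - short-, middle-, long-range
#'   echolocators; `UNKNOWN` for sequences not assignable to a guild.
#'
#' @name vocabulary
#' @aliases BAT_MICROHABITATS BAT_PATTERNS BAT_TAXON_LEVELS BAT_GUILDS
NULL

#' @export
BAT_MICROHABITATS <- c("GROUND", "CANOPY", "GAP")
#' @export
BAT_PATTERNS <- c("FULL_NIGHT", "FIRST_4H", "SPLIT_2H_2H")
#' @export
BAT_TAXON_LEVELS <- c("SPECIES", "SPECIES_GROUP", "GENUS", "GENUS_GROUP", "ORDER")
#' @export
BAT_GUILDS <- c("SRE", "MRE", "LRE", "UNKNOWN")

# minutes in the nightly recording window
NIGHT_MINUTES <- 480
NIGHT_START_MIN <- 21 * 60 + 30 # 21:30 as minutes-of-day

# short field codes accepted as synonyms in input files
.mh_synonyms <- c(
  GROUND = "GROUND", GR = "GROUND", "FOREST GROUND" = "GROUND",
  CANOPY = "CANOPY", CA = "CANOPY",
  GAP = "GAP", GA = "GAP", "FOREST GAP" = "GAP"
)

normalize_microhabitat <- function(x) {
  key <- toupper(trimws(as.character(x)))
  key <- gsub("[_-]", " ", key)
  out <- unname(.mh_synonyms[key])
  out
}

#' Half-open time windows of a temporal sampling pattern
#'
#' @param pattern one of [BAT_PATTERNS].
#' @return two-column matrix of `[start, end)` windows in minutes from 21:30.
#' @export
pattern_windows <- function(pattern) {
  pattern <- match.arg(pattern, BAT_PATTERNS)
  switch(pattern,
    FULL_NIGHT  = matrix(c(0, NIGHT_MINUTES), 1, 2),
    FIRST_4H    = matrix(c(0, 240), 1, 2),
    SPLIT_2H_2H = matrix(c(0, 120, 360, NIGHT_MINUTES), 2, 2, byrow = TRUE)
  )
}

record_columns <- c(
  "night_id", "timestamp", "cell_id", "plot_id", "site_id",
  "microhabitat", "taxon", "taxon_level", "guild", "n_calls"
)

#' Construct and validate a set of detection records
#'
#' A detection record is one identified echolocation call sequence (one bat
#' pass) with spatial, temporal and taxonomic attributes. Records are kept in
#' an ordinary data frame of class `bat_records`.
#'
#' @param df data frame with columns `night_id`, `timestamp` (minutes from
#'   21:30, in `[0, 480)`), `cell_id`, `plot_id`, `site_id`, `microhabitat`,
#'   `taxon`, `taxon_level`; optionally `guild` and `n_calls`.
#' @return the validated data frame with class `bat_records`.
#' @export
as_bat_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(setdiff(record_columns, c("guild", "n_calls")), names(df))
  if (length(missing_cols) > 0) {
    abort("missing record column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$guild)) df$guild <- rep("UNKNOWN", nrow(df))
  if (is.null(df$n_calls)) df$n_calls <- rep(NA_integer_, nrow(df))
  for (col in c("night_id", "cell_id", "plot_id", "site_id", "microhabitat",
                "taxon", "taxon_level", "guild")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$timestamp <- as.numeric(df$timestamp)
  df <- df[, record_columns, drop = FALSE]
  validate_records(df)
  class(df) <- c("bat_records", "data.frame")
  df
}

validate_records <- function(df) {
  bad_t <- which(!is.finite(df$timestamp) | df$timestamp < 0 | df$timestamp >= NIGHT_MINUTES)
  if (length(bad_t) > 0) {
    abort("timestamp outside [0, %d) in row(s): %s", NIGHT_MINUTES,
          paste(utils::head(bad_t, 5), collapse = ", "))
  }
  bad_mh <- which(!(df$microhabitat %in% BAT_MICROHABITATS))
  if (length(bad_mh) > 0) {
    abort("invalid microhabitat in row(s): %s", paste(utils::head(bad_mh, 5), collapse = ", "))
  }
  bad_lv <- which(!(df$taxon_level %in% BAT_TAXON_LEVELS))
  if (length(bad_lv) > 0) {
    abort("invalid taxon_level in row(s): %s", paste(utils::head(bad_lv, 5), collapse = ", "))
  }
  bad_g <- which(!(df$guild %in% BAT_GUILDS))
  if (length(bad_g) > 0) {
    abort("invalid guild in row(s): %s", paste(utils::head(bad_g, 5), collapse = ", "))
  }
  # guild should be UNKNOWN only for order-level sequences
  odd <- df$guild == "UNKNOWN" & df$taxon_level != "ORDER"
  if (any(odd)) {
    warning(sprintf("%d record(s) below ORDER level have guild UNKNOWN; they are excluded from guild summaries", sum(odd)),
            call. = FALSE)
  }
  invisible(TRUE)
}

# "HH:MM" or "HH:MM:SS" clock time -> minutes from 21:30 (nights wrap midnight);
# numeric strings pass through as minutes. Returns NA where unparseable.
parse_night_time <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  numeric_like <- grepl("^[0-9]+(\\.[0-9]+)?$", x)
  out[numeric_like] <- as.numeric(x[numeric_like])
  clock <- grepl("^[0-9]{1,2}:[0-9]{2}(:[0-9]{2})?$", x)
  if (any(clock)) {
    parts <- strsplit(x[clock], ":", fixed = TRUE)
    mins <- vapply(parts, function(p) {
      h <- as.numeric(p[1]); m <- as.numeric(p[2])
      s <- if (length(p) == 3) as.numeric(p[3]) else 0
      if (h >= 24 || m >= 60 || s >= 60) return(NA_real_)
      h * 60 + m + s / 60
    }, numeric(1))
    rel <- mins - NIGHT_START_MIN
    rel[!is.na(rel) & rel < 0] <- rel[!is.na(rel) & rel < 0] + 24 * 60
    out[clock] <- rel
  }
  out
}

default_column_map <- c(
  night_id = "night", timestamp = "time", cell_id = "cell", plot_id = "plot",
  site_id = "site", microhabitat = "microhabitat", taxon = "taxon",
  taxon_level = "level", guild = "guild", n_calls = "n_calls"
)

#' Read detection records from a delimited text file
#'
#' Expects a header naming (by default) `night`, `time`, `cell`, `plot`,
#' `site`, `microhabitat`, `taxon`, `level`, and optionally `guild` and
#' `n_calls`. Clock times (`"HH:MM"` or `"HH:MM:SS"`) are converted to
#' minutes from 21:30, wrapping past midnight; numeric times are taken as
#' minutes directly. Rows with timestamps outside the 8-h recording window
#' are rejected with a line-numbered warning (or an error if `strict`).
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param col_map named character vector mapping internal field names to the
#'   file's column names; defaults cover the conventional names above.
#' @param strict if `TRUE`, out-of-window timestamps are an error rather than
#'   a dropped row.
#' @param guild_table named character vector `taxon -> guild` used when the
#'   file carries no guild column; defaults to [default_guild_table()].
#' @return a [as_bat_records()] data frame.
#' @export
read_records <- function(path, sep = NULL, col_map = NULL, strict = FALSE,
                         guild_table = default_guild_table()) {
  if (!file.exists(path)) abort("records file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  map <- default_column_map
  if (!is.null(col_map)) map[names(col_map)] <- col_map

  required <- setdiff(names(map), c("guild", "n_calls"))
  missing_cols <- required[!(map[required] %in% names(raw))]
  if (length(missing_cols) > 0) {
    abort("format error: missing required column(s) %s in %s",
          paste(sprintf("'%s'", map[missing_cols]), collapse = ", "), path)
  }
  line_no <- seq_len(nrow(raw)) + 1L # header is line 1

  df <- data.frame(
    night_id = as.character(raw[[map["night_id"]]]),
    timestamp = parse_night_time(raw[[map["timestamp"]]]),
    cell_id = as.character(raw[[map["cell_id"]]]),
    plot_id = as.character(raw[[map["plot_id"]]]),
    site_id = as.character(raw[[map["site_id"]]]),
    microhabitat = normalize_microhabitat(raw[[map["microhabitat"]]]),
    taxon = trimws(as.character(raw[[map["taxon"]]])),
    taxon_level = toupper(trimws(as.character(raw[[map["taxon_level"]]]))),
    stringsAsFactors = FALSE
  )
  if (map["guild"] %in% names(raw)) {
    df$guild <- toupper(trimws(as.character(raw[[map["guild"]]])))
  } else {
    df$guild <- unname(guild_table[df$taxon])
    df$guild[is.na(df$guild)] <- "UNKNOWN"
    df$guild[df$taxon_level == "ORDER"] <- "UNKNOWN"
  }
  df$n_calls <- if (map["n_calls"] %in% names(raw)) {
    as.integer(raw[[map["n_calls"]]])
  } else NA_integer_

  bad <- is.na(df$microhabitat)
  if (any(bad)) {
    abort("format error: missing or invalid microhabitat at line(s) %s",
          paste(utils::head(line_no[bad], 10), collapse = ", "))
  }
  bad <- !(df$taxon_level %in% BAT_TAXON_LEVELS)
  if (any(bad)) {
    abort("format error: invalid identification level at line(s) %s",
          paste(utils::head(line_no[bad], 10), collapse = ", "))
  }
  bad <- is.na(df$timestamp)
  if (any(bad)) {
    abort("format error: unparseable time at line(s) %s",
          paste(utils::head(line_no[bad], 10), collapse = ", "))
  }
  outside <- df$timestamp < 0 | df$timestamp >= NIGHT_MINUTES
  if (any(outside)) {
    msg <- sprintf("%d row(s) with timestamps outside the 21:30-05:30 window (line(s) %s)",
                   sum(outside), paste(utils::head(line_no[outside], 10), collapse = ", "))
    if (strict) abort("%s", msg)
    warning(paste(msg, "- dropped"), call. = FALSE)
    df <- df[!outside, , drop = FALSE]
  }
  as_bat_records(df)
}

#' Write detection records back to delimited text
#'
#' Inverse of [read_records()] under the default column names.
#'
#' @param records a `bat_records` data frame.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_records <- function(records, path, sep = ",") {
  out <- data.frame(
    night = records$night_id, time = records$timestamp, cell = records$cell_id,
    plot = records$plot_id, site = records$site_id,
    microhabitat = records$microhabitat, taxon = records$taxon,
    level = records$taxon_level, guild = records$guild, n_calls = records$n_calls,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default grouping of acoustically similar congeners
#'
#' Species whose echolocation calls cannot reliably be told apart are pooled
#' into a single taxon for richness analyses: the two *Plecotus*, the two
#' large *Nyctalus*, and the two *Eptesicus* species of central Europe.
#'
#' @return named list: group label -> member species.
#' @export
default_taxon_groups <- function() {
  list(
    "Plecotus sp."  = c("Plecotus auritus", "Plecotus austriacus"),
    "Nyctalus sp."  = c("Nyctalus noctula", "Nyctalus leisleri"),
    "Eptesicus sp." = c("Eptesicus serotinus", "Eptesicus nilssoni")
  )
}

#' Collapse acoustically indistinguishable species into group taxa
#'
#' Each group counts as one taxon downstream; collapsed rows get
#' `taxon_level = "SPECIES_GROUP"`. Idempotent: group labels map to
#' themselves.
#'
#' @param records `bat_records`.
#' @param groups grouping as returned by [default_taxon_groups()].
#' @return records with taxa relabelled.
#' @export
collapse_taxa <- function(records, groups = default_taxon_groups()) {
  map <- unlist(lapply(names(groups), function(g) {
    stats::setNames(rep(g, length(groups[[g]])), groups[[g]])
  }))
  hit <- records$taxon %in% names(map)
  records$taxon[hit] <- unname(map[records$taxon[hit]])
  records$taxon_level[hit] <- "SPECIES_GROUP"
  records
}

#' Filter records to a temporal sampling pattern
#'
#' Keeps records whose timestamp falls in one of the pattern's half-open
#' windows: `FULL_NIGHT` keeps `[0, 480)`, `FIRST_4H` keeps `[0, 240)`, and
#' `SPLIT_2H_2H` keeps `[0, 120) U [360, 480)`.
#'
#' @param records `bat_records`.
#' @param pattern one of [BAT_PATTERNS].
#' @return the matching subset, same class.
#' @export
filter_temporal <- function(records, pattern) {
  w <- pattern_windows(pattern)
  keep <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(w))) {
    keep <- keep | (records$timestamp >= w[i, 1] & records$timestamp < w[i, 2])
  }
  records[keep, , drop = FALSE]
}

#' Filter records to a spatial sampling design
#'
#' @param records `bat_records`.
#' @param design nonempty subset of [BAT_MICROHABITATS]; short codes
#'   `GR`/`CA`/`GA` are accepted.
#' @return records at the design's microhabitats.
#' @export
filter_design <- function(records, design) {
  design <- normalize_microhabitat(design)
  if (length(design) == 0 || anyNA(design)) {
    abort("`design` must be a nonempty subset of {%s}", paste(BAT_MICROHABITATS, collapse = ", "))
  }
  records[records$microhabitat %in% design, , drop = FALSE]
}

#' Summarise identification success by level and taxon
#'
#' Two tables, following the usual reporting conventions:
#' * per identification level, counts and the percentage of the grand total
#'   (half-up, 1 decimal);
#' * per taxon, counts and the percentage of the guild-assignable total, i.e.
#'   excluding rows with guild `UNKNOWN` (half-up, 2 decimals).
#'
#' Accepts either one row per sequence or pre-aggregated counts through a
#' multiplicity column (`count_col`), so published count tables can be fed
#' in directly.
#'
#' @param records data frame with at least `taxon`, `taxon_level` and
#'   (ideally) `guild`; a full `bat_records` works. When there is no guild
#'   column, every row below ORDER level counts as guild-assignable.
#' @param count_col name of an optional multiplicity column.
#' @return an `identification_summary`: list with elements `levels`, `taxa`,
#'   `total`, `n_guild_assignable`.
#' @export
summarize_identification <- function(records, count_col = "n") {
  n <- if (count_col %in% names(records)) as.numeric(records[[count_col]]) else rep(1, nrow(records))
  total <- sum(n)
  if (total == 0) {
    out <- list(levels = data.frame(level = character(), n = numeric(), pct = numeric()),
                taxa = data.frame(taxon = character(), n = numeric(), pct = numeric()),
                total = 0, n_guild_assignable = 0)
    class(out) <- "identification_summary"
    return(out)
  }
  lv <- stats::aggregate(list(n = n), by = list(level = records$taxon_level), FUN = sum)
  lv <- lv[order(match(lv$level, BAT_TAXON_LEVELS)), , drop = FALSE]
  lv$pct <- round_half_up(100 * lv$n / total, 1)

  assignable <- if ("guild" %in% names(records)) {
    records$guild != "UNKNOWN"
  } else {
    records$taxon_level != "ORDER"
  }
  tx <- data.frame(taxon = records$taxon[assignable], n = n[assignable],
                   stringsAsFactors = FALSE)
  n_assign <- sum(tx$n)
  if (nrow(tx) > 0) {
    tx <- stats::aggregate(n ~ taxon, data = tx, FUN = sum)
    tx$pct <- round_half_up(100 * tx$n / n_assign, 2)
    tx <- tx[order(-tx$n, tx$taxon), , drop = FALSE]
    rownames(tx) <- NULL
  } else {
    tx <- data.frame(taxon = character(), n = numeric(), pct = numeric())
  }
  rownames(lv) <- NULL
  out <- list(levels = lv, taxa = tx, total = total, n_guild_assignable = n_assign)
  class(out) <- "identification_summary"
  out
}

#' @export
print.identification_summary <- function(x, ...) {
  cat(sprintf("Identification summary: %s sequences, %s assignable to a guild\n",
              format(x$total, big.mark = ","), format(x$n_guild_assignable, big.mark = ",")))
  cat("\nBy identification level (% of all sequences):\n")
  print(x$levels, row.names = FALSE)
  cat("\nBy taxon (% of guild-assignable sequences):\n")
  print(utils::head(x$taxa, 10), row.names = FALSE)
  if (nrow(x$taxa) > 10) cat(sprintf("  ... and %d more taxa\n", nrow(x$taxa) - 10))
  invisible(x)
}
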