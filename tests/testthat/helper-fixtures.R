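# Small programmatic fixtures shared across the suite.

# Quick detection-record builder with recycling.
make_records <- function(timestamp, taxon = "Myotis myotis", guild = "SRE",
                         level = "SPECIES", microhabitat = "GAP",
                         night = "n1", cell = "c1", plot = "p1",
                         site = NULL) {
  n <- if (length(timestamp) == 0) 0 else max(lengths(list(timestamp, taxon, microhabitat, night)))
  df <- data.frame(
    night_id = rep_len(night, n), timestamp = rep_len(timestamp, n),
    cell_id = rep_len(cell, n), plot_id = rep_len(plot, n),
    site_id = rep_len(site %||% paste0(rep_len(cell, n), "_", rep_len(plot, n), "_",
                                       tolower(rep_len(microhabitat, n))), n),
    microhabitat = rep_len(microhabitat, n), taxon = rep_len(taxon, n),
    taxon_level = rep_len(level, n), guild = rep_len(guild, n),
    stringsAsFactors = FALSE
  )
  as_bat_records(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap a bare 0/1 matrix (taxa x nights) as an incidence matrix.
toy_incidence <- function(m) {
  dimnames(m) <- list(if (nrow(m) > 0) paste0("taxon", seq_len(nrow(m))),
                      if (ncol(m) > 0) paste0("night", seq_len(ncol(m))))
  out <- list(presence = m, taxa = rownames(m), nights = colnames(m),
              scheme = sampling_scheme("GAP", "FULL_NIGHT"), unit = "toy")
  class(out) <- "incidence_matrix"
  out
}

# Write a records CSV in the default input format.
write_records_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("night,time,cell,plot,site,microhabitat,taxon,level", lines), path)
  path
}

# Brute-force activity oracle: scan all 96 bins.
brute_activity <- function(timestamps) {
  sum(vapply(0:95, function(k) any(timestamps >= 5 * k & timestamps < 5 * (k + 1)),
             logical(1)))
}

# Small community for simulator-dependent tests: bimodal activity, one
# canopy-avoider, moderate rates.
toy_community <- function(base_rate = 40) {
  aff <- matrix(1, 4, 3, dimnames = list(NULL, c("GROUND", "CANOPY", "GAP")))
  aff[2, "CANOPY"] <- 0
  act <- data.frame(peak1_time = c(50, 70, 90, 60), peak1_sd = 50,
                    peak2_time = c(400, 380, 360, 420), peak2_sd = 55,
                    peak1_weight = c(0.7, 0.65, 0.6, 0.65))
  community_config(taxa = paste0("species", 1:4),
                   abundance_weights = c(0.5, 0.25, 0.15, 0.1),
                   guilds = c("MRE", "SRE", "LRE", "SRE"),
                   affinity = aff, activity = act, base_rate = base_rate)
}
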