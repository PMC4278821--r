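#' Build a taxon-by-night incidence matrix for a sampling unit
#'
#' Applies the scheme's spatial and temporal filters to the unit's records,
#' then marks presence per (taxon, night) pooled over the unit's sites.
#' Night is the effort unit: the night set is fixed *before* filtering, so a
#' sampled night whose detections are all filtered out (or that recorded no
#' bats at all) is kept as an all-zero column - a detector-night with no
#' bats is still effort.
#'
#' @param records `bat_records`, already taxon-collapsed (see
#'   [collapse_taxa()]).
#' @param scheme a [sampling_scheme()].
#' @param cell,plot optional unit selectors; give `cell` alone for a
#'   cell-level unit, `cell` + `plot` (or `plot` alone if plot ids are
#'   globally unique) for a plot-level unit.
#' @param nights optional explicit night set, for units whose effort is
#'   known independently of the records.
#' @return object of class `incidence_matrix`: list with `presence`
#'   (binary taxa x nights matrix), `taxa`, `nights`, `scheme`, `unit`.
#' @export
build_incidence <- function(records, scheme, cell = NULL, plot = NULL,
                            nights = NULL) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  unit <- records
  if (!is.null(cell)) unit <- unit[unit$cell_id %in% cell, , drop = FALSE]
  if (!is.null(plot)) unit <- unit[unit$plot_id %in% plot, , drop = FALSE]
  if (is.null(nights)) nights <- sort(unique(unit$night_id))
  if (length(nights) == 0) abort("sampling unit has no sampled nights")

  kept <- filter_temporal(filter_design(unit, scheme$design), scheme$pattern)
  taxa <- sort(unique(kept$taxon))
  presence <- matrix(0L, nrow = length(taxa), ncol = length(nights),
                     dimnames = list(taxa, nights))
  if (nrow(kept) > 0) {
    tab <- table(factor(kept$taxon, levels = taxa),
                 factor(kept$night_id, levels = nights))
    presence[] <- as.integer(tab > 0)
  }
  out <- list(presence = presence, taxa = taxa, nights = as.character(nights),
              scheme = scheme,
              unit = paste(c(cell, plot), collapse = "/"))
  class(out) <- "incidence_matrix"
  out
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("Incidence matrix: %d taxa x %d nights (%s%s)\n",
              length(x$taxa), length(x$nights), format(x$scheme),
              if (nzchar(x$unit)) paste0(", unit ", x$unit) else ""))
  invisible(x)
}

as_curve <- function(effort, mean_richness, sd_richness, n_perm, method) {
  out <- data.frame(effort = effort, mean_richness = mean_richness,
                    sd_richness = sd_richness)
  attr(out, "n_permutations") <- n_perm
  attr(out, "method") <- method
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Species accumulation curve by permutation resampling
#'
#' Randomises the order in which the unit's nights are accumulated and
#' records, for each permutation, the cumulative number of distinct taxa
#' after 1, 2, ... T nights. The mean over permutations is the rarefaction
#' curve; the spread quantifies order dependence. Randomising the order
#' removes order-specific bias (seasonal drift, weather runs) and smooths
#' the curve.
#'
#' @param incidence an [build_incidence()] matrix.
#' @param n_perm number of random orderings (default 1000).
#' @param seed RNG seed for reproducibility.
#' @return an `accumulation_curve` data frame (effort, mean_richness,
#'   sd_richness) with attribute `n_permutations`.
#' @export
accumulation_permuted <- function(incidence, n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 1)
  set_seed_if(seed)
  m <- incidence$presence
  T <- ncol(m)
  detected <- rowSums(m) > 0
  rich <- matrix(0L, nrow = n_perm, ncol = T)
  if (any(detected)) {
    md <- m[detected, , drop = FALSE]
    for (k in seq_len(n_perm)) {
      p <- sample.int(T)
      # first night (in permuted order) on which each taxon appears
      first <- max.col(md[, p, drop = FALSE], ties.method = "first")
      rich[k, ] <- cumsum(tabulate(first, nbins = T))
    }
  }
  sds <- if (n_perm > 1) apply(rich, 2, stats::sd) else rep(0, T)
  as_curve(seq_len(T), colMeans(rich), sds, n_perm, "permutation")
}

#' Exact expected species accumulation curve
#'
#' Closed-form expectation of the permutation estimator over all night
#' orderings. A taxon present on `n_i` of the `T` nights is missing from a
#' random subset of `t` nights with probability `C(T - n_i, t) / C(T, t)`
#' (hypergeometric inclusion), so
#' `E[S(t)] = sum_i (1 - C(T - n_i, t) / C(T, t))`. The standard deviation
#' over orderings follows from the pairwise joint absence probabilities,
#' which depend on the night-set unions of taxon pairs.
#'
#' @param incidence an [build_incidence()] matrix.
#' @return an `accumulation_curve` data frame (exact mean and sd).
#' @export
accumulation_exact <- function(incidence) {
  m <- incidence$presence
  T <- ncol(m)
  t <- seq_len(T)
  if (nrow(m) == 0) return(as_curve(t, rep(0, T), rep(0, T), NA, "exact"))
  n_i <- rowSums(m)
  # q_i(t): probability taxon i is absent from a random t-night subset
  q <- vapply(t, function(tt) exp(lchoose(T - n_i, tt) - lchoose(T, tt)),
              numeric(nrow(m)))
  q <- matrix(q, nrow = nrow(m))
  mean_rich <- colSums(1 - q)

  inter <- m %*% t(m)
  u <- outer(n_i, n_i, "+") - inter # |N_i union N_j|
  var_rich <- vapply(t, function(tt) {
    qi <- q[, tt]
    qij <- exp(lchoose(T - u, tt) - lchoose(T, tt))
    both <- 1 - outer(qi, rep(1, length(qi))) - outer(rep(1, length(qi)), qi) + qij
    diag(both) <- 1 - qi
    sum(both) - sum(1 - qi)^2
  }, numeric(1))
  as_curve(t, mean_rich, sqrt(pmax(0, var_rich)), NA, "exact")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("Accumulation curve (%s%s): richness %.2f after %d nights\n",
              attr(x, "method"),
              if (!is.na(attr(x, "n_permutations") %||% NA)) {
                sprintf(", %d permutations", attr(x, "n_permutations"))
              } else "",
              x$mean_richness[nrow(x)], nrow(x)))
  NextMethod()
}

#' Plot an accumulation curve
#'
#' Mean richness against effort with a +/- 1 sd envelope, optionally
#' overlaying the fitted Clench curve.
#'
#' @param x an `accumulation_curve`.
#' @param fit optional [fit_clench()] result to overlay.
#' @param ... passed to [plot()].
#' @export
plot.accumulation_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$effort, x$mean_richness, type = "b", pch = 16,
                 xlab = "Sampling effort (nights)", ylab = "Taxa detected",
                 ylim = c(0, max(x$mean_richness + x$sd_richness) * 1.05), ...)
  graphics::arrows(x$effort, x$mean_richness - x$sd_richness,
                   x$effort, x$mean_richness + x$sd_richness,
                   angle = 90, code = 3, length = 0.03, col = "grey50")
  if (!is.null(fit)) {
    tt <- seq(0, max(x$effort), length.out = 200)
    graphics::lines(tt, clench_predict(fit$a, fit$b, tt), lty = 2)
  }
  invisible(x)
}
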