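test_that("identical seed and configuration give identical surveys", {
  lay <- survey_layout(n_cells = 2, plots_per_cell = 2, nights_min = 4, nights_max = 7)
  a <- simulate_survey(toy_community(), lay, seed = 11)
  b <- simulate_survey(toy_community(), lay, seed = 11)
  expect_identical(a, b)
  c <- simulate_survey(toy_community(), lay, seed = 12)
  expect_false(identical(a, c))
})

test_that("zero base rate yields an empty but valid survey", {
  r <- simulate_survey(toy_community(base_rate = 0), survey_layout(1, 1, 3, 3), seed = 1)
  expect_s3_class(r, "bat_records")
  expect_equal(nrow(r), 0)
})

test_that("zero affinity is a structural absence", {
  r <- simulate_survey(toy_community(), survey_layout(2, 2, 6, 6), seed = 3)
  expect_equal(sum(r$taxon == "species2" & r$microhabitat == "CANOPY"), 0)
  expect_gt(sum(r$taxon == "species2"), 0)
})

test_that("empirical detection shares converge to the configured weights", {
  # uniform affinity and equal site exposure make the expected share equal
  # the abundance weight exactly; binomial 3-sigma bound on the dominant one
  com <- default_community()
  r <- simulate_survey(com, survey_layout(n_cells = 1, plots_per_cell = 4,
                                          nights_min = 10, nights_max = 10),
                       seed = 7)
  n <- nrow(r)
  expect_gt(n, 10000)
  p_hat <- mean(r$taxon == "Pipistrellus pipistrellus")
  p <- com$abundance_weights[match("Pipistrellus pipistrellus", com$taxa)]
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
  expect_gt(p, 0.87) # the default community is dominance-structured
})

test_that("expected_counts is the closed-form oracle of the generator", {
  aff <- matrix(1, 1, 3, dimnames = list(NULL, c("GROUND", "CANOPY", "GAP")))
  act <- data.frame(peak1_time = 60, peak1_sd = 50, peak2_time = 400,
                    peak2_sd = 55, peak1_weight = 0.7)
  com <- community_config("solo", 1, "SRE", aff, act, base_rate = 5)
  ec <- expected_counts(com)
  expect_equal(ec$expected, rep(5, 3))
  expect_equal(attr(ec, "plot_night_total"), 15)

  # Monte-Carlo agreement: mean count per site-night within 3 SE of 5
  r <- simulate_survey(com, survey_layout(1, 1, 300, 300), seed = 21)
  n_site_nights <- 3 * 300
  m <- nrow(r) / n_site_nights
  se <- sqrt(5 / n_site_nights) # Poisson
  expect_lt(abs(m - 5), 3 * se)
})

test_that("plot-level expectation matches the summed per-site expectations", {
  com <- toy_community()
  ec <- expected_counts(com)
  expect_equal(attr(ec, "plot_night_total"), sum(ec$expected))
  # empirical check at the plot level
  r <- simulate_survey(com, survey_layout(1, 1, 200, 200), seed = 5)
  per_night <- nrow(r) / 200
  se <- sqrt(sum(ec$expected) / 200)
  expect_lt(abs(per_night - sum(ec$expected)), 3 * se)
})

test_that("bimodal species are under-detected by first-4h sampling", {
  r <- simulate_survey(toy_community(base_rate = 100),
                       survey_layout(1, 2, 10, 10), seed = 9)
  for (sp in unique(r$taxon)) {
    rs <- r[r$taxon == sp, ]
    expect_lt(nrow(filter_temporal(rs, "FIRST_4H")), nrow(rs))
  }
})

test_that("night-effect hook scales rates", {
  com <- toy_community(base_rate = 50)
  lay <- survey_layout(1, 2, 8, 8)
  full <- simulate_survey(com, lay, seed = 13)
  halved <- simulate_survey(com, lay, seed = 13,
                            night_effect = function(cell, night) 0.5)
  expect_lt(nrow(halved), nrow(full))
})

test_that("community configuration is validated", {
  aff <- matrix(1, 2, 3)
  act <- data.frame(peak1_time = c(60, 70), peak1_sd = 50,
                    peak2_time = c(400, 410), peak2_sd = 55, peak1_weight = 0.7)
  expect_error(community_config(c("a", "b"), c(0.6, 0.5), c("SRE", "MRE"),
                                aff, act, 10), "sum to 1")
  expect_error(community_config(c("a", "b"), c(0.5, 0.5), c("SRE", "MRE"),
                                aff, transform(act, peak2_time = c(400, 500)), 10),
               "peak times")
  expect_error(community_config(c("a", "b"), c(0.5, 0.5), c("SRE", "XXX"),
                                aff, act, 10), "guilds")
})
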