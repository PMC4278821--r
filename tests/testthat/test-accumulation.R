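test_that("incidence matrices pool sites, filter by scheme, and keep empty nights", {
  r <- make_records(c(30, 270, 100, 100),
                    night = c("n1", "n1", "n2", "n3"),
                    taxon = c("A", "B", "A", "A"),
                    microhabitat = c("GAP", "GAP", "GROUND", "CANOPY"))
  full <- build_incidence(r, sampling_scheme(c("GR", "CA", "GA"), "FULL_NIGHT"))
  expect_equal(dim(full$presence), c(2, 3))
  expect_equal(sum(full$presence), 4)

  # taxon detected only at 02:00 is present under FULL_NIGHT, absent under FIRST_4H
  first <- build_incidence(r, sampling_scheme(c("GR", "CA", "GA"), "FIRST_4H"))
  expect_true("B" %in% full$taxa)
  expect_false("B" %in% first$taxa)
  # the filtered-out night n1 of taxon B does not shrink the effort axis
  expect_equal(first$nights, c("n1", "n2", "n3"))

  # a GAP-only design never sees GROUND/CANOPY detections, but their nights
  # remain as all-zero effort columns
  gap <- build_incidence(r, sampling_scheme("GA", "FULL_NIGHT"))
  expect_equal(length(gap$nights), 3)
  expect_equal(unname(colSums(gap$presence)), c(2, 0, 0))

  expect_error(build_incidence(r[0, ], sampling_scheme("GA", "FULL_NIGHT")),
               "no sampled nights")
})

test_that("single ever-present taxon gives a flat curve at 1", {
  inc <- toy_incidence(matrix(1L, 1, 5))
  for (cur in list(accumulation_permuted(inc, 50, seed = 1), accumulation_exact(inc))) {
    expect_equal(cur$mean_richness, rep(1, 5))
    expect_equal(cur$sd_richness, rep(0, 5))
  }
})

test_that("exact curve matches the hand-enumerated 3-night case", {
  # one taxon present a single night: all 6 orderings give S = 1/3, 2/3, 1
  inc <- toy_incidence(matrix(c(1L, 0L, 0L), 1, 3))
  ex <- accumulation_exact(inc)
  expect_equal(ex$mean_richness, c(1 / 3, 2 / 3, 1))
  # variance of a Bernoulli(t/3) inclusion
  expect_equal(ex$sd_richness^2, c(2 / 9, 2 / 9, 0))
})

test_that("empty incidence gives an all-zero curve", {
  inc <- toy_incidence(matrix(integer(0), 0, 4))
  expect_equal(accumulation_exact(inc)$mean_richness, rep(0, 4))
  expect_equal(accumulation_permuted(inc, 10, seed = 1)$mean_richness, rep(0, 4))
})

test_that("exact mean agrees with the independent vegan implementation", {
  set.seed(77)
  for (i in 1:10) {
    m <- matrix(rbinom(60, 1, runif(1, 0.2, 0.8)), 10, 6)
    ex <- accumulation_exact(toy_incidence(m))
    ref <- suppressWarnings(vegan::specaccum(t(m), method = "exact"))
    expect_equal(ex$mean_richness, unname(ref$richness), tolerance = 1e-12)
  }
})

test_that("exact sd agrees with high-replication permutation", {
  set.seed(78)
  m <- matrix(rbinom(48, 1, 0.4), 8, 6)
  ex <- accumulation_exact(toy_incidence(m))
  pm <- accumulation_permuted(toy_incidence(m), 4000, seed = 79)
  # sd of cumulative richness over orderings, to Monte-Carlo accuracy
  expect_equal(pm$sd_richness, ex$sd_richness, tolerance = 0.05)
})

test_that("permutation estimator is unbiased for the exact expectation", {
  set.seed(80)
  m <- matrix(rbinom(30, 1, 0.5), 10, 3)
  ex <- accumulation_exact(toy_incidence(m))
  pm <- accumulation_permuted(toy_incidence(m), 1000, seed = 81)
  se <- ex$sd_richness / sqrt(1000)
  ok <- se == 0 | abs(pm$mean_richness - ex$mean_richness) <= 3 * se
  expect_true(all(ok))
  expect_equal(pm$mean_richness[3], ex$mean_richness[3]) # t = T is exact
})

test_that("curves are reproducible and properly shaped", {
  m <- matrix(rbinom(40, 1, 0.3), 8, 5)
  a <- accumulation_permuted(toy_incidence(m), 1, seed = 42)
  b <- accumulation_permuted(toy_incidence(m), 1, seed = 42)
  expect_identical(a, b)
  cur <- accumulation_permuted(toy_incidence(m), 200, seed = 43)
  expect_true(all(diff(cur$mean_richness) >= 0))
  expect_equal(cur$mean_richness[5], sum(rowSums(m) > 0))
  expect_equal(cur$sd_richness[5], 0)
})

test_that("richer designs dominate their sub-designs pointwise", {
  set.seed(90)
  r <- simulate_survey(toy_community(base_rate = 12), survey_layout(1, 1, 8, 8),
                       seed = 91)
  sub <- accumulation_exact(build_incidence(r, sampling_scheme("GA", "FULL_NIGHT")))
  sup <- accumulation_exact(build_incidence(r, sampling_scheme(c("GA", "GR"), "FULL_NIGHT")))
  expect_true(all(sup$mean_richness - sub$mean_richness >= -1e-12))
})

test_that("an added night confirming all detections never lowers the curve", {
  # note: an added *empty* night legitimately dilutes the expectation at
  # fixed effort t (it is extra effort with no return), so monotonicity in
  # nights holds only when the new night re-detects the known taxa
  set.seed(92)
  m <- matrix(rbinom(35, 1, 0.4), 7, 5)
  ex5 <- accumulation_exact(toy_incidence(m))
  m6 <- cbind(m, as.integer(rowSums(m) > 0))
  ex6 <- accumulation_exact(toy_incidence(m6))
  expect_true(all(ex6$mean_richness[1:5] - ex5$mean_richness >= -1e-12))
})
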