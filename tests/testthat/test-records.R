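test_that("clock times convert to minutes from the 21:30 window start", {
  path <- write_records_csv(c(
    "2013-06-04,21:30,c1,p1,s1,GAP,Myotis myotis,SPECIES",
    "2013-06-04,23:59,c1,p1,s1,GAP,Myotis myotis,SPECIES",
    "2013-06-04,00:00,c1,p1,s1,GR,Myotis myotis,SPECIES",
    "2013-06-04,05:29,c1,p1,s1,canopy,Myotis myotis,SPECIES",
    "2013-06-04,42.5,c1,p1,s1,GA,Myotis myotis,SPECIES"
  ))
  r <- read_records(path)
  expect_s3_class(r, "bat_records")
  expect_equal(r$timestamp, c(0, 149, 150, 479, 42.5))
  expect_equal(r$microhabitat, c("GAP", "GAP", "GROUND", "CANOPY", "GAP"))
  # guild derived from the packaged lookup when the file has no guild column
  expect_true(all(r$guild == "SRE"))
})

test_that("tab-delimited input is auto-detected", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("night", "time", "cell", "plot", "site", "microhabitat",
                       "taxon", "level"), collapse = "\t"),
               paste(c("n1", "22:00", "c1", "p1", "s1", "GAP",
                       "Pipistrellus pipistrellus", "SPECIES"), collapse = "\t")),
             path)
  r <- read_records(path)
  expect_equal(nrow(r), 1)
  expect_equal(r$timestamp, 30)
  expect_equal(r$guild, "MRE")
})

test_that("malformed input is rejected with line-level diagnostics", {
  # a required column missing entirely
  path <- tempfile(fileext = ".csv")
  writeLines(c("night,time,cell,plot,site,taxon,level",
               "n1,22:00,c1,p1,s1,Myotis myotis,SPECIES"), path)
  expect_error(read_records(path), "missing required column.*microhabitat")

  # a row with an empty microhabitat field names its line
  path2 <- write_records_csv(c(
    "n1,22:00,c1,p1,s1,GAP,Myotis myotis,SPECIES",
    "n1,22:05,c1,p1,s1,,Myotis myotis,SPECIES"
  ))
  expect_error(read_records(path2), "microhabitat at line\\(s\\) 3")

  # timestamps outside 21:30-05:30: dropped with a warning, error in strict mode
  path3 <- write_records_csv(c(
    "n1,12:00,c1,p1,s1,GAP,Myotis myotis,SPECIES",
    "n1,22:00,c1,p1,s1,GAP,Myotis myotis,SPECIES"
  ))
  expect_warning(r <- read_records(path3), "outside the 21:30-05:30 window")
  expect_equal(nrow(r), 1)
  expect_error(suppressWarnings(read_records(path3, strict = TRUE)), "outside")
})

test_that("acoustically similar congeners collapse to one taxon, idempotently", {
  r <- make_records(c(10, 20, 30, 40),
                    taxon = c("Plecotus auritus", "Plecotus austriacus",
                              "Nyctalus noctula", "Myotis daubentonii"))
  cc <- collapse_taxa(r)
  expect_equal(sort(unique(cc$taxon)),
               c("Myotis daubentonii", "Nyctalus sp.", "Plecotus sp."))
  expect_equal(cc$taxon_level[1:3], rep("SPECIES_GROUP", 3))
  expect_identical(collapse_taxa(cc), cc)
  # the two Plecotus rows are a single taxon downstream
  expect_equal(sum(unique(cc$taxon) == "Plecotus sp."), 1)
  # non-grouped species pass through untouched
  expect_equal(cc$taxon[4], "Myotis daubentonii")
})

test_that("temporal filters implement the half-open recording windows", {
  r <- make_records(c(30, 270, 390)) # 22:00, 02:00, 04:00
  expect_equal(filter_temporal(r, "FULL_NIGHT")$timestamp, c(30, 270, 390))
  expect_equal(filter_temporal(r, "FIRST_4H")$timestamp, 30)
  expect_equal(filter_temporal(r, "SPLIT_2H_2H")$timestamp, c(30, 390))

  # boundary behaviour: window ends are exclusive, starts inclusive
  rb <- make_records(c(0, 119.99, 120, 239.99, 240, 360, 479.99))
  expect_equal(filter_temporal(rb, "FIRST_4H")$timestamp, c(0, 119.99, 120, 239.99))
  expect_equal(filter_temporal(rb, "SPLIT_2H_2H")$timestamp, c(0, 119.99, 360, 479.99))
})

test_that("FULL_NIGHT is the identity and part-night windows nest inside it", {
  set.seed(31)
  r <- make_records(runif(200, 0, 480))
  expect_equal(nrow(filter_temporal(r, "FULL_NIGHT")), 200)
  n_first <- nrow(filter_temporal(r, "FIRST_4H"))
  n_split <- nrow(filter_temporal(r, "SPLIT_2H_2H"))
  both <- unique(rbind(filter_temporal(r, "FIRST_4H"), filter_temporal(r, "SPLIT_2H_2H")))
  expect_gte(n_first + n_split, nrow(both))
  expect_lte(nrow(both), 200)
})

test_that("design filter keeps exactly the requested microhabitats", {
  r <- make_records(1:6, microhabitat = rep(c("GAP", "GROUND", "CANOPY"), 2))
  expect_equal(unique(filter_design(r, "GA")$microhabitat), "GAP")
  two <- filter_design(r, c("GAP", "GROUND"))
  expect_setequal(unique(two$microhabitat), c("GAP", "GROUND"))
  expect_equal(nrow(two), 4)
  expect_equal(nrow(filter_design(r, c("GR", "CA", "GA"))), 6)
  expect_error(filter_design(r, character(0)), "nonempty")
  expect_error(filter_design(r, "RIVER"), "nonempty subset")
})

test_that("identification summary follows the reporting conventions", {
  df <- data.frame(
    taxon = c("A", "A", "B", "C", "Chiroptera"),
    taxon_level = c("SPECIES", "SPECIES", "SPECIES", "GENUS", "ORDER"),
    guild = c("MRE", "MRE", "SRE", "SRE", "UNKNOWN"),
    n = c(60, 20, 15, 4, 1)
  )
  s <- summarize_identification(df)
  expect_equal(s$total, 100)
  expect_equal(s$n_guild_assignable, 99)
  expect_equal(s$levels$pct[s$levels$level == "SPECIES"], 95)
  expect_equal(s$levels$pct[s$levels$level == "ORDER"], 1)
  # percentages of the guild-assignable total, half-up to 2 decimals
  expect_equal(s$taxa$pct[s$taxa$taxon == "A"], round_half_up(8000 / 99, 2))
  # level percentages sum to 100 within rounding tolerance
  expect_lt(abs(sum(s$levels$pct) - 100), 0.05 * nrow(s$levels))
  expect_lt(abs(sum(s$taxa$pct) - 100), 0.05 * nrow(s$taxa))

  one <- summarize_identification(data.frame(taxon = "A", taxon_level = "SPECIES",
                                             guild = "SRE"))
  expect_equal(one$levels$pct, 100)
  empty <- summarize_identification(data.frame(taxon = character(),
                                               taxon_level = character(),
                                               guild = character()))
  expect_equal(empty$total, 0)
  expect_equal(nrow(empty$levels), 0)
})

test_that("record validation enforces the domain invariants", {
  expect_error(make_records(480), "timestamp outside")
  expect_error(make_records(-1), "timestamp outside")
  expect_error(make_records(10, microhabitat = "HEDGE"), "microhabitat")
  expect_error(make_records(10, level = "FAMILY"), "taxon_level")
  expect_warning(make_records(10, guild = "UNKNOWN", level = "SPECIES"),
                 "guild UNKNOWN")
})
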