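# The stewardship rubric: date/location parsing, origin classification,
# completeness, overrides, and their invariants.

test_that("collection_date parses to the finest stated precision", {
  res <- parse_collection_date(c("2019-03-15", "2018", "2018-06", "15-Mar-2019", "Mar-2019"))
  expect_equal(as.character(res$temporal), c("day", "year", "month", "day", "month"))
  expect_equal(res$year, c(2019L, 2018L, 2018L, 2019L, 2019L))
  expect_equal(res$month, c(3L, NA, 6L, 3L, 3L))
  expect_equal(res$day, c(15L, NA, NA, 15L, NA))
})

test_that("INSDC null tokens and absent values behave identically (idempotence)", {
  tokens <- c(insdc_null_tokens(), "", "  ", NA_character_)
  base_t <- parse_collection_date(NA_character_)
  base_s <- parse_location(NA_character_, NA_character_)
  for (tok in tokens) {
    t <- parse_collection_date(tok)
    expect_equal(as.character(t$temporal), as.character(base_t$temporal), info = tok)
    s <- parse_location(tok, tok)
    expect_equal(as.character(s$spatial), as.character(base_s$spatial), info = tok)
  }
})

test_that("unparseable dates warn and degrade to none, never fail", {
  res <- parse_collection_date(c("sometime in spring", "2019-13-40", "99"))
  expect_true(all(as.character(res$temporal) == "none"))
  expect_true(all(!is.na(res$warning)))
})

test_that("date ranges resolve to the earliest bound (vs brute-force oracle)", {
  cases <- c(
    "2016/2017", "2017/2016", "2016-05/2016-02", "2015-12-31/2016-01-01",
    "2019-06/2019", "2018/2018-03-04", "2011-01-02/2011-01-01"
  )
  got <- parse_collection_date(cases)
  for (i in seq_along(cases)) {
    oracle <- oracle_range_date(cases[i])
    expect_equal(as.character(got$temporal[i]), unname(oracle["granularity"]), info = cases[i])
    expect_equal(got$year[i], as.integer(oracle["year"]), info = cases[i])
  }
  # the worked example: range of two years keeps year precision, earliest value
  ex <- parse_collection_date("2016/2017")
  expect_equal(as.character(ex$temporal), "year")
  expect_equal(ex$year, 2016L)
})

test_that("location parsing follows the lat_lon > region > country > none ladder", {
  r1 <- parse_location("United Kingdom: Wytham Great Wood", NA)
  expect_equal(as.character(r1$spatial), "region_city")
  expect_equal(r1$country, "United Kingdom")
  expect_equal(r1$admin_region, "Wytham Great Wood")

  r2 <- parse_location("USA", NA)
  expect_equal(as.character(r2$spatial), "country")
  expect_equal(r2$country, "United States")

  r3 <- parse_location(NA, "30.61 N 96.34 W")
  expect_equal(as.character(r3$spatial), "coordinates")
  expect_equal(r3$latitude, 30.61)
  expect_equal(r3$longitude, -96.34)

  r4 <- parse_location(NA, "-41.27, 174.77")
  expect_equal(as.character(r4$spatial), "coordinates")
  expect_equal(r4$latitude, -41.27)

  # a valid lat_lon dominates any geo_loc_name level
  r5 <- parse_location("New Zealand", "41.27 S 174.77 E")
  expect_equal(as.character(r5$spatial), "coordinates")
})

test_that("malformed lat_lon falls back to the geo level with a warning", {
  r <- parse_location("New Zealand: Pelorus", "41 deg 16 min S 173 deg 34 min E")
  expect_equal(as.character(r$spatial), "region_city")
  expect_match(r$warning, "lat_lon")
  r2 <- parse_location(NA, "123.4 N 500 E") # out of range
  expect_equal(as.character(r2$spatial), "none")
  expect_match(r2$warning, "lat_lon")
  r3 <- parse_location("Atlantis", NA) # unrecognized bare country
  expect_equal(as.character(r3$spatial), "none")
  expect_match(r3$warning, "unrecognized")
})

test_that("origin classification recovers keyword classes with precedence on conflict", {
  expect_equal(
    as.character(classify_origin(c(isolation_source = "wild caught, pheromone trap"))$origin),
    "field"
  )
  expect_equal(
    as.character(classify_origin(c(strain = "inbred lab colony G21"))$origin),
    "laboratory"
  )
  expect_equal(
    as.character(classify_origin(c(isolation_source = "missing"))$origin),
    "unknown"
  )
  conf <- classify_origin(c(isolation_source = "field-collected founders, lab colony F12"))
  expect_equal(as.character(conf$origin), "laboratory")
  expect_true(conf$conflict_flag)
})

test_that("origin precedence agrees with brute-force token enumeration", {
  cases <- list(
    c(isolation_source = "wild caught"),
    c(isolation_source = "purchased from commercial supplier, wild founders"),
    c(strain = "isofemale culture"),
    c(isolation_source = "managed apiary colony"),
    c(isolation_source = "field trap near the apiary"),
    c(isolation_source = "commercial lab strain from supplier"),
    c(isolate = "wild-caught, then cultured in the laboratory"),
    c(sample_name = "colony sample 12"),
    c(host = "wild apple"), # host is not origin-bearing
    c(isolation_source = "not collected")
  )
  for (a in cases) {
    got <- classify_origin(a)
    want <- oracle_origin(a)
    expect_equal(as.character(got$origin), want$origin, info = paste(names(a), a))
    expect_equal(got$conflict_flag, want$conflict, info = paste(names(a), a))
  }
})

test_that("completeness requires status, country-level location and year", {
  expect_true(assess_completeness("field", "country", "year"))
  expect_false(assess_completeness("unknown", "coordinates", "day"))
  expect_false(assess_completeness("laboratory", "none", "year"))
  expect_false(assess_completeness("field", "country", "none"))
  expect_true(assess_completeness("laboratory", "coordinates", "month"))
})

test_that("assess_record composes the rubric deterministically", {
  full <- assess_record(make_record(
    isolation_source = "wild caught", geo_loc_name = "United Kingdom: Wytham Great Wood",
    collection_date = "2020-08-14", tissue = "thorax", dev_stage = "adult", sex = "female"
  ))
  expect_equal(as.character(full$origin), "field")
  expect_equal(as.character(full$spatial), "region_city")
  expect_true(full$complete)
  expect_true(all(c(full$has_tissue, full$has_dev_stage, full$has_sex)))

  bare <- assess_record(make_record(accession = "GCA_0.1"))
  expect_equal(as.character(bare$origin), "unknown")
  expect_equal(as.character(bare$spatial), "none")
  expect_equal(as.character(bare$temporal), "none")
  expect_false(bare$complete)
})

test_that("granularity and completeness are monotone under attribute enrichment", {
  base_cases <- list(
    c(geo_loc_name = "New Zealand"),
    c(geo_loc_name = "New Zealand: Pelorus"),
    c(geo_loc_name = "Atlantis")
  )
  for (a in base_cases) {
    before <- parse_location(a[["geo_loc_name"]], NA)
    after <- parse_location(a[["geo_loc_name"]], "41.27 S 174.77 E")
    expect_true(after$spatial >= before$spatial)
  }
  t_before <- parse_collection_date("2018")
  t_after <- parse_collection_date("2018-06-15")
  expect_true(t_after$temporal >= t_before$temporal)

  rec <- make_record(
    isolation_source = "wild caught", geo_loc_name = "New Zealand",
    collection_date = "2018"
  )
  expect_true(assess_record(rec)$complete)
  enriched <- make_record(
    isolation_source = "wild caught", geo_loc_name = "New Zealand",
    collection_date = "2018-06-15", lat_lon = "41.27 S 174.77 E"
  )
  expect_true(assess_record(enriched)$complete) # enrichment never flips complete off
})

test_that("origin overrides rescue only unknowns and report the rescue arithmetic", {
  n_unknown <- 20
  recs <- make_cohort(
    purrr::map(seq_len(n_unknown), function(i) {
      make_record(accession = sprintf("GCA_U%03d.1", i))
    }),
    make_record(accession = "GCA_F001.1", isolation_source = "wild caught")
  )
  ass <- assess_cohort(recs)
  ov <- tibble::tibble(
    accession = c(sprintf("GCA_U%03d.1", 1:5), sprintf("GCA_U%03d.1", 6:9),
      "GCA_F001.1", "GCA_MISSING.1"),
    field = "origin",
    value = c(rep("field", 5), rep("laboratory", 4), "laboratory", "field"),
    evidence = "Some et al. 2020"
  )
  res <- apply_overrides(recs, ass, ov)
  expect_equal(res$rescue$n_to_field, 5L)
  expect_equal(res$rescue$n_to_captive, 4L)
  expect_equal(res$rescue$n_remaining_unknown, n_unknown - 9L)
  # the field record kept its attribute-derived origin; two warnings emitted
  j <- match("GCA_F001.1", res$assessments$accession)
  expect_equal(as.character(res$assessments$origin[j]), "field")
  expect_equal(res$assessments$origin_source[j], "attributes")
  expect_equal(nrow(res$warnings), 2)
  # empty override list is the identity
  res0 <- apply_overrides(recs, ass, ov[0, ])
  expect_identical(res0$assessments, ass)
})

test_that("override application never increases unknowns nor touches non-unknowns", {
  cfg <- synthetic_config(n = 150, seed = 7)
  out <- generate_cohort(cfg)
  ass <- assess_cohort(out$records)
  unknown_before <- sum(as.character(ass$origin) == "unknown")
  ov <- tibble::tibble(
    accession = ass$accession[as.character(ass$origin) == "unknown"][1:10],
    field = "origin", value = "field", evidence = "Lit 2021"
  )
  res <- apply_overrides(out$records, ass, ov)
  expect_lte(res$rescue$n_remaining_unknown, unknown_before)
  untouched <- as.character(ass$origin) != "unknown"
  expect_identical(res$assessments$origin[untouched], ass$origin[untouched])
})
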