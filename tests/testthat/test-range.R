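# Native/expanded range classification and dual-range detection.

table1 <- generate_table1_fixture()
table1_assessed <- assess_cohort(table1$records)

test_that("worked examples classify as published", {
  recs <- table1$records
  ass <- table1_assessed
  pick <- function(acc) match(acc, recs$accession)

  # common wasp collected in its invaded range
  j <- pick("GCA_014466185.1")
  expect_equal(
    classify_range(recs[j, ], ass[j, ], table1$gazetteer), "expanded"
  )
  # sharpshooter from Texas: same-country both-sets case decided by admin region
  j <- pick("GCA_021130785.2")
  expect_equal(
    classify_range(recs[j, ], ass[j, ], table1$gazetteer), "native"
  )
})

test_that("ambiguity and missing information yield undetermined", {
  gaz <- table1$gazetteer
  # country in both sets and no admin resolution on the record
  rec <- make_record(
    species = "Homalodisca vitripennis",
    isolation_source = "wild caught", geo_loc_name = "USA"
  )
  ass <- assess_cohort(rec)
  expect_equal(classify_range(rec, ass, gaz), "undetermined")
  # admin present but matching neither side
  rec2 <- make_record(
    species = "Homalodisca vitripennis",
    isolation_source = "wild caught", geo_loc_name = "USA: Florida"
  )
  expect_equal(classify_range(rec2, assess_cohort(rec2), gaz), "undetermined")
  # field record with no location at all
  rec3 <- make_record(species = "Vespula vulgaris", isolation_source = "wild caught")
  expect_equal(classify_range(rec3, assess_cohort(rec3), gaz), "undetermined")
  # species absent from the gazetteer
  rec4 <- make_record(
    species = "Unknownia missingi",
    isolation_source = "wild caught", geo_loc_name = "Japan"
  )
  expect_equal(classify_range(rec4, assess_cohort(rec4), gaz), "undetermined")
  # feral species are forced undetermined
  feral_gaz <- tibble::tibble(
    species = "Vespula vulgaris", status = c("native", "expanded"),
    country = c("United Kingdom", "New Zealand"), admin_region = NA_character_,
    feral = TRUE
  )
  rec5 <- make_record(
    species = "Vespula vulgaris",
    isolation_source = "wild caught", geo_loc_name = "New Zealand"
  )
  expect_equal(classify_range(rec5, assess_cohort(rec5), feral_gaz), "undetermined")
})

test_that("classify_range enforces the field-origin contract", {
  rec <- make_record(isolation_source = "inbred laboratory culture")
  ass <- assess_cohort(rec)
  expect_error(classify_range(rec, ass, table1$gazetteer), class = "audit_contract_error")
  # cohort version marks non-field records not_applicable instead
  r <- classify_ranges(rec, ass, table1$gazetteer)
  expect_equal(as.character(r$range_status), "not_applicable")
})

test_that("no record classified native or expanded lacks spatial information", {
  cfg <- synthetic_config(n = 300, seed = 5)
  out <- generate_cohort(cfg)
  ass <- assess_cohort(out$records)
  r <- classify_ranges(out$records, ass, out$gazetteer)
  decided <- as.character(r$range_status) %in% c("native", "expanded")
  expect_true(all(as.character(ass$spatial[decided]) != "none"))
})

test_that("classify_range is invariant to gazetteer row order", {
  recs <- table1$records
  ass <- table1_assessed
  base <- classify_ranges(recs, ass, table1$gazetteer)
  for (seed in 1:3) {
    gaz <- withr::with_seed(seed, table1$gazetteer[sample(nrow(table1$gazetteer)), ])
    expect_equal(
      as.character(classify_ranges(recs, ass, gaz)$range_status),
      as.character(base$range_status)
    )
  }
})

test_that("dual-range detection equals the brute-force species scan", {
  # planted case: the generator marks exactly dual_range_species species
  for (seed in c(2, 9, 23)) {
    cfg <- synthetic_config(n = 250, seed = seed, dual_range_species = 2)
    out <- generate_cohort(cfg)
    ass <- assess_cohort(out$records)
    got <- find_dual_range_species(out$records, ass, out$gazetteer)
    expect_equal(got, brute_dual_range(out$records, ass, out$gazetteer))
    truth_dual <- out$truth |>
      dplyr::filter(.data$range_status %in% c("native", "expanded")) |>
      dplyr::left_join(out$records[, c("accession", "species")], by = "accession") |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(
        dual = dplyr::n_distinct(as.character(.data$range_status)) == 2,
        .groups = "drop"
      )
    expect_setequal(got, truth_dual$species[truth_dual$dual])
    expect_gte(length(got), 2) # the planted species are always among them
  }
})

test_that("a native-only cohort yields no dual-range species", {
  recs <- make_cohort(
    make_record(
      accession = "GCA_A.1", species = "Vespula vulgaris",
      isolation_source = "wild caught", geo_loc_name = "United Kingdom: Oxford"
    ),
    make_record(
      accession = "GCA_B.1", species = "Vespula vulgaris",
      isolation_source = "wild caught", geo_loc_name = "United Kingdom"
    )
  )
  ass <- assess_cohort(recs)
  expect_length(find_dual_range_species(recs, ass, table1$gazetteer), 0)
})

test_that("range overrides reclassify only undetermined field records", {
  recs <- make_cohort(
    make_record(
      accession = "GCA_A.1", species = "Vespula vulgaris",
      isolation_source = "wild caught"
    ), # no location -> undetermined
    make_record(
      accession = "GCA_B.1", species = "Vespula vulgaris",
      isolation_source = "wild caught", geo_loc_name = "New Zealand"
    )
  )
  ass <- assess_cohort(recs)
  ranges <- classify_ranges(recs, ass, table1$gazetteer)
  ov <- tibble::tibble(
    accession = c("GCA_A.1", "GCA_B.1"), field = "range",
    value = c("expanded", "native"), evidence = "Harrop et al. 2020"
  )
  res <- apply_range_overrides(ranges, ov)
  expect_equal(as.character(res$ranges$range_status), c("expanded", "expanded"))
  expect_equal(nrow(res$warnings), 1) # the determined record was protected
})
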