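# The seeded generator: determinism, exact marginals, recoverability, coverage.

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- synthetic_config(n = 90, seed = 12)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  # and generation does not disturb the session RNG stream
  withr::with_seed(1, {
    before <- stats::runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_cohort(cfg))
    after <- stats::runif(1)
  })
  expect_identical(before, after)
})

test_that("different seeds shuffle assignments but preserve marginal counts exactly", {
  cfg1 <- synthetic_config(n = 173, seed = 1)
  cfg2 <- synthetic_config(n = 173, seed = 2)
  a <- generate_cohort(cfg1)
  b <- generate_cohort(cfg2)
  expect_false(identical(a$truth$origin, b$truth$origin))
  expect_equal(table(a$truth$origin), table(b$truth$origin))
  expect_equal(table(a$truth$spatial), table(b$truth$spatial))
  expect_equal(table(a$truth$temporal), table(b$truth$temporal))
  expect_equal(sum(a$truth$has_sex), sum(b$truth$has_sex))
})

test_that("planted mixtures are realized exactly by largest-remainder allocation", {
  cfg <- synthetic_config(
    n = 199, seed = 3,
    origin_mixture = c(field = 64, laboratory = 42, commercial = 14, managed_colony = 3, unknown = 76) / 199
  )
  out <- generate_cohort(cfg)
  expect_equal(
    as.integer(table(out$truth$origin)[c("field", "laboratory", "commercial", "managed_colony", "unknown")]),
    c(64L, 42L, 14L, 3L, 76L)
  )
})

test_that("degenerate mixtures behave: all temporal mass on none", {
  cfg <- synthetic_config(
    n = 40, seed = 6,
    temporal_mixture = c(none = 1, year = 0, month = 0, day = 0)
  )
  out <- generate_cohort(cfg)
  dates <- purrr::map_chr(out$records$attributes, function(a) {
    i <- match("collection_date", names(a))
    if (is.na(i)) NA_character_ else a[[i]]
  })
  expect_true(all(is.na(dates) | tolower(dates) %in% insdc_null_tokens()))
})

test_that("infeasible or malformed configs are rejected", {
  expect_error(synthetic_config(n = 0), class = "audit_config_error")
  expect_error(
    synthetic_config(origin_mixture = c(field = 0.5, laboratory = 0.2, commercial = 0.1, managed_colony = 0.1, unknown = 0.2)),
    class = "audit_config_error"
  )
  expect_error(
    synthetic_config(n = 10, dual_range_species = 11),
    class = "audit_config_error"
  )
  # not enough located field records to plant dual-range species
  expect_error(
    synthetic_config(
      n = 20, dual_range_species = 5,
      origin_mixture = c(field = 0.1, laboratory = 0.3, commercial = 0.1, managed_colony = 0.1, unknown = 0.4)
    ),
    class = "audit_config_error"
  )
})

test_that("pipeline recovers planted truth exactly across seeded configs", {
  seeds <- 1:20
  sizes <- rep(c(60, 150, 400, 1000), 5)
  for (i in seq_along(seeds)) {
    cfg <- synthetic_config(n = sizes[i], seed = seeds[i])
    out <- generate_cohort(cfg)
    ass <- assess_cohort(out$records)
    expect_equal(as.character(ass$origin), as.character(out$truth$origin), info = seeds[i])
    expect_equal(as.character(ass$spatial), as.character(out$truth$spatial), info = seeds[i])
    expect_equal(as.character(ass$temporal), as.character(out$truth$temporal), info = seeds[i])
    expect_equal(ass$has_tissue, out$truth$has_tissue)
    expect_equal(ass$has_dev_stage, out$truth$has_dev_stage)
    expect_equal(ass$has_sex, out$truth$has_sex)
    ranges <- classify_ranges(out$records, ass, out$gazetteer)
    expect_equal(as.character(ranges$range_status), as.character(out$truth$range_status), info = seeds[i])
  }
})

test_that("recovery also holds at ten-thousand-record scale", {
  cfg <- synthetic_config(n = 10000, seed = 99)
  out <- generate_cohort(cfg)
  ass <- assess_cohort(out$records)
  expect_equal(as.character(ass$origin), as.character(out$truth$origin))
  expect_equal(as.character(ass$spatial), as.character(out$truth$spatial))
  expect_equal(as.character(ass$temporal), as.character(out$truth$temporal))
})

test_that("a default-sized cohort covers every category at least once", {
  out <- generate_cohort(synthetic_config(n = 199, seed = 5))
  expect_setequal(unique(as.character(out$truth$origin)), c("field", "laboratory", "commercial", "managed_colony", "unknown"))
  expect_setequal(unique(as.character(out$truth$spatial)), c("none", "country", "region_city", "coordinates"))
  expect_setequal(unique(as.character(out$truth$temporal)), c("none", "year", "month", "day"))
})

test_that("adversarial templates stress the fallback paths without breaking truth", {
  cfg <- synthetic_config(n = 300, seed = 14, adversarial = TRUE)
  out <- generate_cohort(cfg)
  expect_gt(sum(out$truth$adversarial), 0)
  ass <- assess_cohort(out$records)
  expect_equal(as.character(ass$origin), as.character(out$truth$origin))
  expect_equal(as.character(ass$spatial), as.character(out$truth$spatial))
  expect_equal(as.character(ass$temporal), as.character(out$truth$temporal))
})
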