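# Seeded synthetic-cohort generator with planted, recoverable ground truth.
# Category counts are realized exactly (largest-remainder allocation, not
# sampling), so tests on planted marginals are deterministic at any seed;
# seeds shuffle which record gets which category, never the counts.

#' Default species pool for synthetic cohorts
#'
#' Ten well-known invasive terrestrial arthropods with one native and one
#' expanded (invaded) country each, plus a region name per side used to build
#' `"Country: Region"` location strings. Purely illustrative geography at
#' country grain — sufficient for unambiguous range classification.
#'
#' @return Tibble: `species`, `taxonomic_order`, `native_country`,
#'   `native_region`, `expanded_country`, `expanded_region`.
#' @export
default_species_pool <- function() {
  tibble::tribble(
    ~species, ~taxonomic_order, ~native_country, ~native_region, ~expanded_country, ~expanded_region,
    "Drosophila suzukii", "Diptera", "Japan", "Honshu", "United States", "California",
    "Halyomorpha halys", "Hemiptera", "China", "Hebei", "United States", "Pennsylvania",
    "Aedes albopictus", "Diptera", "Thailand", "Chiang Mai", "Italy", "Lazio",
    "Lymantria dispar", "Lepidoptera", "France", "Grand Est", "Canada", "Ontario",
    "Solenopsis invicta", "Hymenoptera", "Brazil", "Pantanal", "Australia", "Queensland",
    "Bactrocera dorsalis", "Diptera", "India", "Kerala", "Kenya", "Nairobi",
    "Anoplophora glabripennis", "Coleoptera", "China", "Shandong", "Austria", "Styria",
    "Vespa velutina", "Hymenoptera", "Indonesia", "Java", "France", "Aquitaine",
    "Cydia pomonella", "Lepidoptera", "Turkey", "Anatolia", "Argentina", "Mendoza",
    "Tuta absoluta", "Lepidoptera", "Peru", "Lima", "Spain", "Valencia"
  )
}

# Largest-remainder allocation of n among named proportions; deterministic.
allocate_counts <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

#' Build and validate a synthetic-cohort configuration
#'
#' Defaults describe the study conditions the generator emulates: a cohort of
#' 199 assemblies submitted 2010–2022 with origin mixture
#' 64 field / 42 laboratory / 14 commercial / 3 managed-colony / 76 unknown,
#' 45 records lacking any location and 69 lacking any collection year,
#' tissue and developmental-stage present for 134 records, sex for 100,
#' 89 reference genomes and a 64% SRA-linkage rate.
#'
#' @param n Cohort size.
#' @param seed Integer RNG seed; generation is deterministic under
#'   (config, seed).
#' @param origin_mixture,spatial_mixture,temporal_mixture Named proportion
#'   vectors over the respective category levels; each must sum to 1
#'   (tolerance 1e-9).
#' @param presence_rates Named proportions for `tissue`, `dev_stage`, `sex`.
#' @param year_range Inclusive submission-year span.
#' @param species_pool Tibble as [default_species_pool()].
#' @param dual_range_species Number of species planted with both a native and
#'   an expanded field-collected record.
#' @param reference_fraction Proportion flagged as reference genomes.
#' @param sra_rate Proportion with SRA linkage.
#' @param adversarial If TRUE, a fraction of records uses the adversarial
#'   template set (conflicting origin keywords, date ranges, malformed
#'   lat_lon); truth rows are marked accordingly.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n = 199,
                             seed = 1,
                             origin_mixture = c(
                               field = 64, laboratory = 42, commercial = 14,
                               managed_colony = 3, unknown = 76
                             ) / 199,
                             spatial_mixture = c(
                               none = 45, country = 30, region_city = 80,
                               coordinates = 44
                             ) / 199,
                             temporal_mixture = c(
                               none = 69, year = 40, month = 30, day = 60
                             ) / 199,
                             presence_rates = c(
                               tissue = 134 / 199, dev_stage = 134 / 199,
                               sex = 100 / 199
                             ),
                             year_range = c(2010L, 2022L),
                             species_pool = default_species_pool(),
                             dual_range_species = 2,
                             reference_fraction = 89 / 199,
                             sra_rate = 0.64,
                             adversarial = FALSE) {
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    origin_mixture = origin_mixture, spatial_mixture = spatial_mixture,
    temporal_mixture = temporal_mixture, presence_rates = presence_rates,
    year_range = as.integer(year_range), species_pool = species_pool,
    dual_range_species = as.integer(dual_range_species),
    reference_fraction = reference_fraction, sra_rate = sra_rate,
    adversarial = isTRUE(adversarial)
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (is.na(cfg$n) || cfg$n <= 0) {
    abort("config error: n must be > 0", class = "audit_config_error")
  }
  check_mixture <- function(mix, levels, what) {
    if (!setequal(names(mix), levels)) {
      abort(paste0("config error: ", what, " must be named over {", paste(levels, collapse = ", "), "}"),
        class = "audit_config_error"
      )
    }
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
      abort(paste0("config error: ", what, " must be non-negative and sum to 1"),
        class = "audit_config_error"
      )
    }
  }
  check_mixture(cfg$origin_mixture, ORIGIN_LEVELS, "origin_mixture")
  check_mixture(cfg$spatial_mixture, SPATIAL_LEVELS, "spatial_mixture")
  check_mixture(cfg$temporal_mixture, TEMPORAL_LEVELS, "temporal_mixture")
  if (!setequal(names(cfg$presence_rates), c("tissue", "dev_stage", "sex")) ||
    any(cfg$presence_rates < 0 | cfg$presence_rates > 1)) {
    abort("config error: presence_rates must name tissue/dev_stage/sex in [0, 1]",
      class = "audit_config_error"
    )
  }
  if (length(cfg$year_range) != 2 || cfg$year_range[1] > cfg$year_range[2]) {
    abort("config error: year_range must be an inclusive c(min, max)", class = "audit_config_error")
  }
  if (cfg$dual_range_species > nrow(cfg$species_pool)) {
    abort("config error: dual_range_species exceeds the species pool",
      class = "audit_config_error"
    )
  }
  # each planted dual-range species needs two located field records
  n_field <- allocate_counts(cfg$n, cfg$origin_mixture)[["field"]]
  n_located <- cfg$n - allocate_counts(cfg$n, cfg$spatial_mixture)[["none"]]
  if (cfg$dual_range_species > 0 &&
    2 * cfg$dual_range_species > min(n_field, n_located)) {
    abort("config error: not enough located field records to plant the requested dual-range species",
      class = "audit_config_error"
    )
  }
  invisible(cfg)
}

null_token_or_absent <- function(n) {
  # half the planted-missing values use an explicit INSDC null token, half are
  # simply absent; both must behave identically downstream
  tokens <- c("missing", "not collected", "not applicable", "restricted access")
  ifelse(stats::runif(n) < 0.5, sample(tokens, n, replace = TRUE), NA_character_)
}

FIELD_TEMPLATES <- c(
  "wild caught, pheromone trap",
  "field collected from natural population",
  "wild, collected from nature",
  "trapped in the field"
)
LAB_TEMPLATES <- c(
  "inbred laboratory culture",
  "isofemale lab culture",
  "long-term laboratory strain"
)
COMMERCIAL_TEMPLATES <- c(
  "purchased from commercial supplier",
  "obtained from commercial vendor"
)
COLONY_TEMPLATES <- c(
  "managed apiary colony",
  "sample from managed hive"
)
ADVERSARIAL_ORIGIN <- "field-collected founders, lab colony F12" # classifies laboratory, flagged

#' Generate a synthetic cohort with planted truth
#'
#' Produces an assembly cohort whose attribute strings are drawn from
#' unambiguous dialect templates (ISO dates at the planted precision,
#' `"Country: Region"` strings, hemisphere-style lat_lon, origin keyword
#' phrases, INSDC null tokens for planted-missing fields), together with the
#' per-record planted truth and the implied home-range gazetteer. Category
#' counts are realized exactly via largest-remainder allocation; output is
#' deterministic under (config, seed).
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (cohort tibble), `truth` (tibble: `accession`,
#'   `origin`, `spatial`, `temporal`, `range_status`, `has_tissue`,
#'   `has_dev_stage`, `has_sex`, `adversarial`) and `gazetteer`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n
  pool <- cfg$species_pool
  origin <- sample(rep(ORIGIN_LEVELS, allocate_counts(n, cfg$origin_mixture[ORIGIN_LEVELS])))
  spatial <- sample(rep(SPATIAL_LEVELS, allocate_counts(n, cfg$spatial_mixture[SPATIAL_LEVELS])))
  temporal <- sample(rep(TEMPORAL_LEVELS, allocate_counts(n, cfg$temporal_mixture[TEMPORAL_LEVELS])))
  presence <- lapply(cfg$presence_rates, function(p) {
    k <- allocate_counts(n, c(yes = p, no = 1 - p))[["yes"]]
    sample(rep(c(TRUE, FALSE), c(k, n - k)))
  })

  species_idx <- sample(nrow(pool), n, replace = TRUE)
  side <- ifelse(stats::runif(n) < 0.5, "native", "expanded")

  # Plant dual-range species on located field records (two each, one per side).
  located_field <- which(origin == "field" & spatial != "none")
  if (cfg$dual_range_species > 0) {
    dual_sp <- sample(nrow(pool), cfg$dual_range_species)
    slots <- sample(located_field, 2 * cfg$dual_range_species)
    for (k in seq_len(cfg$dual_range_species)) {
      pair <- slots[c(2 * k - 1, 2 * k)]
      species_idx[pair] <- dual_sp[k]
      side[pair] <- c("native", "expanded")
    }
  }

  adversarial <- rep(FALSE, n)
  if (cfg$adversarial) {
    k <- max(1L, floor(n / 10))
    adversarial[sample(n, k)] <- TRUE
  }

  sp <- pool[species_idx, ]
  loc_country <- ifelse(side == "native", sp$native_country, sp$expanded_country)
  loc_region <- ifelse(side == "native", sp$native_region, sp$expanded_region)

  geo <- rep(NA_character_, n)
  lat_lon <- rep(NA_character_, n)
  lat <- round(stats::runif(n, -60, 70), 2)
  lon <- round(stats::runif(n, -179, 179), 2)
  hemi <- sprintf(
    "%.2f %s %.2f %s",
    abs(lat), ifelse(lat < 0, "S", "N"), abs(lon), ifelse(lon < 0, "W", "E")
  )
  geo[spatial == "country"] <- loc_country[spatial == "country"]
  rc <- spatial %in% c("region_city", "coordinates")
  geo[rc] <- paste0(loc_country[rc], ": ", loc_region[rc])
  lat_lon[spatial == "coordinates"] <- hemi[spatial == "coordinates"]
  geo[spatial == "none"] <- null_token_or_absent(sum(spatial == "none"))
  # adversarial records carry a malformed lat_lon; the parser must fall back
  # to the geo_loc_name level, so planted spatial truth is the geo level
  adv_ll <- adversarial & spatial %in% c("country", "region_city")
  lat_lon[adv_ll] <- "34 deg 02 min N 118 deg 15 min W"

  coll_year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n, replace = TRUE)
  coll_month <- sample(12L, n, replace = TRUE)
  coll_day <- sample(28L, n, replace = TRUE)
  collection_date <- rep(NA_character_, n)
  collection_date[temporal == "year"] <- sprintf("%d", coll_year[temporal == "year"])
  collection_date[temporal == "month"] <-
    sprintf("%d-%02d", coll_year[temporal == "month"], coll_month[temporal == "month"])
  collection_date[temporal == "day"] <- sprintf(
    "%d-%02d-%02d",
    coll_year[temporal == "day"], coll_month[temporal == "day"], coll_day[temporal == "day"]
  )
  collection_date[temporal == "none"] <- null_token_or_absent(sum(temporal == "none"))
  adv_dt <- adversarial & temporal == "year"
  collection_date[adv_dt] <- sprintf("%d/%d", coll_year[adv_dt], coll_year[adv_dt] + 1)

  isolation_source <- rep(NA_character_, n)
  isolation_source[origin == "field"] <-
    sample(FIELD_TEMPLATES, sum(origin == "field"), replace = TRUE)
  isolation_source[origin == "laboratory"] <-
    sample(LAB_TEMPLATES, sum(origin == "laboratory"), replace = TRUE)
  isolation_source[origin == "commercial"] <-
    sample(COMMERCIAL_TEMPLATES, sum(origin == "commercial"), replace = TRUE)
  isolation_source[origin == "managed_colony"] <-
    sample(COLONY_TEMPLATES, sum(origin == "managed_colony"), replace = TRUE)
  isolation_source[origin == "unknown"] <- null_token_or_absent(sum(origin == "unknown"))
  adv_or <- adversarial & origin == "laboratory"
  isolation_source[adv_or] <- ADVERSARIAL_ORIGIN

  tissue <- ifelse(presence$tissue, sample(c("whole body", "thorax", "leg"), n, replace = TRUE),
    null_token_or_absent(n)
  )
  dev_stage <- ifelse(presence$dev_stage, sample(c("adult", "larva", "pupa"), n, replace = TRUE),
    null_token_or_absent(n)
  )
  sex <- ifelse(presence$sex, sample(c("female", "male"), n, replace = TRUE),
    null_token_or_absent(n)
  )

  sub_year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n, replace = TRUE)
  submission_date <- as.Date(sprintf(
    "%d-%02d-%02d", sub_year,
    sample(12L, n, replace = TRUE), sample(28L, n, replace = TRUE)
  ))
  n_ref <- allocate_counts(n, c(yes = cfg$reference_fraction, no = 1 - cfg$reference_fraction))[["yes"]]
  is_reference <- sample(rep(c(TRUE, FALSE), c(n_ref, n - n_ref)))
  n_sra <- allocate_counts(n, c(yes = cfg$sra_rate, no = 1 - cfg$sra_rate))[["yes"]]
  sra_linked <- sample(rep(c(TRUE, FALSE), c(n_sra, n - n_sra)))
  institutes <- c(
    "Invasive Arthropod Genomics Consortium", "National Sequencing Centre",
    "University Genome Institute", "Agricultural Research Institute"
  )
  inst_country <- c("United States", "United Kingdom", "France", "New Zealand")
  inst_idx <- sample(4L, n, replace = TRUE)
  level <- sample(ASSEMBLY_LEVELS, n, replace = TRUE, prob = c(0.12, 0.54, 0.34))

  attributes <- map(seq_len(n), function(i) {
    a <- c(
      collection_date = collection_date[i],
      geo_loc_name = geo[i],
      lat_lon = lat_lon[i],
      isolation_source = isolation_source[i],
      tissue = tissue[i],
      dev_stage = dev_stage[i],
      sex = sex[i]
    )
    a[!is.na(a)]
  })

  records <- tibble(
    accession = sprintf("GCA_9%08d.1", seq_len(n)),
    species = sp$species,
    taxonomic_order = sp$taxonomic_order,
    assembly_level = factor(level, levels = ASSEMBLY_LEVELS),
    submission_date = submission_date,
    submitter_institute = institutes[inst_idx],
    submitter_country = inst_country[inst_idx],
    is_reference = is_reference,
    sra_linked = sra_linked,
    attributes = attributes
  )
  records <- validate_cohort(records)

  range_truth <- ifelse(
    origin != "field", "not_applicable",
    ifelse(spatial == "none", "undetermined", side)
  )
  truth <- tibble(
    accession = records$accession,
    origin = origin_factor(origin),
    spatial = spatial_factor(spatial),
    temporal = temporal_factor(temporal),
    range_status = range_factor(range_truth),
    has_tissue = presence$tissue,
    has_dev_stage = presence$dev_stage,
    has_sex = presence$sex,
    adversarial = adversarial
  )

  gazetteer <- bind_rows(
    tibble(
      species = pool$species, status = "native",
      country = pool$native_country, admin_region = NA_character_, feral = FALSE
    ),
    tibble(
      species = pool$species, status = "expanded",
      country = pool$expanded_country, admin_region = NA_character_, feral = FALSE
    )
  ) |> arrange(.data$species, .data$status)

  list(records = records, truth = truth, gazetteer = gazetteer)
}

#' Load the packaged dual-range worked example
#'
#' The packaged fixture of seven invasive species (15 assemblies) for which
#' both native- and expanded-range field-collected genome assemblies exist,
#' together with the implied home-range gazetteer. Accessions, species,
#' taxonomic orders and collection locations mirror the published record of
#' these assemblies; submission dates, assembly levels, flags and the
#' remaining sample attributes are synthetic stand-ins.
#'
#' @return List with `records` (15-row cohort tibble) and `gazetteer`.
#' @export
generate_table1_fixture <- function() {
  records <- read_assembly_table(
    aa_extdata("table1_assemblies.tsv"),
    dialect = "canonical_tsv",
    attributes_path = aa_extdata("table1_attributes.ndjson")
  )
  gazetteer <- read_home_ranges(aa_extdata("table1_gazetteer.tsv"))
  list(records = records, gazetteer = gazetteer)
}

#' Write a generated cohort to a directory
#'
#' Materializes a synthetic cohort in the canonical dialects: assembly TSV,
#' sidecar NDJSON attributes, planted-truth TSV and gazetteer TSV.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
simulate_to_dir <- function(config, dir) {
  out <- generate_cohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    assemblies = file.path(dir, "assemblies.tsv"),
    attributes = file.path(dir, "attributes.ndjson"),
    truth = file.path(dir, "truth.tsv"),
    gazetteer = file.path(dir, "gazetteer.tsv")
  )
  write_assembly_table(out$records, paths[["assemblies"]])
  write_attribute_records(out$records, paths[["attributes"]])
  readr::write_tsv(out$truth, paths[["truth"]], progress = FALSE)
  readr::write_tsv(out$gazetteer, paths[["gazetteer"]], progress = FALSE)
  invisible(paths)
}
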