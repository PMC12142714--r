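# Native-vs-expanded range classification of field-collected records against
# the species home-range gazetteer, plus dual-range species detection.

classify_one_range <- function(species, country, admin_region, spatial, gaz) {
  rows <- gaz[gaz$species == species, , drop = FALSE]
  if (nrow(rows) == 0) {
    return("undetermined") # species absent from gazetteer
  }
  if (any(rows$feral)) {
    return("undetermined") # feral species are unclassifiable by design
  }
  if (as.character(spatial) == "none" || is.na(country)) {
    return("undetermined") # no usable collection location
  }
  country <- normalize_country(country)
  native <- rows[rows$status == "native" & rows$country == country, , drop = FALSE]
  expanded <- rows[rows$status == "expanded" & rows$country == country, , drop = FALSE]
  in_native <- nrow(native) > 0
  in_expanded <- nrow(expanded) > 0
  if (!in_native && !in_expanded) {
    return("undetermined")
  }
  if (in_native && !in_expanded) {
    return("native")
  }
  if (!in_native && in_expanded) {
    return("expanded")
  }
  # country in both sets (the admin-qualified, Texas/California case):
  # decide only on an exact admin-region match on exactly one side.
  if (is.na(admin_region)) {
    return("undetermined")
  }
  adm <- str_to_lower(str_squish(admin_region))
  hit_native <- adm %in% str_to_lower(str_squish(native$admin_region[!is.na(native$admin_region)]))
  hit_expanded <- adm %in% str_to_lower(str_squish(expanded$admin_region[!is.na(expanded$admin_region)]))
  if (hit_native && !hit_expanded) {
    return("native")
  }
  if (hit_expanded && !hit_native) {
    return("expanded")
  }
  "undetermined"
}

#' Classify a field-collected record as native or expanded range
#'
#' Matches the record's normalized collection country (and admin region when
#' both the record and the gazetteer resolve below country level) against the
#' species' native and expanded sets. A country present in exactly one set
#' decides; a country present in both sets requires an exact admin-region
#' match on exactly one side, otherwise the record is `undetermined` — as are
#' records with no usable location, species absent from the gazetteer, and
#' species flagged feral.
#'
#' `classify_range()` checks the field-origin contract for a single record;
#' `classify_ranges()` maps a whole cohort, marking non-field records
#' `not_applicable`.
#'
#' @param record One-row cohort tibble.
#' @param assessment Matching one-row assessment tibble.
#' @param gazetteer Gazetteer tibble from [read_home_ranges()].
#' @return `classify_range()`: a single range status string.
#' @export
classify_range <- function(record, assessment, gazetteer) {
  stopifnot(nrow(record) == 1, nrow(assessment) == 1)
  if (as.character(assessment$origin) != "field") {
    abort("classify_range() requires a field-collected record", class = "audit_contract_error")
  }
  classify_one_range(
    record$species, assessment$country, assessment$admin_region,
    assessment$spatial, gazetteer
  )
}

#' @rdname classify_range
#' @param records Cohort tibble.
#' @param assessments Assessment tibble aligned 1:1 with `records`.
#' @return `classify_ranges()`: tibble `accession`, `species`, `country`,
#'   `admin_region`, `range_status` with levels
#'   native/expanded/undetermined/not_applicable.
#' @export
classify_ranges <- function(records, assessments, gazetteer) {
  if (!identical(records$accession, assessments$accession)) {
    abort("records and assessments are not aligned", class = "audit_contract_error")
  }
  status <- map_chr(seq_len(nrow(records)), function(i) {
    if (as.character(assessments$origin[i]) != "field") {
      return("not_applicable")
    }
    classify_one_range(
      records$species[i], assessments$country[i], assessments$admin_region[i],
      assessments$spatial[i], gazetteer
    )
  })
  tibble(
    accession = records$accession,
    species = records$species,
    country = assessments$country,
    admin_region = assessments$admin_region,
    range_status = range_factor(status)
  )
}

#' Apply curated range overrides
#'
#' Conservative, mirroring [apply_overrides()]: only field-collected records
#' whose range is currently `undetermined` are reclassified; anything else
#' (unknown accession, non-field record, already-determined range) is skipped
#' with a warning row.
#'
#' @param ranges Range tibble from [classify_ranges()].
#' @param overrides Override tibble; only `field == "range"` rows are used.
#' @return List with `ranges` (updated) and `warnings`.
#' @export
apply_range_overrides <- function(ranges, overrides) {
  warnings <- tibble(accession = character(), reason = character())
  if (nrow(overrides) > 0) {
    ov <- validate_overrides(overrides)
    ov <- ov[ov$field == "range", , drop = FALSE]
    for (i in seq_len(nrow(ov))) {
      j <- match(ov$accession[i], ranges$accession)
      if (is.na(j)) {
        warnings <- bind_rows(warnings, tibble(
          accession = ov$accession[i],
          reason = "override accession not in cohort; skipped"
        ))
        next
      }
      if (as.character(ranges$range_status[j]) != "undetermined") {
        warnings <- bind_rows(warnings, tibble(
          accession = ov$accession[i],
          reason = "range override targets a record that is not undetermined; skipped"
        ))
        next
      }
      ranges$range_status[j] <- ov$value[i]
    }
  }
  list(ranges = ranges, warnings = warnings)
}

#' Find dual-range species
#'
#' Species with at least one field-collected assembly classified native and
#' at least one classified expanded — the subset for which within-species
#' native/invaded genomic comparisons are possible without new sequencing.
#'
#' @inheritParams classify_ranges
#' @return Sorted character vector of species names.
#' @export
find_dual_range_species <- function(records, assessments, gazetteer) {
  ranges <- classify_ranges(records, assessments, gazetteer)
  dual <- ranges |>
    filter(.data$range_status %in% c("native", "expanded")) |>
    group_by(.data$species) |>
    summarise(
      dual = any(.data$range_status == "native") && any(.data$range_status == "expanded"),
      .groups = "drop"
    ) |>
    filter(.data$dual)
  sort(dual$species)
}
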