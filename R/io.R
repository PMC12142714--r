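# Readers/writers for the canonical tabular dialects: assembly TSV, sidecar
# NDJSON attribute records, home-range gazetteer, override table, income table.
# All validation happens here so downstream modules can assume clean input.

ASSEMBLY_COLUMNS <- c(
  "accession", "species", "taxonomic_order", "assembly_level",
  "submission_date", "submitter_institute", "submitter_country",
  "is_reference", "sra_linked"
)

default_year_window <- function() {
  c(1990L, as.integer(format(Sys.Date(), "%Y")))
}

# Shared invariant checks for an assembly cohort tibble (reader + generator).
validate_cohort <- function(records, year_window = default_year_window()) {
  missing_cols <- setdiff(ASSEMBLY_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      class = "audit_schema_error"
    )
  }
  if (any(is.na(records$accession) | records$accession == "")) {
    abort("accession must be non-empty for every record", class = "audit_schema_error")
  }
  dup <- unique(records$accession[duplicated(records$accession)])
  if (length(dup) > 0) {
    abort(
      paste0("duplicate accession(s): ", paste(dup, collapse = ", ")),
      class = "audit_integrity_error"
    )
  }
  lev <- str_to_lower(str_trim(as.character(records$assembly_level)))
  bad <- which(!lev %in% ASSEMBLY_LEVELS)
  if (length(bad) > 0) {
    abort(
      paste0(
        "unknown assembly_level ", encodeString(as.character(records$assembly_level)[bad[1]], quote = "'"),
        " in row ", bad[1], " (accession ", records$accession[bad[1]], ")"
      ),
      class = "audit_value_error"
    )
  }
  yr <- as.integer(format(records$submission_date, "%Y"))
  if (any(is.na(yr))) {
    abort("submission_date must be a parseable date (year mandatory)", class = "audit_value_error")
  }
  out_of_window <- which(yr < year_window[1] | yr > year_window[2])
  if (length(out_of_window) > 0) {
    abort(
      paste0(
        "submission year ", yr[out_of_window[1]], " outside validity window ",
        year_window[1], "-", year_window[2], " (accession ",
        records$accession[out_of_window[1]], ")"
      ),
      class = "audit_value_error"
    )
  }
  records$assembly_level <- factor(lev, levels = ASSEMBLY_LEVELS)
  if (!"attributes" %in% names(records)) {
    records$attributes <- rep(list(character()), nrow(records))
  }
  as_tibble(records[, c(ASSEMBLY_COLUMNS, "attributes")])
}

# Normalize one raw attribute map: snake-case keys once, trim values only.
normalize_attributes <- function(a) {
  if (length(a) == 0) {
    return(stats::setNames(character(), character()))
  }
  vals <- str_trim(vapply(a, function(v) as.character(v)[1], character(1)))
  stats::setNames(vals, normalize_keys(names(a)))
}

#' Read an assembly table into a cohort tibble
#'
#' Reads one of the two canonical cohort dialects:
#' * `canonical_tsv` — a TSV with the fixed column set (`accession`, `species`,
#'   `taxonomic_order`, `assembly_level`, `submission_date`,
#'   `submitter_institute`, `submitter_country`, `is_reference`, `sra_linked`);
#'   sample attributes come from an optional sidecar NDJSON file
#'   (`attributes_path`, see [read_attribute_records()]).
#' * `records_json` — line-delimited JSON records carrying the same fields plus
#'   a flat `attributes` object per record.
#'
#' Attribute keys are normalized to lower snake case exactly once here; values
#' are kept verbatim apart from surrounding-whitespace stripping. Unrecognized
#' keys are preserved.
#'
#' @param path Input file.
#' @param dialect `"canonical_tsv"` (default) or `"records_json"`.
#' @param attributes_path Optional sidecar NDJSON attribute file
#'   (canonical_tsv dialect only).
#' @param year_window Inclusive `c(min, max)` validity window for the
#'   submission year (default 1990 to the current year).
#' @return A cohort tibble: one row per assembly, assembly columns plus an
#'   `attributes` list-column of named character vectors. Row order follows
#'   the file.
#' @export
read_assembly_table <- function(path,
                                dialect = c("canonical_tsv", "records_json"),
                                attributes_path = NULL,
                                year_window = default_year_window()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path), class = "audit_schema_error")
  }
  if (dialect == "canonical_tsv") {
    records <- readr::read_tsv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    missing_cols <- setdiff(ASSEMBLY_COLUMNS, names(records))
    if (length(missing_cols) > 0) {
      abort(
        paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
        class = "audit_schema_error"
      )
    }
    records$submission_date <- as.Date(records$submission_date)
    records$is_reference <- as.logical(records$is_reference)
    records$sra_linked <- as.logical(records$sra_linked)
    if (nrow(records) == 0) {
      abort("assembly table has a header but no records", class = "audit_schema_error")
    }
    records$attributes <- rep(list(stats::setNames(character(), character())), nrow(records))
    if (!is.null(attributes_path)) {
      attrs <- read_attribute_records(attributes_path)
      idx <- match(records$accession, attrs$accession)
      records$attributes[!is.na(idx)] <- attrs$attributes[idx[!is.na(idx)]]
    }
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(str_trim(lines))]
    if (length(lines) == 0) {
      abort("records_json input contains no records", class = "audit_schema_error")
    }
    recs <- map(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    field_or_na <- function(r, f) {
      v <- r[[f]]
      if (is.null(v)) NA_character_ else as.character(v)[1]
    }
    records <- tibble(
      accession = map_chr(recs, field_or_na, "accession"),
      species = map_chr(recs, field_or_na, "species"),
      taxonomic_order = map_chr(recs, field_or_na, "taxonomic_order"),
      assembly_level = map_chr(recs, field_or_na, "assembly_level"),
      submission_date = as.Date(map_chr(recs, field_or_na, "submission_date")),
      submitter_institute = map_chr(recs, field_or_na, "submitter_institute"),
      submitter_country = map_chr(recs, field_or_na, "submitter_country"),
      is_reference = map_lgl(recs, function(r) isTRUE(as.logical(r[["is_reference"]]))),
      sra_linked = map_lgl(recs, function(r) isTRUE(as.logical(r[["sra_linked"]]))),
      attributes = map(recs, function(r) normalize_attributes(as.list(r[["attributes"]])))
    )
  }
  records$attributes <- map(records$attributes, normalize_attributes)
  validate_cohort(records, year_window = year_window)
}

#' Read sidecar attribute records
#'
#' Line-delimited JSON, one record per line:
#' `{"accession": "...", "attributes": {"collection_date": "2019-03-15", ...}}`.
#' Keys are normalized to lower snake case; values kept verbatim apart from
#' surrounding-whitespace stripping.
#'
#' @param path NDJSON file.
#' @return Tibble with columns `accession` and `attributes` (list-column).
#' @export
read_attribute_records <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path), class = "audit_schema_error")
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(str_trim(lines))]
  recs <- map(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  tibble(
    accession = map_chr(recs, function(r) as.character(r[["accession"]])[1]),
    attributes = map(recs, function(r) normalize_attributes(as.list(r[["attributes"]])))
  )
}

#' Write a cohort in the canonical dialects
#'
#' `write_assembly_table()` writes the fixed-column TSV (ISO dates,
#' TRUE/FALSE logicals); reading it back with [read_assembly_table()] and
#' writing again is byte-identical. `write_attribute_records()` writes the
#' sidecar NDJSON attribute file.
#'
#' @param records A cohort tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_assembly_table <- function(records, path) {
  out <- records[, ASSEMBLY_COLUMNS]
  out$assembly_level <- as.character(out$assembly_level)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_assembly_table
#' @export
write_attribute_records <- function(records, path) {
  lines <- map_chr(seq_len(nrow(records)), function(i) {
    a <- records$attributes[[i]]
    jsonlite::toJSON(
      list(accession = records$accession[i], attributes = as.list(a)),
      auto_unbox = TRUE
    )
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a species home-range gazetteer
#'
#' TSV with columns `species`, `status` (`native`/`expanded`), `country`,
#' optional `admin_region` and optional per-species logical `feral`. Country
#' names are normalized via the packaged alias table at read time. Validity:
#' every species needs at least one native region; the same
#' (country, admin_region) pair may not sit in both sets; a bare country may
#' appear on both sides only when at least one side also carries
#' admin-region qualifiers (e.g. a species native to Texas and introduced in
#' California, both United States).
#'
#' @param path TSV file.
#' @return Tibble: `species`, `status`, `country`, `admin_region`, `feral`.
#' @export
read_home_ranges <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path), class = "audit_schema_error")
  }
  gaz <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE)
  required <- c("species", "status", "country")
  missing_cols <- setdiff(required, names(gaz))
  if (length(missing_cols) > 0) {
    abort(
      paste0("gazetteer missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "audit_schema_error"
    )
  }
  if (!"admin_region" %in% names(gaz)) gaz$admin_region <- NA_character_
  if (!"feral" %in% names(gaz)) gaz$feral <- "FALSE"
  gaz <- gaz |>
    mutate(
      status = str_to_lower(str_trim(.data$status)),
      country = normalize_country(.data$country),
      admin_region = str_squish(.data$admin_region),
      feral = as.logical(str_to_lower(.data$feral) %in% c("true", "1", "yes"))
    )
  gaz$admin_region[!is.na(gaz$admin_region) & gaz$admin_region == ""] <- NA_character_
  bad_status <- setdiff(unique(gaz$status), c("native", "expanded"))
  if (length(bad_status) > 0) {
    abort(
      paste0("gazetteer status must be native/expanded, got: ", paste(bad_status, collapse = ", ")),
      class = "audit_schema_error"
    )
  }
  validate_home_ranges(gaz)
  gaz
}

validate_home_ranges <- function(gaz) {
  no_native <- setdiff(unique(gaz$species), gaz$species[gaz$status == "native"])
  if (length(no_native) > 0) {
    abort(
      paste0("species with empty native set: ", paste(no_native, collapse = ", ")),
      class = "audit_schema_error"
    )
  }
  key <- paste(gaz$species, gaz$country, ifelse(is.na(gaz$admin_region), "", gaz$admin_region), sep = "\r")
  both <- intersect(key[gaz$status == "native"], key[gaz$status == "expanded"])
  if (length(both) > 0) {
    abort(
      paste0("region listed as both native and expanded: ", gsub("\r", " / ", both[1])),
      class = "audit_integrity_error"
    )
  }
  # bare-country-in-both rule
  ck <- paste(gaz$species, gaz$country, sep = "\r")
  shared <- intersect(ck[gaz$status == "native"], ck[gaz$status == "expanded"])
  for (s in shared) {
    rows <- gaz[ck == s, ]
    if (all(is.na(rows$admin_region))) {
      abort(
        paste0(
          "country in both native and expanded sets without admin-region qualifiers: ",
          gsub("\r", " / ", s)
        ),
        class = "audit_integrity_error"
      )
    }
  }
  invisible(gaz)
}

OVERRIDE_VALUES <- list(
  origin = setdiff(ORIGIN_LEVELS, "unknown"),
  range = c("native", "expanded")
)

#' Read a curated override table
#'
#' The manual literature-rescue table: TSV with columns `accession`, `field`
#' (`origin` or `range`), `value` (the replacement classification) and
#' `evidence` (a citation; an override without a source is rejected).
#' Accessions need not exist yet — they are matched when the overrides are
#' applied.
#'
#' @param path TSV file.
#' @return Tibble: `accession`, `field`, `value`, `evidence`.
#' @export
read_overrides <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path), class = "audit_schema_error")
  }
  ov <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE)
  required <- c("accession", "field", "value", "evidence")
  missing_cols <- setdiff(required, names(ov))
  if (length(missing_cols) > 0) {
    abort(
      paste0("override table missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "audit_schema_error"
    )
  }
  validate_overrides(ov)
}

validate_overrides <- function(ov) {
  ov <- ov |>
    mutate(
      field = str_to_lower(str_trim(.data$field)),
      value = str_to_lower(str_trim(.data$value)),
      evidence = str_trim(.data$evidence)
    )
  if (any(is.na(ov$evidence) | ov$evidence == "")) {
    abort("override without evidence (a cited source is mandatory)", class = "audit_validation_error")
  }
  bad_field <- !ov$field %in% names(OVERRIDE_VALUES)
  if (any(bad_field)) {
    abort(
      paste0("illegal override field: ", ov$field[which(bad_field)[1]]),
      class = "audit_validation_error"
    )
  }
  legal <- map_lgl(seq_len(nrow(ov)), function(i) ov$value[i] %in% OVERRIDE_VALUES[[ov$field[i]]])
  if (!all(legal)) {
    i <- which(!legal)[1]
    abort(
      paste0("illegal override value '", ov$value[i], "' for field '", ov$field[i], "'"),
      class = "audit_validation_error"
    )
  }
  as_tibble(ov)
}

#' Read a country income table
#'
#' TSV with columns `country` and `gni_per_capita` (USD, strictly positive).
#' The high-income threshold is fixed per run and carried on the returned
#' tibble as the `"threshold"` attribute; the default (USD 12,055) is the
#' World Bank style GNI-per-capita cutoff used for the high-income group.
#'
#' @param path TSV file.
#' @param threshold High-income GNI-per-capita cutoff in USD (default 12055).
#' @return Tibble `country`, `gni_per_capita` with attribute `threshold`.
#' @export
read_income_table <- function(path, threshold = 12055) {
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path), class = "audit_schema_error")
  }
  inc <- readr::read_tsv(path, col_types = readr::cols(
    country = readr::col_character(),
    gni_per_capita = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(c("country", "gni_per_capita"), names(inc))
  if (length(missing_cols) > 0) {
    abort(
      paste0("income table missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "audit_schema_error"
    )
  }
  if (any(is.na(inc$gni_per_capita) | inc$gni_per_capita <= 0)) {
    abort("GNI per capita must be strictly positive", class = "audit_value_error")
  }
  inc$country <- normalize_country(inc$country)
  attr(inc, "threshold") <- threshold
  inc
}
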