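# The stewardship rubric: attribute-string parsers (collection_date,
# geo_loc_name/lat_lon dialects), keyword origin classifier, completeness
# scoring, and the literature-rescue override step. This is the core of the
# audit; everything else is plumbing around these functions.

# ---- temporal -----------------------------------------------------------

month_from_name <- function(x) {
  match(str_to_lower(substr(x, 1, 3)), str_to_lower(month.abb))
}

# Parse a single date *bound* (no ranges). Returns list(year, month, day, ok).
parse_date_bound <- function(x) {
  x <- str_trim(x)
  m <- str_match(x, "^(\\d{4})-(\\d{1,2})-(\\d{1,2})$")
  if (!is.na(m[1, 1])) {
    return(list(year = as.integer(m[1, 2]), month = as.integer(m[1, 3]), day = as.integer(m[1, 4])))
  }
  m <- str_match(x, "^(\\d{4})-(\\d{1,2})$")
  if (!is.na(m[1, 1])) {
    return(list(year = as.integer(m[1, 2]), month = as.integer(m[1, 3]), day = NA_integer_))
  }
  m <- str_match(x, "^(\\d{4})$")
  if (!is.na(m[1, 1])) {
    return(list(year = as.integer(m[1, 2]), month = NA_integer_, day = NA_integer_))
  }
  # INSDC legacy forms: DD-Mmm-YYYY and Mmm-YYYY
  m <- str_match(x, "^(\\d{1,2})[- ]([A-Za-z]{3,})[- ](\\d{4})$")
  if (!is.na(m[1, 1])) {
    return(list(year = as.integer(m[1, 4]), month = month_from_name(m[1, 3]), day = as.integer(m[1, 2])))
  }
  m <- str_match(x, "^([A-Za-z]{3,})[- ](\\d{4})$")
  if (!is.na(m[1, 1])) {
    return(list(year = as.integer(m[1, 3]), month = month_from_name(m[1, 2]), day = NA_integer_))
  }
  list(year = NA_integer_, month = NA_integer_, day = NA_integer_)
}

bound_valid <- function(b) {
  if (is.na(b$year)) {
    return(FALSE)
  }
  if (!is.na(b$month) && (is.na(b$month) || b$month < 1 || b$month > 12)) {
    return(FALSE)
  }
  if (!is.na(b$day)) {
    if (is.na(b$month)) {
      return(FALSE)
    }
    if (b$day < 1 || b$day > 31) {
      return(FALSE)
    }
  }
  TRUE
}

bound_key <- function(b) {
  b$year * 372L + (if (is.na(b$month)) 1L else b$month) * 31L + (if (is.na(b$day)) 1L else b$day)
}

parse_one_date <- function(x) {
  none <- list(granularity = "none", year = NA_integer_, month = NA_integer_, day = NA_integer_, warning = NA_character_)
  if (is_null_value(x)) {
    return(none)
  }
  x <- str_trim(x)
  parts <- str_trim(strsplit(x, "/", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0 || length(parts) > 2) {
    none$warning <- paste0("unparseable collection_date: '", x, "'")
    return(none)
  }
  bounds <- lapply(parts, parse_date_bound)
  if (!all(vapply(bounds, bound_valid, logical(1)))) {
    none$warning <- paste0("unparseable collection_date: '", x, "'")
    return(none)
  }
  # a range resolves to its earliest bound, at that bound's own precision
  b <- bounds[[which.min(vapply(bounds, bound_key, numeric(1)))]]
  gran <- if (!is.na(b$day)) "day" else if (!is.na(b$month)) "month" else "year"
  list(granularity = gran, year = b$year, month = b$month, day = b$day, warning = NA_character_)
}

#' Parse collection_date strings into temporal granularity
#'
#' Resolves INSDC `collection_date` values to the finest calendar precision
#' they carry, on the ordered scale `none < year < month < day`. Accepted
#' dialects: ISO `YYYY[-MM[-DD]]`, legacy `DD-Mmm-YYYY` / `Mmm-YYYY`, and
#' `start/end` ranges, which resolve to the earliest bound at that bound's own
#' precision (conservative for invasion-timeline use). INSDC null tokens
#' ("missing", "not collected", ...), empty strings and `NA` yield `none`.
#' Anything else yields `none` with a parse warning — never a hard failure.
#'
#' @param x Character vector of raw `collection_date` values (NA allowed).
#' @return Tibble with columns `temporal` (ordered factor), `year`, `month`,
#'   `day` (integers at the achieved precision) and `warning` (NA or message).
#' @examples
#' parse_collection_date(c("2019-03-15", "2018", "missing", "2016/2017"))
#' @export
parse_collection_date <- function(x) {
  res <- map(as.character(x), parse_one_date)
  tibble(
    temporal = temporal_factor(map_chr(res, "granularity")),
    year = map_int(res, "year"),
    month = map_int(res, "month"),
    day = map_int(res, "day"),
    warning = map_chr(res, "warning")
  )
}

# ---- spatial ------------------------------------------------------------

parse_one_latlon <- function(x) {
  bad <- list(lat = NA_real_, lon = NA_real_, ok = FALSE)
  if (is_null_value(x)) {
    return(c(bad, list(absent = TRUE)))
  }
  x <- str_squish(x)
  m <- str_match(x, "^(\\d+(?:\\.\\d+)?)\\s*([NSns])[,;]?\\s+(\\d+(?:\\.\\d+)?)\\s*([EWew])$")
  if (!is.na(m[1, 1])) {
    lat <- as.numeric(m[1, 2]) * ifelse(str_to_lower(m[1, 3]) == "s", -1, 1)
    lon <- as.numeric(m[1, 4]) * ifelse(str_to_lower(m[1, 5]) == "w", -1, 1)
  } else {
    m <- str_match(x, "^([+-]?\\d+(?:\\.\\d+)?)[,;]?\\s+([+-]?\\d+(?:\\.\\d+)?)$")
    if (is.na(m[1, 1])) {
      return(c(bad, list(absent = FALSE)))
    }
    lat <- as.numeric(m[1, 2])
    lon <- as.numeric(m[1, 3])
  }
  if (is.na(lat) || is.na(lon) || abs(lat) > 90 || abs(lon) > 180) {
    return(c(bad, list(absent = FALSE)))
  }
  list(lat = lat, lon = lon, ok = TRUE, absent = FALSE)
}

parse_one_location <- function(geo, lat_lon) {
  ll <- parse_one_latlon(lat_lon)
  warning <- NA_character_
  if (!ll$ok && !ll$absent) {
    warning <- paste0("malformed lat_lon: '", str_trim(lat_lon), "'")
  }
  country <- NA_character_
  admin <- NA_character_
  level <- "none"
  if (!is_null_value(geo)) {
    geo <- str_trim(geo)
    pieces <- str_split_fixed(geo, fixed(":"), 2)
    country_part <- str_trim(pieces[1, 1])
    remainder <- str_squish(pieces[1, 2])
    country <- normalize_country(country_part)
    if (nzchar(remainder)) {
      level <- "region_city"
      admin <- remainder
    } else if (country_recognized(country_part)) {
      level <- "country"
    } else {
      warning2 <- paste0("unrecognized geo_loc_name country: '", country_part, "'")
      warning <- if (is.na(warning)) warning2 else paste(warning, warning2, sep = "; ")
      country <- country_part
      level <- "none"
    }
  }
  if (ll$ok) level <- "coordinates" # a valid coordinate pair is always the top level
  list(
    spatial = level, country = country, admin_region = admin,
    latitude = ll$lat, longitude = ll$lon, warning = warning
  )
}

#' Parse geo_loc_name / lat_lon into spatial granularity
#'
#' Resolves a record's location attributes to the ordered scale
#' `none < country < region_city < coordinates`. A valid `lat_lon` (either
#' `"30.61 N 96.34 W"` hemisphere style or a signed decimal pair) always
#' yields `coordinates`; otherwise `geo_loc_name` decides: text after the
#' INSDC country separator (`"Country: place"`) yields `region_city`, a
#' recognizable bare country yields `country`, anything else `none`.
#' Malformed `lat_lon` (including DMS strings) falls back to the
#' `geo_loc_name` level with a parse warning.
#'
#' @param geo_loc_name,lat_lon Character vectors of raw attribute values.
#' @return Tibble: `spatial` (ordered factor), `country` (normalized),
#'   `admin_region`, `latitude`, `longitude` (signed decimal degrees),
#'   `warning`.
#' @examples
#' parse_location("United Kingdom: Wytham Great Wood", NA)
#' parse_location(NA, "30.61 N 96.34 W")
#' @export
parse_location <- function(geo_loc_name, lat_lon) {
  n <- max(length(geo_loc_name), length(lat_lon))
  geo_loc_name <- rep_len(as.character(geo_loc_name), n)
  lat_lon <- rep_len(as.character(lat_lon), n)
  res <- map(seq_len(n), function(i) parse_one_location(geo_loc_name[i], lat_lon[i]))
  tibble(
    spatial = spatial_factor(map_chr(res, "spatial")),
    country = map_chr(res, "country"),
    admin_region = map_chr(res, "admin_region"),
    latitude = vapply(res, function(r) r$latitude, numeric(1)),
    longitude = vapply(res, function(r) r$longitude, numeric(1)),
    warning = map_chr(res, "warning")
  )
}

# ---- origin -------------------------------------------------------------

ORIGIN_PRECEDENCE <- c("commercial", "laboratory", "managed_colony", "field")
ORIGIN_BEARING_KEYS <- c("isolation_source", "strain", "isolate", "sample_name")

#' Origin keyword vocabulary
#'
#' The packaged, editable keyword lists behind [classify_origin()]: a TSV of
#' (class, token) pairs at
#' `system.file("extdata", "origin_vocabulary.tsv", package = "assemblyaudit")`.
#' Keeping the lexicon as data makes the rubric auditable and extensible.
#'
#' @param path Optional alternative vocabulary TSV (columns `class`, `token`).
#' @return Tibble with columns `class` and `token`.
#' @export
origin_vocabulary <- function(path = NULL) {
  if (!is.null(path)) {
    return(readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE))
  }
  if (is.null(the$vocabulary)) {
    the$vocabulary <- readr::read_tsv(aa_extdata("origin_vocabulary.tsv"),
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  the$vocabulary
}

vocab_patterns <- function(vocab) {
  classes <- intersect(ORIGIN_PRECEDENCE, unique(vocab$class))
  stats::setNames(lapply(classes, function(cl) {
    tokens <- vocab$token[vocab$class == cl]
    esc <- gsub("([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1", tokens, perl = TRUE)
    esc <- gsub("[-_ ]+", "[-_ ]+", esc)
    regex(paste0("\\b(", paste(esc, collapse = "|"), ")\\b"), ignore_case = TRUE)
  }), classes)
}

#' Classify sample origin from keyword evidence
#'
#' Scans the origin-bearing attributes (`isolation_source`, `strain`,
#' `isolate`, `sample_name`) for vocabulary tokens and assigns one of
#' `field`, `laboratory`, `commercial`, `managed_colony`, `unknown`. When
#' tokens from two or more classes match, precedence
#' `commercial > laboratory > managed_colony > field` decides (captive
#' propagation outranks founder provenance) and the conflict flag is set.
#' No token match, or all origin-bearing values null/absent, yields
#' `unknown`. Total: never fails.
#'
#' @param attributes A single named character vector of sample attributes, or
#'   a list of such vectors for `classify_origins()`.
#' @param vocab Vocabulary tibble (default the packaged one).
#' @return `classify_origin()`: list with `origin` (factor) and
#'   `conflict_flag`. `classify_origins()`: tibble with those columns, one
#'   row per record.
#' @examples
#' classify_origin(c(isolation_source = "wild caught, pheromone trap"))
#' @export
classify_origin <- function(attributes, vocab = origin_vocabulary()) {
  res <- classify_origins(list(attributes), vocab = vocab)
  list(origin = res$origin[1], conflict_flag = res$conflict_flag[1])
}

#' @rdname classify_origin
#' @export
classify_origins <- function(attributes, vocab = origin_vocabulary()) {
  text <- map_chr(attributes, function(a) {
    vals <- a[names(a) %in% ORIGIN_BEARING_KEYS]
    vals <- vals[!is_null_value(vals)]
    if (length(vals) == 0) NA_character_ else paste(vals, collapse = " | ")
  })
  pats <- vocab_patterns(vocab)
  hits <- vapply(pats, function(p) !is.na(text) & str_detect(text, p), logical(length(text)))
  if (length(text) == 1) hits <- matrix(hits, nrow = 1, dimnames = list(NULL, names(pats)))
  n_hit <- rowSums(hits)
  origin <- rep("unknown", length(text))
  for (cl in rev(names(pats))) origin[hits[, cl]] <- cl # ascending precedence; highest wins
  tibble(origin = origin_factor(origin), conflict_flag = n_hit >= 2)
}

# ---- completeness & composition ----------------------------------------

#' Completeness rubric
#'
#' A record is complete when it provides collection status (origin is not
#' unknown), geographic location to at least country level, and a collection
#' date to at least year level.
#'
#' @param origin Origin class (character or factor).
#' @param spatial,temporal Granularity levels (character or ordered factors).
#' @return Logical vector.
#' @examples
#' assess_completeness("field", "country", "year") # TRUE
#' assess_completeness("unknown", "coordinates", "day") # FALSE
#' @export
assess_completeness <- function(origin, spatial, temporal) {
  if (!is.factor(spatial)) spatial <- spatial_factor(as.character(spatial))
  if (!is.factor(temporal)) temporal <- temporal_factor(as.character(temporal))
  as.character(origin) != "unknown" & spatial >= "country" & temporal >= "year"
}

#' Assess a cohort against the stewardship rubric
#'
#' Runs the full per-record rubric over a cohort tibble: location and date
#' parsing, origin classification, presence flags for tissue /
#' developmental stage / sex (a non-null, non-INSDC-null value counts as
#' present), and the completeness rubric. Deterministic; parse problems
#' surface as warnings in the `parse_warnings` column, never as failures.
#'
#' @param records A cohort tibble from [read_assembly_table()] or
#'   [generate_cohort()].
#' @param vocab Origin vocabulary tibble (default packaged).
#' @return An assessment tibble aligned 1:1 with `records`: `accession`,
#'   `origin`, `origin_source` (`attributes`/`override`/`unresolved`),
#'   `conflict_flag`, `spatial`, `country`, `admin_region`, `latitude`,
#'   `longitude`, `temporal`, `year`, `month`, `day`, `has_tissue`,
#'   `has_dev_stage`, `has_sex`, `complete`, `parse_warnings`.
#' @export
assess_cohort <- function(records, vocab = origin_vocabulary()) {
  attrs <- records$attributes
  loc <- parse_location(attr_chr(attrs, "geo_loc_name"), attr_chr(attrs, "lat_lon"))
  tmp <- parse_collection_date(attr_chr(attrs, "collection_date"))
  org <- classify_origins(attrs, vocab = vocab)
  warnings <- map_chr(seq_len(nrow(records)), function(i) {
    w <- c(loc$warning[i], tmp$warning[i])
    w <- w[!is.na(w)]
    if (length(w) == 0) NA_character_ else paste(w, collapse = "; ")
  })
  tibble(
    accession = records$accession,
    origin = org$origin,
    origin_source = ifelse(as.character(org$origin) == "unknown", "unresolved", "attributes"),
    conflict_flag = org$conflict_flag,
    spatial = loc$spatial,
    country = loc$country,
    admin_region = loc$admin_region,
    latitude = loc$latitude,
    longitude = loc$longitude,
    temporal = tmp$temporal,
    year = tmp$year,
    month = tmp$month,
    day = tmp$day,
    has_tissue = !is_null_value(attr_chr(attrs, "tissue")),
    has_dev_stage = !is_null_value(attr_chr(attrs, "dev_stage")),
    has_sex = !is_null_value(attr_chr(attrs, "sex")),
    complete = assess_completeness(org$origin, loc$spatial, tmp$temporal),
    parse_warnings = warnings
  )
}

#' @rdname assess_cohort
#' @param record A one-row cohort tibble.
#' @export
assess_record <- function(record, vocab = origin_vocabulary()) {
  stopifnot(nrow(record) == 1)
  assess_cohort(record, vocab = vocab)
}

# ---- overrides ----------------------------------------------------------

#' Apply literature-rescue origin overrides
#'
#' Applies curated origin overrides to an assessed cohort, conservatively:
#' only records currently classified `unknown` are touched (repository
#' attributes outrank literature), and each applied override sets
#' `origin_source = "override"` and rescores completeness. Overrides whose
#' accession is absent from the cohort, or that target a non-unknown record,
#' are skipped with a warning row. Range overrides are handled separately by
#' [apply_range_overrides()].
#'
#' @param records Cohort tibble.
#' @param assessments Assessment tibble aligned 1:1 with `records`.
#' @param overrides Override tibble from [read_overrides()].
#' @return List with `assessments` (updated), `rescue` (one-row tibble:
#'   `n_to_field`, `n_to_captive`, `n_remaining_unknown`) and `warnings`
#'   (tibble `accession`, `reason`).
#' @export
apply_overrides <- function(records, assessments, overrides) {
  if (!identical(records$accession, assessments$accession)) {
    abort("records and assessments are not aligned", class = "audit_contract_error")
  }
  warnings <- tibble(accession = character(), reason = character())
  n_to_field <- 0L
  n_to_captive <- 0L
  if (nrow(overrides) > 0) {
    ov <- validate_overrides(overrides)
    ov <- ov[ov$field == "origin", , drop = FALSE]
    for (i in seq_len(nrow(ov))) {
      j <- match(ov$accession[i], assessments$accession)
      if (is.na(j)) {
        warnings <- bind_rows(warnings, tibble(
          accession = ov$accession[i],
          reason = "override accession not in cohort; skipped"
        ))
        next
      }
      if (as.character(assessments$origin[j]) != "unknown") {
        warnings <- bind_rows(warnings, tibble(
          accession = ov$accession[i],
          reason = "override targets a record whose attributes already classify origin; skipped"
        ))
        next
      }
      assessments$origin[j] <- ov$value[i]
      assessments$origin_source[j] <- "override"
      assessments$complete[j] <- assess_completeness(
        assessments$origin[j], assessments$spatial[j], assessments$temporal[j]
      )
      if (ov$value[i] == "field") {
        n_to_field <- n_to_field + 1L
      } else {
        n_to_captive <- n_to_captive + 1L
      }
    }
  }
  list(
    assessments = assessments,
    rescue = tibble(
      n_to_field = n_to_field,
      n_to_captive = n_to_captive,
      n_remaining_unknown = sum(as.character(assessments$origin) == "unknown")
    ),
    warnings = warnings
  )
}
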