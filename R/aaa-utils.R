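# Shared enum definitions, rounding and INSDC null-token handling.

ORIGIN_LEVELS <- c("field", "laboratory", "commercial", "managed_colony", "unknown")
SPATIAL_LEVELS <- c("none", "country", "region_city", "coordinates")
TEMPORAL_LEVELS <- c("none", "year", "month", "day")
ASSEMBLY_LEVELS <- c("contig", "scaffold", "chromosome")
RANGE_LEVELS <- c("native", "expanded", "undetermined", "not_applicable")
INCOME_LEVELS <- c("high_income", "other", "unresolved")

origin_factor <- function(x) factor(x, levels = ORIGIN_LEVELS)

#' Ordered spatial granularity factor
#'
#' Spatial granularity of a sample's collection location is an ordered scale:
#' `none < country < region_city < coordinates`. Ordered factors make
#' threshold comparisons such as `spatial >= "country"` direct.
#'
#' @param x Character vector of level names.
#' @return An ordered factor.
#' @export
spatial_factor <- function(x) factor(x, levels = SPATIAL_LEVELS, ordered = TRUE)

#' Ordered temporal granularity factor
#'
#' Collection-date precision on the ordered scale `none < year < month < day`.
#'
#' @param x Character vector of level names.
#' @return An ordered factor.
#' @export
temporal_factor <- function(x) factor(x, levels = TEMPORAL_LEVELS, ordered = TRUE)

range_factor <- function(x) factor(x, levels = RANGE_LEVELS)

# Package data caches (alias table, vocabulary, null tokens).
the <- new.env(parent = emptyenv())

aa_extdata <- function(file) {
  path <- system.file("extdata", file, package = "assemblyaudit")
  if (!nzchar(path)) {
    # during in-source development (pkgload) system.file already handles inst/
    abort(paste0("packaged data file not found: ", file), class = "audit_internal_error")
  }
  path
}

#' INSDC null tokens
#'
#' The standardized placeholder strings submitters use for absent attribute
#' values ("missing", "not collected", ...). Any attribute whose value is one
#' of these tokens (case-insensitive), or is empty/NA, is treated exactly like
#' an absent attribute throughout the rubric.
#'
#' @return Character vector of null tokens.
#' @export
insdc_null_tokens <- function() {
  if (is.null(the$null_tokens)) {
    the$null_tokens <- readr::read_lines(aa_extdata("insdc_null_tokens.txt"))
  }
  the$null_tokens
}

# TRUE where the value counts as absent: NA, empty/whitespace, or a null token.
is_null_value <- function(x) {
  x <- str_trim(x)
  is.na(x) | x == "" | str_to_lower(x) %in% insdc_null_tokens()
}

# Round half away from zero (R's round() is half-to-even). This is the rule
# used for every reported percentage: it reproduces printed figures such as
# 38 from 76/199 at zero decimals.
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Rounded percentage
#'
#' `100 * numerator / denominator`, rounded half away from zero to the given
#' number of decimals — the rounding convention used for every percentage this
#' package reports.
#'
#' @param numerator,denominator Non-negative counts with
#'   `0 <= numerator <= denominator` and `denominator > 0`.
#' @param decimals Number of decimal places (default 1).
#' @return A numeric percentage on the 0–100 scale.
#' @examples
#' percent(76, 199, 0) # 38
#' percent(27, 76, 1)  # 35.5
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) {
    abort("percentage undefined: denominator must be > 0", class = "audit_value_error")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    abort("numerator must lie in [0, denominator]", class = "audit_value_error")
  }
  round_half_away(100 * numerator / denominator, decimals)
}

# Extract one attribute across a cohort's attribute list-column.
attr_chr <- function(attributes, key) {
  map_chr(attributes, function(a) {
    i <- match(key, names(a))
    if (is.na(i)) NA_character_ else as.character(a[[i]])
  })
}

# Normalize attribute keys to lower snake case (done exactly once, at ingest).
normalize_keys <- function(keys) {
  k <- str_to_lower(str_trim(keys))
  k <- gsub("[^a-z0-9]+", "_", k)
  gsub("^_+|_+$", "", k)
}
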