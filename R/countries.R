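# Country-name normalization against the packaged alias table.
# §: unmatched names are passed through unchanged and flagged, never dropped —
# the audit must surface, not hide, unparseable geography.

#' Country alias table
#'
#' The packaged alias table mapping common spellings ("USA", "UK",
#' "United States of America") onto one canonical country name per country.
#' Users can inspect it to see which spellings are recognized; the file lives
#' at `system.file("extdata", "country_aliases.tsv", package = "assemblyaudit")`
#' and is intentionally editable data, not code.
#'
#' @return A tibble with columns `alias` and `country`.
#' @export
country_aliases <- function() {
  if (is.null(the$aliases)) {
    the$aliases <- readr::read_tsv(aa_extdata("country_aliases.tsv"),
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  the$aliases
}

#' Normalize country names
#'
#' Maps each name onto its canonical form via the packaged alias table
#' (case-insensitive). Names with no alias entry are returned unchanged
#' (surrounding whitespace stripped); use [country_recognized()] to flag them.
#'
#' @param x Character vector of country names.
#' @return Character vector of canonical (or passed-through) names.
#' @export
normalize_country <- function(x) {
  al <- country_aliases()
  x <- str_trim(x)
  idx <- match(str_to_lower(x), al$alias)
  out <- ifelse(is.na(idx), x, al$country[idx])
  out[is.na(x)] <- NA_character_
  out
}

#' @rdname normalize_country
#' @return For `country_recognized()`, a logical vector: TRUE where the name
#'   matched the alias table.
#' @export
country_recognized <- function(x) {
  !is.na(x) & str_to_lower(str_trim(x)) %in% country_aliases()$alias
}
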