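# In-code fixture builders and independent brute-force oracles.

make_record <- function(accession = "GCA_000000001.1",
                        species = "Drosophila suzukii",
                        taxonomic_order = "Diptera",
                        assembly_level = "scaffold",
                        submission_date = as.Date("2020-05-01"),
                        is_reference = FALSE,
                        sra_linked = TRUE,
                        ...) {
  attrs <- c(...)
  if (is.null(attrs)) attrs <- character()
  tibble::tibble(
    accession = accession, species = species, taxonomic_order = taxonomic_order,
    assembly_level = factor(assembly_level, levels = c("contig", "scaffold", "chromosome")),
    submission_date = submission_date,
    submitter_institute = "Test Institute", submitter_country = "United States",
    is_reference = is_reference, sra_linked = sra_linked,
    attributes = list(attrs)
  )
}

make_cohort <- function(...) {
  dplyr::bind_rows(...)
}

# Independent oracle for the date-range rule: parse both bounds with a
# minimal ISO-only parser, take the chronological minimum.
oracle_range_date <- function(raw) {
  parse_iso <- function(s) {
    s <- trimws(s)
    p <- as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
    list(year = p[1], month = if (length(p) >= 2) p[2] else NA_integer_,
         day = if (length(p) >= 3) p[3] else NA_integer_)
  }
  bounds <- lapply(strsplit(raw, "/", fixed = TRUE)[[1]], parse_iso)
  keys <- vapply(bounds, function(b) {
    b$year * 10000 + ifelse(is.na(b$month), 1, b$month) * 100 + ifelse(is.na(b$day), 1, b$day)
  }, numeric(1))
  b <- bounds[[which.min(keys)]]
  gran <- if (!is.na(b$day)) "day" else if (!is.na(b$month)) "month" else "year"
  c(granularity = gran, year = b$year)
}

# Independent oracle for origin precedence: enumerate every token match over
# the combined origin-bearing text, then pick by the precedence list.
oracle_origin <- function(attrs, vocab = assemblyaudit::origin_vocabulary()) {
  keys <- c("isolation_source", "strain", "isolate", "sample_name")
  text <- paste(attrs[names(attrs) %in% keys], collapse = " | ")
  matched <- unique(vocab$class[vapply(seq_len(nrow(vocab)), function(i) {
    grepl(paste0("\\b", gsub(" ", "[-_ ]+", vocab$token[i]), "\\b"), text, ignore.case = TRUE)
  }, logical(1))])
  precedence <- c("commercial", "laboratory", "managed_colony", "field")
  hit <- precedence[precedence %in% matched]
  list(
    origin = if (length(hit) == 0) "unknown" else hit[1],
    conflict = length(matched) >= 2
  )
}

# Independent brute-force dual-range scan: per species, check the existence
# of one field record in the native countries and one in the expanded
# countries by raw set membership (valid for gazetteers without the
# both-sets country case).
brute_dual_range <- function(records, assessments, gazetteer) {
  out <- character()
  for (s in unique(records$species)) {
    nat <- gazetteer$country[gazetteer$species == s & gazetteer$status == "native"]
    exp <- gazetteer$country[gazetteer$species == s & gazetteer$status == "expanded"]
    idx <- which(records$species == s &
      as.character(assessments$origin) == "field" &
      as.character(assessments$spatial) != "none")
    ctry <- assessments$country[idx]
    if (any(ctry %in% setdiff(nat, exp)) && any(ctry %in% setdiff(exp, nat))) {
      out <- c(out, s)
    }
  }
  sort(out)
}

write_tsv_file <- function(df, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(df, path, progress = FALSE)
  path
}
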