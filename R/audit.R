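# End-to-end audit surface: audit -> rescue -> range -> summarize, plus the
# report writer used by the command-line wrapper (inst/scripts/audit.R).

#' Audit a cohort end to end
#'
#' Composes the full workflow: rubric assessment, literature-rescue origin
#' overrides, native/expanded range classification (with range overrides),
#' and the cohort summary. Deterministic for fixed inputs.
#'
#' @param records Cohort tibble from [read_assembly_table()] or
#'   [generate_cohort()].
#' @param gazetteer Optional gazetteer tibble; without it the range stage is
#'   skipped.
#' @param overrides Optional override tibble ([read_overrides()]).
#' @param income_table Optional income tibble ([read_income_table()]).
#' @param cohort_label Label recorded on the summary.
#' @param decimals Percentage precision.
#' @param vocab Origin vocabulary tibble.
#' @return A `cohort_audit` object: list with `records`, `assessments`
#'   (post-override), `ranges` (or NULL), `rescue`, `summary`
#'   (a `cohort_summary`) and `warnings` (aggregated parse/override
#'   warnings, one row per issue — the visible manual-curation debt).
#' @export
audit_cohort <- function(records, gazetteer = NULL, overrides = NULL,
                         income_table = NULL,
                         cohort_label = c("assembly", "reference", "field_subset"),
                         decimals = 1, vocab = origin_vocabulary()) {
  cohort_label <- match.arg(cohort_label)
  assessments <- assess_cohort(records, vocab = vocab)
  warnings <- assessments |>
    filter(!is.na(.data$parse_warnings)) |>
    select("accession", reason = "parse_warnings")
  rescue <- NULL
  if (!is.null(overrides) && nrow(overrides) > 0) {
    res <- apply_overrides(records, assessments, overrides)
    assessments <- res$assessments
    rescue <- res$rescue
    warnings <- bind_rows(warnings, res$warnings)
  }
  ranges <- NULL
  if (!is.null(gazetteer)) {
    ranges <- classify_ranges(records, assessments, gazetteer)
    if (!is.null(overrides) && nrow(overrides) > 0) {
      rr <- apply_range_overrides(ranges, overrides)
      ranges <- rr$ranges
      warnings <- bind_rows(warnings, rr$warnings)
    }
  }
  summary <- summarize_cohort(records, assessments,
    ranges = ranges,
    income_table = income_table, cohort_label = cohort_label, decimals = decimals
  )
  structure(
    list(
      records = records, assessments = assessments, ranges = ranges,
      rescue = rescue, summary = summary, warnings = warnings
    ),
    class = "cohort_audit"
  )
}

#' @export
print.cohort_audit <- function(x, ...) {
  cat("<cohort_audit> n =", nrow(x$records), "records\n")
  print(glance(x))
  invisible(x)
}

#' Per-record tidy view of an audit
#'
#' @param x A `cohort_audit`.
#' @param ... Unused.
#' @return One row per assembly: the assessment columns joined with species,
#'   submission metadata and (when computed) range status.
#' @export
tidy.cohort_audit <- function(x, ...) {
  out <- x$records |>
    select("accession", "species", "taxonomic_order", "assembly_level",
      "submission_date", "is_reference", "sra_linked") |>
    left_join(x$assessments, by = "accession")
  if (!is.null(x$ranges)) {
    out <- left_join(out, select(x$ranges, "accession", "range_status"), by = "accession")
  }
  out
}

#' One-row overview of an audit
#'
#' @param x A `cohort_audit`.
#' @param ... Unused.
#' @return One-row tibble: headline counts/percentages plus the number of
#'   dual-range species when the range stage ran.
#' @export
glance.cohort_audit <- function(x, ...) {
  g <- glance(x$summary)
  if (!is.null(x$ranges)) {
    dual <- x$ranges |>
      filter(.data$range_status %in% c("native", "expanded")) |>
      group_by(.data$species) |>
      summarise(
        dual = any(.data$range_status == "native") && any(.data$range_status == "expanded"),
        .groups = "drop"
      )
    g$n_dual_range_species <- sum(dual$dual)
  }
  g
}

#' Write audit report files
#'
#' Writes the per-record assessment TSV, range TSV (when computed), the long
#' partition table, per-year series, a warnings TSV and a machine-readable
#' `summary.json` carrying the provenance block (cohort label, n, income
#' threshold, package version, timestamp). Output is byte-stable across runs
#' on identical input except for the timestamp field.
#'
#' @param audit A `cohort_audit`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_audit_report <- function(audit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    assessments = file.path(dir, "assessments.tsv"),
    partitions = file.path(dir, "partitions.tsv"),
    per_year = file.path(dir, "per_year.tsv"),
    warnings = file.path(dir, "warnings.tsv"),
    summary = file.path(dir, "summary.json")
  )
  readr::write_tsv(tidy(audit), paths[["assessments"]], progress = FALSE)
  readr::write_tsv(audit$summary$partitions, paths[["partitions"]], progress = FALSE)
  readr::write_tsv(audit$summary$per_year, paths[["per_year"]], progress = FALSE)
  readr::write_tsv(audit$warnings, paths[["warnings"]], progress = FALSE)
  if (!is.null(audit$ranges)) {
    paths[["ranges"]] <- file.path(dir, "ranges.tsv")
    readr::write_tsv(audit$ranges, paths[["ranges"]], progress = FALSE)
    paths[["geo_points"]] <- file.path(dir, "geo_points.tsv")
    geo <- tidy(audit) |>
      filter(!is.na(.data$latitude)) |>
      select("accession", lat = "latitude", lon = "longitude", "range_status")
    readr::write_tsv(geo, paths[["geo_points"]], progress = FALSE)
  }
  summary_doc <- list(
    cohort_label = audit$summary$cohort_label,
    n = audit$summary$n,
    glance = as.list(glance(audit)),
    rescue = if (is.null(audit$rescue)) NULL else as.list(audit$rescue),
    provenance = c(audit$summary$provenance, list(timestamp = format(Sys.time(), tz = "UTC")))
  )
  jsonlite::write_json(summary_doc, paths[["summary"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full audit from input files
#'
#' The programmatic core behind the command-line wrapper: reads the canonical
#' inputs, audits, and writes the report directory. Any ingest error aborts
#' before any output is written — no partial summaries.
#'
#' @param assembly_path Canonical assembly TSV (or records_json file).
#' @param out_dir Report output directory.
#' @param attributes_path,gazetteer_path,overrides_path,income_path Optional
#'   input files.
#' @param dialect Assembly-table dialect.
#' @param cohort_label,decimals Passed to [audit_cohort()].
#' @param vocabulary_path Optional alternative origin vocabulary TSV.
#' @return The `cohort_audit`, invisibly.
#' @export
run_audit <- function(assembly_path, out_dir,
                      attributes_path = NULL, gazetteer_path = NULL,
                      overrides_path = NULL, income_path = NULL,
                      dialect = "canonical_tsv",
                      cohort_label = "assembly", decimals = 1,
                      vocabulary_path = NULL) {
  records <- read_assembly_table(assembly_path, dialect = dialect, attributes_path = attributes_path)
  gazetteer <- if (!is.null(gazetteer_path)) read_home_ranges(gazetteer_path)
  overrides <- if (!is.null(overrides_path)) read_overrides(overrides_path)
  income <- if (!is.null(income_path)) read_income_table(income_path)
  audit <- audit_cohort(records,
    gazetteer = gazetteer, overrides = overrides,
    income_table = income, cohort_label = cohort_label, decimals = decimals,
    vocab = if (is.null(vocabulary_path)) origin_vocabulary() else origin_vocabulary(vocabulary_path)
  )
  write_audit_report(audit, out_dir)
  invisible(audit)
}
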