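# Cohort-level aggregation: category partitions with rounded percentages,
# per-year deposition/completeness series, per-order and per-species
# composition, and income-group classification.

#' Classify a country into an income group
#'
#' `high_income` iff GNI per capita strictly exceeds the table's threshold
#' ("exceeds", so equality falls into `other`); countries absent from the
#' table are `unresolved`.
#'
#' @param country Character vector of country names (normalized internally).
#' @param income_table Tibble from [read_income_table()] (columns `country`,
#'   `gni_per_capita`; attribute `threshold`).
#' @param threshold Override for the table's threshold attribute.
#' @return Factor with levels high_income/other/unresolved.
#' @export
classify_income <- function(country, income_table,
                            threshold = attr(income_table, "threshold") %||% 12055) {
  gni <- income_table$gni_per_capita[match(normalize_country(country), income_table$country)]
  out <- ifelse(is.na(gni), "unresolved", ifelse(gni > threshold, "high_income", "other"))
  factor(out, levels = INCOME_LEVELS)
}

#' Per-year deposition and completeness series
#'
#' Tabulates, by submission year, the number of field-collected assemblies
#' versus "other" (the union of laboratory, commercial, managed-colony and
#' unknown origins), together with the number of rubric-complete records.
#' Years inside the cohort's span with no submissions are emitted with zeros.
#'
#' @param records Cohort tibble.
#' @param assessments Aligned assessment tibble.
#' @return Tibble `year`, `field`, `other`, `complete`, `n`.
#' @export
tabulate_by_year <- function(records, assessments) {
  if (!identical(records$accession, assessments$accession)) {
    abort("records and assessments are not aligned", class = "audit_contract_error")
  }
  yr <- as.integer(format(records$submission_date, "%Y"))
  per <- tibble(
    year = yr,
    is_field = as.character(assessments$origin) == "field",
    complete = assessments$complete
  ) |>
    group_by(.data$year) |>
    summarise(
      field = sum(.data$is_field),
      other = sum(!.data$is_field),
      complete = sum(.data$complete),
      n = n(),
      .groups = "drop"
    )
  span <- tibble(year = seq(min(yr), max(yr)))
  span |>
    left_join(per, by = "year") |>
    mutate(across(c("field", "other", "complete", "n"), ~ tidyr::replace_na(.x, 0L))) |>
    arrange(.data$year)
}

#' Extract a named cohort subset
#'
#' The audit reports on three cohorts: the full `assembly` dataset, the
#' `reference` subset (records flagged as the species' reference genome) and
#' the `field_subset` (records whose assessed origin is field).
#'
#' @param records Cohort tibble.
#' @param assessments Aligned assessment tibble.
#' @param which `"assembly"`, `"reference"` or `"field_subset"`.
#' @return List with aligned, filtered `records` and `assessments`.
#' @export
cohort_subset <- function(records, assessments,
                          which = c("assembly", "reference", "field_subset")) {
  which <- match.arg(which)
  keep <- switch(which,
    assembly = rep(TRUE, nrow(records)),
    reference = records$is_reference,
    field_subset = as.character(assessments$origin) == "field"
  )
  list(records = records[keep, , drop = FALSE], assessments = assessments[keep, , drop = FALSE])
}

partition_tibble <- function(name, values, levels, denominator, decimals) {
  x <- factor(as.character(values), levels = levels)
  cnt <- table(x)
  tibble(
    partition = name,
    category = names(cnt),
    n = as.integer(cnt),
    pct = percent(as.integer(cnt), denominator, decimals)
  )
}

#' Summarize an assessed cohort
#'
#' Aggregates per-record assessments (and optionally range statuses and an
#' income table) into the cohort-level report: every category partition with
#' raw counts and rounded percentages, the per-year series, per-order and
#' per-species composition. Counts in each partition sum to the cohort size
#' (the range partition counts non-field records as `not_applicable`);
#' percentages use the half-away-from-zero rule at `decimals` places. Both
#' counts and percentages are always emitted so rounding never hides data.
#'
#' @param records Cohort tibble.
#' @param assessments Aligned assessment tibble (post-override if overrides
#'   were applied).
#' @param ranges Optional range tibble from [classify_ranges()].
#' @param income_table Optional tibble from [read_income_table()]; income
#'   groups are classified from `submitter_country`.
#' @param cohort_label `"assembly"`, `"reference"` or `"field_subset"` — a
#'   label recorded in the summary, not a filter (use [cohort_subset()]).
#' @param decimals Percentage precision (default 1).
#' @return A `cohort_summary` object: list with `cohort_label`, `n`,
#'   `partitions`, `per_year`, `per_order`, `per_species`, `provenance`.
#' @export
summarize_cohort <- function(records, assessments, ranges = NULL,
                             income_table = NULL,
                             cohort_label = c("assembly", "reference", "field_subset"),
                             decimals = 1) {
  cohort_label <- match.arg(cohort_label)
  if (!identical(records$accession, assessments$accession)) {
    abort("records and assessments are not aligned", class = "audit_contract_error")
  }
  n <- nrow(records)
  if (n == 0) {
    abort("cannot summarize an empty cohort", class = "audit_value_error")
  }
  parts <- bind_rows(
    partition_tibble("origin", assessments$origin, ORIGIN_LEVELS, n, decimals),
    partition_tibble("assembly_level", records$assembly_level, ASSEMBLY_LEVELS, n, decimals),
    partition_tibble("spatial", assessments$spatial, SPATIAL_LEVELS, n, decimals),
    partition_tibble("temporal", assessments$temporal, TEMPORAL_LEVELS, n, decimals),
    partition_tibble("complete", assessments$complete, c("TRUE", "FALSE"), n, decimals),
    partition_tibble("sra_linked", records$sra_linked, c("TRUE", "FALSE"), n, decimals),
    partition_tibble("has_tissue", assessments$has_tissue, c("TRUE", "FALSE"), n, decimals),
    partition_tibble("has_dev_stage", assessments$has_dev_stage, c("TRUE", "FALSE"), n, decimals),
    partition_tibble("has_sex", assessments$has_sex, c("TRUE", "FALSE"), n, decimals)
  )
  if (!is.null(ranges)) {
    if (!identical(ranges$accession, records$accession)) {
      abort("records and ranges are not aligned", class = "audit_contract_error")
    }
    parts <- bind_rows(
      parts,
      partition_tibble("range", ranges$range_status, RANGE_LEVELS, n, decimals)
    )
  }
  threshold <- NULL
  if (!is.null(income_table)) {
    threshold <- attr(income_table, "threshold") %||% 12055
    grp <- classify_income(records$submitter_country, income_table, threshold)
    parts <- bind_rows(
      parts,
      partition_tibble("income_group", grp, INCOME_LEVELS, n, decimals)
    )
  }
  per_order <- records |>
    group_by(taxonomic_order = .data$taxonomic_order) |>
    summarise(n_species = n_distinct(.data$species), n_assemblies = n(), .groups = "drop") |>
    arrange(.data$taxonomic_order)
  per_species <- records |>
    count(.data$species, name = "n_assemblies") |>
    arrange(.data$species)
  structure(
    list(
      cohort_label = cohort_label,
      n = n,
      partitions = parts,
      per_year = tabulate_by_year(records, assessments),
      per_order = per_order,
      per_species = per_species,
      decimals = decimals,
      provenance = list(
        income_threshold = threshold,
        n_field = sum(as.character(assessments$origin) == "field"),
        package_version = as.character(utils::packageVersion("assemblyaudit"))
      )
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$cohort_label, " cohort, n = ", x$n, "\n", sep = "")
  key <- x$partitions |> filter(.data$partition %in% c("origin", "complete"))
  for (i in seq_len(nrow(key))) {
    cat(sprintf(
      "  %-14s %-15s %4d (%s%%)\n",
      key$partition[i], key$category[i], key$n[i], format(key$pct[i])
    ))
  }
  invisible(x)
}

#' Tidy a cohort summary into its partition table
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return The long partition tibble (`partition`, `category`, `n`, `pct`).
#' @export
tidy.cohort_summary <- function(x, ...) {
  x$partitions
}

#' One-row overview of a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return One-row tibble with the headline counts and percentages.
#' @export
glance.cohort_summary <- function(x, ...) {
  g <- function(p, cat) {
    row <- x$partitions[x$partitions$partition == p & x$partitions$category == cat, ]
    c(row$n[1], row$pct[1])
  }
  fo <- g("origin", "field")
  fu <- g("origin", "unknown")
  fc <- g("complete", "TRUE")
  crd <- g("spatial", "coordinates")
  tibble(
    cohort_label = x$cohort_label,
    n = x$n,
    n_field = as.integer(fo[1]), pct_field = fo[2],
    n_unknown = as.integer(fu[1]), pct_unknown = fu[2],
    n_complete = as.integer(fc[1]), pct_complete = fc[2],
    n_coordinates = as.integer(crd[1]), pct_coordinates = crd[2]
  )
}
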