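#' Missingness statistics for a patient field table
#'
#' Quantifies how much of a field table is unspecified: total and missing cell
#' counts, the overall missing fraction, per-field missing counts, the fields
#' that are never missing, and the mean number of missing fields per record.
#' Missing cells are `NA`, the empty string or `"not specified"`
#' (case-insensitive). Fractions are kept at full precision internally;
#' rendered reports show them to 2 decimals.
#'
#' @param table A `data.frame` with a `patient_id` column; all other columns
#'   are fields.
#' @return An object of class `missingness_stats` with fields `total_cells`,
#'   `missing_cells`, `missing_fraction`, `per_field_missing`,
#'   `always_known_fields`, `mean_missing_per_record`, `n_patients`,
#'   `n_fields`.
#' @examples
#' tab <- data.frame(patient_id = c("a", "b", "c"),
#'                   x = c(1, NA, 3), y = c(NA, NA, "not specified"))
#' missingness_stats(tab)
#' @export
missingness_stats <- function(table) {
  stopifnot(is.data.frame(table), "patient_id" %in% names(table))
  fields <- setdiff(names(table), "patient_id")
  if (nrow(table) == 0 || length(fields) == 0) {
    stop("missingness is undefined on an empty table", call. = FALSE)
  }
  miss <- matrix(FALSE, nrow(table), length(fields),
                 dimnames = list(NULL, fields))
  for (f in fields) miss[, f] <- is_missing_cell(table[[f]])
  per_field <- stats::setNames(as.integer(colSums(miss)), fields)
  total <- nrow(table) * length(fields)
  missing <- sum(per_field)
  structure(list(
    total_cells = total,
    missing_cells = missing,
    missing_fraction = missing / total,
    per_field_missing = per_field,
    always_known_fields = fields[per_field == 0],
    mean_missing_per_record = missing / nrow(table),
    n_patients = nrow(table),
    n_fields = length(fields)
  ), class = "missingness_stats")
}

#' @export
print.missingness_stats <- function(x, ...) {
  cat(sprintf("%d patients x %d fields: %d of %d values missing (%.2f%%)\n",
              x$n_patients, x$n_fields, x$missing_cells, x$total_cells,
              100 * x$missing_fraction))
  cat(sprintf("mean missing fields per record: %.2f (of %d)\n",
              x$mean_missing_per_record, x$n_fields))
  cat(sprintf("fields never missing: %d\n", length(x$always_known_fields)))
  invisible(x)
}

#' Per-trial field report
#'
#' For each trial, reports how its bound fields behave in a patient field
#' table: the number of fields referenced by the rules of its inclusion
#' criteria, of its exclusion criteria, and by both sides (*common* fields);
#' the missing-value fraction restricted to the trial's fields; and how many
#' patients have all inclusion fields, all exclusion fields, and all fields
#' known. Criteria without a binding rule contribute no field.
#'
#' @param trials List of validated [trial_definition()]s (or one trial).
#' @param rules List of [binding_rule()]s mapping criteria to fields.
#' @param table A `data.frame` field table with `patient_id`.
#' @return An object of class `trial_field_report`: a list with one entry per
#'   trial, each holding `trial_id`, `n_inclusion_fields`,
#'   `n_exclusion_fields`, `n_common_fields`, `missing_fraction`,
#'   `n_patients_all_inclusion_known`, `n_patients_all_exclusion_known`,
#'   `n_patients_all_known`.
#' @export
trial_field_report <- function(trials, rules, table) {
  if (inherits(trials, "trial_definition")) trials <- list(trials)
  lapply(trials, assert_validated_trial)
  stopifnot(is.data.frame(table), "patient_id" %in% names(table))
  rule_fields <- stats::setNames(
    vapply(rules, function(r) r$field, character(1)),
    vapply(rules, function(r) r$criterion_id, character(1))
  )
  absent <- setdiff(unname(rule_fields), names(table))
  if (length(absent)) {
    stop("binding rule(s) reference column(s) absent from the table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  fields_all <- setdiff(names(table), "patient_id")
  known <- matrix(TRUE, nrow(table), length(fields_all),
                  dimnames = list(NULL, fields_all))
  for (f in fields_all) known[, f] <- !is_missing_cell(table[[f]])

  blocks <- lapply(trials, function(trial) {
    inc_fields <- unique(unname(rule_fields[intersect(trial$inclusion, names(rule_fields))]))
    exc_fields <- unique(unname(rule_fields[intersect(trial$exclusion, names(rule_fields))]))
    all_fields <- union(inc_fields, exc_fields)
    all_known_over <- function(fields) {
      if (!length(fields)) return(nrow(table))
      sum(rowSums(known[, fields, drop = FALSE]) == length(fields))
    }
    miss_frac <- if (length(all_fields)) {
      1 - sum(known[, all_fields, drop = FALSE]) / (nrow(table) * length(all_fields))
    } else NA_real_
    list(trial_id = trial$trial_id,
         n_inclusion_fields = length(inc_fields),
         n_exclusion_fields = length(exc_fields),
         n_common_fields = length(intersect(inc_fields, exc_fields)),
         missing_fraction = miss_frac,
         n_patients_all_inclusion_known = all_known_over(inc_fields),
         n_patients_all_exclusion_known = all_known_over(exc_fields),
         n_patients_all_known = all_known_over(all_fields))
  })
  names(blocks) <- vapply(trials, function(t) t$trial_id, character(1))
  structure(blocks, class = "trial_field_report")
}

#' @export
print.trial_field_report <- function(x, ...) {
  rows <- c("Nb inclusion fields", "Nb exclusion fields", "Nb common fields",
            "Missing values", "Nb patients with all inclusion fields known",
            "Nb patients with all exclusion fields known",
            "Nb patients with all fields known")
  cells <- vapply(unclass(x), function(b) c(
    b$n_inclusion_fields, b$n_exclusion_fields, b$n_common_fields,
    if (is.na(b$missing_fraction)) NA else round(100 * b$missing_fraction, 2),
    b$n_patients_all_inclusion_known, b$n_patients_all_exclusion_known,
    b$n_patients_all_known), numeric(7))
  cells <- matrix(cells, nrow = 7, dimnames = list(rows, names(x)))
  fmt <- format(cells)
  fmt[4, ] <- ifelse(is.na(cells[4, ]), "-", sprintf("%.2f%%", cells[4, ]))
  print(as.data.frame(fmt), right = TRUE)
  invisible(x)
}

#' Screening report for a classified cohort
#'
#' Assembles the human-facing outcome of a pre-screening run: counts per
#' decision (rendered as "eligible", "not eligible" and "potentially
#' eligible"), for every potentially-eligible patient the exact criteria that
#' must be sought, for every rejected patient the causing criteria, and the
#' set of patients a closed-world policy would over-reject.
#'
#' @param classification A [classify_cohort()] result.
#' @param conflicts Character vector of over-rejected patient ids, from
#'   [compare_policies()] (optional).
#' @return An object of class `screening_report`; see
#'   [render_screening_report()] for the plain-text rendering and
#'   [screening_report_json()] for the JSON document.
#' @export
screening_report <- function(classification, conflicts = character()) {
  stopifnot(inherits(classification, "cohort_classification"))
  res <- classification$results
  pick <- function(decision) Filter(function(r) r$decision == decision, res)
  structure(list(
    trial_id = classification$trial_id,
    n_patients = length(res),
    counts = list(
      eligible = unname(classification$counts[["ELIGIBLE"]]),
      not_eligible = unname(classification$counts[["NOT_ELIGIBLE"]]),
      potentially_eligible = unname(classification$counts[["UNDETERMINED"]])
    ),
    potentially_eligible = lapply(pick("UNDETERMINED"), function(r) list(
      patient_id = r$patient_id,
      missing_criteria = c(r$unknown_inclusions, r$unknown_exclusions)
    )),
    not_eligible = lapply(pick("NOT_ELIGIBLE"), function(r) list(
      patient_id = r$patient_id,
      failed_inclusions = r$failed_inclusions,
      matched_exclusions = r$matched_exclusions
    )),
    eligible = vapply(pick("ELIGIBLE"), function(r) r$patient_id, character(1)),
    closed_world_over_rejected = as.character(conflicts)
  ), class = "screening_report")
}

#' Render a screening report as plain text
#'
#' @param report A [screening_report()].
#' @return Character vector of lines.
#' @export
render_screening_report <- function(report) {
  stopifnot(inherits(report, "screening_report"))
  pct <- function(k) {
    if (report$n_patients == 0) "0.00%" else
      sprintf("%.2f%%", 100 * k / report$n_patients)
  }
  lines <- c(
    sprintf("Screening report for trial '%s' (%d patients)",
            report$trial_id, report$n_patients),
    sprintf("  eligible:             %d (%s)", report$counts$eligible,
            pct(report$counts$eligible)),
    sprintf("  not eligible:         %d (%s)", report$counts$not_eligible,
            pct(report$counts$not_eligible)),
    sprintf("  potentially eligible: %d (%s)",
            report$counts$potentially_eligible,
            pct(report$counts$potentially_eligible))
  )
  if (length(report$potentially_eligible)) {
    lines <- c(lines, "Potentially eligible patients (criteria to seek):")
    for (p in report$potentially_eligible) {
      lines <- c(lines, sprintf("  %s: missing %s", p$patient_id,
                                paste(p$missing_criteria, collapse = ", ")))
    }
  }
  if (length(report$not_eligible)) {
    lines <- c(lines, "Not eligible patients (cause):")
    for (p in report$not_eligible) {
      cause <- c(if (length(p$failed_inclusions))
                   paste0("failed inclusion ", paste(p$failed_inclusions, collapse = ", ")),
                 if (length(p$matched_exclusions))
                   paste0("matched exclusion ", paste(p$matched_exclusions, collapse = ", ")))
      lines <- c(lines, sprintf("  %s: %s", p$patient_id,
                                paste(cause, collapse = "; ")))
    }
  }
  if (length(report$closed_world_over_rejected)) {
    lines <- c(lines, paste0(
      "Patients a closed-world policy would over-reject: ",
      paste(report$closed_world_over_rejected, collapse = ", ")))
  }
  lines
}

#' @export
print.screening_report <- function(x, ...) {
  cat(render_screening_report(x), sep = "\n")
  invisible(x)
}

#' Screening report as a JSON document
#'
#' @param report A [screening_report()].
#' @return A single JSON string; it round-trips through
#'   `jsonlite::fromJSON()` without loss.
#' @export
screening_report_json <- function(report) {
  stopifnot(inherits(report, "screening_report"))
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, null = "null",
                   pretty = TRUE)
}
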