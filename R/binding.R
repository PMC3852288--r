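#' Binding rules: from raw patient fields to criterion statuses
#'
#' A binding rule derives the three-valued status of one atomic criterion from
#' one column of a raw patient field table. The rule language is deliberately
#' small: a field name, a comparator and (for most comparators) an operand.
#' Complex criteria are decomposed by the user into one rule per atomic
#' condition and combined at trial level.
#'
#' Comparators:
#' * `eq`, `ne` — equality / inequality after type-faithful coercion (numeric
#'   if both sides parse as numbers, string comparison otherwise);
#' * `lt`, `le`, `gt`, `ge` — numeric order comparisons; the operand must be
#'   numeric and a non-numeric cell is a data error;
#' * `in`, `not_in` — set membership, operand is a vector;
#' * `present`, `absent` — tests whether the field itself carries a value;
#'   these always decide, even on a missing cell.
#'
#' For every comparator except `present`/`absent`, a missing cell yields an
#' unknown status (`NA`): the record does not say, so the criterion status
#' cannot be computed. Recognized missing-cell encodings are `NA`, the empty
#' string and `"not specified"` (case-insensitive), matching case-report forms
#' whose answer options are "yes" / "no" / "not specified".
#'
#' @param criterion_id Criterion the rule computes.
#' @param field Column name in the field table.
#' @param comparator One of the comparators above.
#' @param operand Scalar (or vector for `in`/`not_in`); must be absent for
#'   `present`/`absent`.
#' @return An object of class `binding_rule`.
#' @examples
#' binding_rule("gleason_ge_7", "gleason", "ge", 7)
#' binding_rule("age_over_70", "age", "gt", 70)
#' @export
binding_rule <- function(criterion_id, field, comparator, operand = NULL) {
  comparators <- c("eq", "ne", "lt", "le", "gt", "ge", "in", "not_in",
                   "present", "absent")
  if (!is.character(comparator) || length(comparator) != 1 ||
      !comparator %in% comparators) {
    stop("unknown comparator: ", deparse(comparator), call. = FALSE)
  }
  criterion_id <- normalize_criterion_id(criterion_id)
  field <- as.character(field)
  stopifnot(length(field) == 1, nzchar(field))
  if (comparator %in% c("present", "absent")) {
    if (!is.null(operand)) {
      stop("comparator '", comparator, "' takes no operand", call. = FALSE)
    }
  } else {
    if (is.null(operand) || !length(operand)) {
      stop("comparator '", comparator, "' requires an operand", call. = FALSE)
    }
    if (comparator %in% c("lt", "le", "gt", "ge")) {
      num <- suppressWarnings(as.numeric(operand))
      if (length(num) != 1 || is.na(num)) {
        stop("ordering comparator '", comparator,
             "' requires a single numeric operand", call. = FALSE)
      }
      operand <- num
    }
    if (comparator %in% c("eq", "ne") && length(operand) != 1) {
      stop("comparator '", comparator, "' requires a scalar operand",
           call. = FALSE)
    }
  }
  structure(list(criterion_id = criterion_id, field = field,
                 comparator = comparator, operand = operand),
            class = "binding_rule")
}

# Missing-cell encodings recognized in field tables.
is_missing_cell <- function(x) {
  is.na(x) | (is.character(x) & tolower(trimws(x)) %in% c("", "na", "not specified"))
}

#' Evaluate one binding rule on one patient row
#'
#' @param rule A [binding_rule()].
#' @param row Named list (or one-row data.frame) of field values for one
#'   patient; fields may be absent or missing.
#' @param patient_id Optional id used in error messages.
#' @return Logical scalar status: `TRUE`, `FALSE` or `NA` (unknown).
#' @examples
#' r <- binding_rule("gleason_ge_7", "gleason", "ge", 7)
#' evaluate_binding(r, list(gleason = 6))   # FALSE
#' evaluate_binding(r, list())              # NA: field missing
#' @export
evaluate_binding <- function(rule, row, patient_id = "<unknown>") {
  stopifnot(inherits(rule, "binding_rule"))
  row <- as.list(row)
  raw <- if (rule$field %in% names(row)) row[[rule$field]] else NA
  if (length(raw) != 1) raw <- if (length(raw)) raw[[1]] else NA
  missing <- isTRUE(is_missing_cell(raw))
  if (rule$comparator == "present") return(!missing)
  if (rule$comparator == "absent") return(missing)
  if (missing) return(NA)
  op <- rule$operand
  switch(rule$comparator,
    eq = compare_cells(raw, op, identity_cmp = TRUE),
    ne = !compare_cells(raw, op, identity_cmp = TRUE),
    `in` = as.character(raw) %in% as.character(op) ||
      (is_numeric_like(raw) && all(vapply(op, is_numeric_like, logical(1))) &&
         as.numeric(raw) %in% as.numeric(op)),
    not_in = !(as.character(raw) %in% as.character(op) ||
      (is_numeric_like(raw) && all(vapply(op, is_numeric_like, logical(1))) &&
         as.numeric(raw) %in% as.numeric(op))),
    lt = , le = , gt = , ge = {
      num <- suppressWarnings(as.numeric(raw))
      if (is.na(num)) {
        stop("non-numeric value for ordering comparator: patient '", patient_id,
             "', field '", rule$field, "', value ", sQuote(as.character(raw)),
             call. = FALSE)
      }
      switch(rule$comparator,
             lt = num < op, le = num <= op, gt = num > op, ge = num >= op)
    }
  )
}

is_numeric_like <- function(x) {
  !is.na(suppressWarnings(as.numeric(x)))
}

# eq/ne: numeric comparison when both sides are numeric-like, else string.
compare_cells <- function(a, b, identity_cmp = FALSE) {
  if (is_numeric_like(a) && is_numeric_like(b)) {
    as.numeric(a) == as.numeric(b)
  } else {
    as.character(a) == as.character(b)
  }
}

#' Derive criterion statuses for a whole cohort
#'
#' Applies a set of binding rules (at most one per criterion) to every row of
#' a patient field table, producing one [patient_record()] per row. Criteria
#' with no rule are simply absent from the records — i.e. unknown.
#'
#' @param rules List of [binding_rule()]s; criterion ids must be distinct.
#' @param table A `data.frame` with a `patient_id` column; remaining columns
#'   are fields. Cells equal to `NA`, `""` or `"not specified"` are missing.
#' @return List of [patient_record()]s, one per table row, in row order.
#' @examples
#' tab <- data.frame(patient_id = c("a", "b", "c"), age = c(75, 60, NA))
#' recs <- bind_cohort(list(binding_rule("age_over_70", "age", "gt", 70)), tab)
#' sapply(recs, function(r) r$statuses[["age_over_70"]])
#' @export
bind_cohort <- function(rules, table) {
  stopifnot(is.data.frame(table), "patient_id" %in% names(table))
  if (anyDuplicated(table$patient_id)) {
    stop("duplicate patient id(s) in field table", call. = FALSE)
  }
  crit_ids <- vapply(rules, function(r) r$criterion_id, character(1))
  if (anyDuplicated(crit_ids)) {
    stop("more than one binding rule for criterion id(s): ",
         paste(unique(crit_ids[duplicated(crit_ids)]), collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(table)), function(i) {
    row <- as.list(table[i, , drop = FALSE])
    pid <- as.character(row$patient_id)
    statuses <- vapply(rules, function(r) evaluate_binding(r, row, pid),
                       logical(1))
    names(statuses) <- crit_ids
    patient_record(pid, statuses)
  })
}
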