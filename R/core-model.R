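#' Normalize a criterion identifier
#'
#' Criterion ids become fragments of OWL class names, so they are normalized
#' before any uniqueness check: leading/trailing whitespace is trimmed and
#' internal whitespace runs are replaced by a single underscore. An id that is
#' empty after normalization is rejected.
#'
#' @param id Character vector of raw identifiers.
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_criterion_id("  Gleason score ")
#' @export
normalize_criterion_id <- function(id) {
  id <- gsub("\\s+", "_", trimws(as.character(id)))
  if (any(is.na(id)) || any(!nzchar(id))) {
    stop("criterion ids must be non-empty", call. = FALSE)
  }
  id
}

#' Criterion registry
#'
#' A registry is the set of known eligibility criteria: one row per criterion
#' with a unique normalized `id` and a free-text `label`. Trials are validated
#' against a registry so that a typo in a criterion list is caught before any
#' patient is evaluated.
#'
#' @param ids Character vector of criterion identifiers (normalized with
#'   [normalize_criterion_id()]).
#' @param labels Optional character vector of human-readable labels, recycled
#'   against `ids`; defaults to the ids themselves.
#' @return A `data.frame` of class `criterion_registry` with columns `id` and
#'   `label`.
#' @examples
#' criterion_registry(c("I0", "I1", "E0", "E1"),
#'                    c("prostate adenocarcinoma", "no metastasis",
#'                      "older than 70", "diabetes"))
#' @export
criterion_registry <- function(ids, labels = NULL) {
  ids <- normalize_criterion_id(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate criterion id(s) in registry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(labels)) labels <- ids
  reg <- data.frame(id = ids, label = rep_len(as.character(labels), length(ids)),
                    stringsAsFactors = FALSE)
  class(reg) <- c("criterion_registry", "data.frame")
  reg
}

#' Trial definition
#'
#' A clinical trial is modeled as an ordered list of inclusion criterion ids
#' and an ordered list of exclusion criterion ids. A patient is eligible when
#' every inclusion criterion is met and no exclusion criterion is met. Both
#' lists may be empty; each list must be duplicate-free; and no criterion may
#' appear in both lists of the same trial (such a trial would require the
#' criterion to be simultaneously true and false and is rejected as
#' unsatisfiable). The same criterion may, however, be an inclusion criterion
#' of one trial and an exclusion criterion of another.
#'
#' @param trial_id Identifier for the trial (normalized like criterion ids).
#' @param inclusion,exclusion Character vectors of criterion ids.
#' @return An object of class `trial_definition` with fields `trial_id`,
#'   `inclusion` and `exclusion`. Structural invariants are checked on
#'   construction; use [validate_trial()] to additionally check the ids
#'   against a registry and mark the trial as validated.
#' @examples
#' trial_definition("ct", inclusion = c("I0", "I1"), exclusion = c("E0", "E1"))
#' @export
trial_definition <- function(trial_id, inclusion = character(), exclusion = character()) {
  trial_id <- normalize_criterion_id(trial_id)
  inclusion <- if (length(inclusion)) normalize_criterion_id(inclusion) else character()
  exclusion <- if (length(exclusion)) normalize_criterion_id(exclusion) else character()
  for (side in list(c("inclusion"), c("exclusion"))) {
    ids <- if (side == "inclusion") inclusion else exclusion
    if (anyDuplicated(ids)) {
      stop("duplicate criterion id(s) in ", side, " list of trial '", trial_id,
           "': ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    }
  }
  both <- intersect(inclusion, exclusion)
  if (length(both)) {
    stop("unsatisfiable trial '", trial_id, "': criterion id(s) ",
         paste(both, collapse = ", "),
         " appear in both the inclusion and the exclusion list", call. = FALSE)
  }
  structure(
    list(trial_id = trial_id, inclusion = inclusion, exclusion = exclusion),
    class = "trial_definition"
  )
}

#' Validate a trial against a criterion registry
#'
#' Re-checks the structural invariants of a [trial_definition()] (duplicate-free
#' lists, no criterion on both sides) and verifies that every referenced
#' criterion id exists in the registry. On success the trial is returned
#' unchanged apart from a `validated` attribute; the evaluation functions
#' require a validated trial. Validation is idempotent.
#'
#' @param trial A [trial_definition()].
#' @param registry A [criterion_registry()]; if `NULL`, a registry containing
#'   exactly the trial's own criteria is used (structural validation only).
#' @return The validated `trial_definition`.
#' @examples
#' trial <- trial_definition("ct", c("I0", "I1"), c("E0", "E1"))
#' reg <- criterion_registry(c("I0", "I1", "E0", "E1"))
#' validate_trial(trial, reg)
#' @export
validate_trial <- function(trial, registry = NULL) {
  if (!inherits(trial, "trial_definition")) {
    stop("`trial` must be a trial_definition", call. = FALSE)
  }
  # reconstruct so that invariants hold even on a hand-edited object
  trial2 <- trial_definition(trial$trial_id, trial$inclusion, trial$exclusion)
  if (is.null(registry)) {
    registry <- criterion_registry(unique(c(trial2$inclusion, trial2$exclusion)))
  }
  if (!inherits(registry, "criterion_registry")) {
    stop("`registry` must be a criterion_registry", call. = FALSE)
  }
  missing <- setdiff(c(trial2$inclusion, trial2$exclusion), registry$id)
  if (length(missing)) {
    stop("trial '", trial2$trial_id, "' references unknown criterion id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  attr(trial2, "validated") <- TRUE
  trial2
}

is_validated_trial <- function(trial) {
  inherits(trial, "trial_definition") && isTRUE(attr(trial, "validated"))
}

assert_validated_trial <- function(trial) {
  if (!is_validated_trial(trial)) {
    stop("trial must be validated with validate_trial() before evaluation",
         call. = FALSE)
  }
  invisible(trial)
}

#' Patient record of criterion statuses
#'
#' A patient record maps criterion ids to three-valued statuses (logical with
#' `NA` = unknown). A criterion id absent from the mapping is semantically
#' unknown — exactly like an explicit `NA` entry. This mirrors how missing
#' knowledge is represented in the ontology: by the *absence* of an assertion,
#' never by a dedicated "unknown" assertion.
#'
#' @param patient_id Identifier for the patient.
#' @param statuses Named logical vector (names are criterion ids, normalized);
#'   may be empty.
#' @param registry Optional [criterion_registry()]; when supplied every status
#'   key must be a registered criterion.
#' @return An object of class `patient_record`.
#' @examples
#' patient_record("p2", c(I0 = TRUE, I1 = TRUE, E0 = FALSE, E1 = NA))
#' @export
patient_record <- function(patient_id, statuses = logical(), registry = NULL) {
  patient_id <- normalize_criterion_id(patient_id)
  nm0 <- names(statuses)
  statuses <- as.logical(statuses)
  names(statuses) <- nm0
  if (length(statuses)) {
    nm <- names(statuses)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("statuses must be a named logical vector", call. = FALSE)
    }
    names(statuses) <- normalize_criterion_id(nm)
    if (anyDuplicated(names(statuses))) {
      stop("duplicate criterion id(s) in statuses of patient '", patient_id,
           "'", call. = FALSE)
    }
    if (!is.null(registry)) {
      unknown <- setdiff(names(statuses), registry$id)
      if (length(unknown)) {
        stop("patient '", patient_id, "' references unknown criterion id(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(list(patient_id = patient_id, statuses = statuses),
            class = "patient_record")
}

#' Look up a patient's status for one criterion
#'
#' @param patient A [patient_record()].
#' @param criterion_id Single criterion id.
#' @return A logical scalar; `NA` when the criterion is absent from the record
#'   or explicitly unknown.
#' @export
patient_status <- function(patient, criterion_id) {
  stopifnot(inherits(patient, "patient_record"))
  s <- patient$statuses
  idx <- match(criterion_id, names(s))
  ifelse(is.na(idx), NA, unname(s[idx]))
}

# Internal constructor enforcing the EligibilityResult invariants.
eligibility_result <- function(patient_id, trial_id, decision,
                               failed_inclusions, matched_exclusions,
                               unknown_inclusions, unknown_exclusions) {
  decided_against <- length(failed_inclusions) + length(matched_exclusions) > 0
  has_unknown <- length(unknown_inclusions) + length(unknown_exclusions) > 0
  ok <- switch(decision,
    NOT_ELIGIBLE = decided_against,
    ELIGIBLE = !decided_against && !has_unknown,
    UNDETERMINED = !decided_against && has_unknown,
    FALSE
  )
  if (!isTRUE(ok)) {
    stop("internal error: inconsistent eligibility result for patient '",
         patient_id, "'", call. = FALSE)
  }
  structure(
    list(patient_id = patient_id, trial_id = trial_id, decision = decision,
         failed_inclusions = failed_inclusions,
         matched_exclusions = matched_exclusions,
         unknown_inclusions = unknown_inclusions,
         unknown_exclusions = unknown_exclusions),
    class = "eligibility_result"
  )
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat(sprintf("<%s / %s> %s\n", x$patient_id, x$trial_id,
              decision_label(x$decision)))
  if (length(x$failed_inclusions)) {
    cat("  failed inclusion: ", paste(x$failed_inclusions, collapse = ", "), "\n")
  }
  if (length(x$matched_exclusions)) {
    cat("  matched exclusion:", paste(x$matched_exclusions, collapse = ", "), "\n")
  }
  unk <- c(x$unknown_inclusions, x$unknown_exclusions)
  if (length(unk)) {
    cat("  unknown:          ", paste(unk, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.trial_definition <- function(x, ...) {
  cat(sprintf("trial '%s': %d inclusion / %d exclusion criteria\n",
              x$trial_id, length(x$inclusion), length(x$exclusion)))
  if (length(x$inclusion)) cat("  inclusion:", paste(x$inclusion, collapse = ", "), "\n")
  if (length(x$exclusion)) cat("  exclusion:", paste(x$exclusion, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("patient '%s': %d known status(es)\n", x$patient_id,
              sum(!is.na(x$statuses))))
  if (length(x$statuses)) {
    cat(" ", paste(sprintf("%s=%s", names(x$statuses),
                           format_truth_value(x$statuses)), collapse = " "), "\n")
  }
  invisible(x)
}

# Decision vocabulary used in rendered reports: the screening terminology is
# "eligible" / "not eligible" / "potentially eligible".
decision_label <- function(decision) {
  c(ELIGIBLE = "eligible",
    NOT_ELIGIBLE = "not eligible",
    UNDETERMINED = "potentially eligible")[decision]
}
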