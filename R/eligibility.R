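#' Open-world eligibility evaluation
#'
#' Evaluates a patient against a trial in three-valued logic: eligibility is
#' the strong Kleene conjunction of the statuses of all inclusion criteria and
#' the negated statuses of all exclusion criteria. An unknown status never
#' counts as a failure — it can only leave the decision undetermined — so the
#' three outcomes are:
#'
#' * `ELIGIBLE`: every inclusion criterion is known to be met and every
#'   exclusion criterion known to be unmet;
#' * `NOT_ELIGIBLE`: at least one inclusion criterion is known to fail or one
#'   exclusion criterion is known to be met (a decided rejection, even if
#'   other criteria remain unknown);
#' * `UNDETERMINED`: nothing decides against the patient, but at least one
#'   relevant criterion is unknown — the patient is *potentially eligible*
#'   and the missing criteria are identified.
#'
#' The result carries the causes: the failed inclusion criteria, the matched
#' exclusion criteria, and the unknown criteria on each side. For a rejected
#' patient the unknown sets are still reported (they list what additionally
#' could not be verified) but play no role in the decision.
#'
#' @param trial A [trial_definition()] validated with [validate_trial()].
#' @param patient A [patient_record()]; criteria absent from its status map
#'   are unknown.
#' @return An object of class `eligibility_result` with fields `patient_id`,
#'   `trial_id`, `decision` (`"ELIGIBLE"`, `"NOT_ELIGIBLE"` or
#'   `"UNDETERMINED"`), `failed_inclusions`, `matched_exclusions`,
#'   `unknown_inclusions` and `unknown_exclusions`.
#' @seealso [evaluate_closed_world()] for the negation-as-failure baseline,
#'   [completion_oracle()] for the brute-force semantics.
#' @examples
#' trial <- validate_trial(trial_definition("ct", c("I0", "I1"), c("E0", "E1")))
#' # all information available: decided
#' evaluate_open_world(trial, patient_record("p1",
#'   c(I0 = TRUE, I1 = TRUE, E0 = FALSE, E1 = FALSE)))
#' # unknown exclusion status: potentially eligible, E1 must be sought
#' evaluate_open_world(trial, patient_record("p2",
#'   c(I0 = TRUE, I1 = TRUE, E0 = FALSE)))
#' @export
evaluate_open_world <- function(trial, patient) {
  assert_validated_trial(trial)
  stopifnot(inherits(patient, "patient_record"))
  s_inc <- patient_status_vec(patient, trial$inclusion)
  s_exc <- patient_status_vec(patient, trial$exclusion)
  value <- kleene_and(c(s_inc, kleene_not(s_exc)))
  decision <- if (is.na(value)) "UNDETERMINED" else if (value) "ELIGIBLE" else "NOT_ELIGIBLE"
  eligibility_result(
    patient_id = patient$patient_id,
    trial_id = trial$trial_id,
    decision = decision,
    failed_inclusions = trial$inclusion[!is.na(s_inc) & !s_inc],
    matched_exclusions = trial$exclusion[!is.na(s_exc) & s_exc],
    unknown_inclusions = trial$inclusion[is.na(s_inc)],
    unknown_exclusions = trial$exclusion[is.na(s_exc)]
  )
}

patient_status_vec <- function(patient, ids) {
  if (!length(ids)) return(logical())
  idx <- match(ids, names(patient$statuses))
  out <- rep(NA, length(ids))
  hit <- !is.na(idx)
  out[hit] <- unname(patient$statuses[idx[hit]])
  out
}

#' Closed-world (negation-as-failure) baseline
#'
#' The classic two-valued reading of the eligibility conjunction: a conjunct
#' counts only if it is provable. A patient is `INCLUDE` only when every
#' inclusion criterion is provably true and every exclusion criterion provably
#' false; anything unknown fails the conjunction, so the patient is `EXCLUDE`.
#' This baseline over-rejects: it cannot distinguish a patient known to be
#' ineligible from one whose eligibility merely cannot be asserted yet. Use
#' [compare_policies()] to list the patients it over-rejects relative to the
#' open-world evaluation.
#'
#' @inheritParams evaluate_open_world
#' @return `"INCLUDE"` or `"EXCLUDE"`.
#' @export
evaluate_closed_world <- function(trial, patient) {
  assert_validated_trial(trial)
  stopifnot(inherits(patient, "patient_record"))
  s_inc <- patient_status_vec(patient, trial$inclusion)
  s_exc <- patient_status_vec(patient, trial$exclusion)
  provable <- all(!is.na(s_inc) & s_inc) && all(!is.na(s_exc) & !s_exc)
  if (provable) "INCLUDE" else "EXCLUDE"
}

#' Brute-force completion oracle
#'
#' Independent ground-truth semantics used to test the engine: every unknown
#' status among the trial's criteria is completed to `TRUE`/`FALSE` in all
#' `2^u` possible ways, each completion is evaluated classically, and the
#' decisions are aggregated — `ELIGIBLE` when every completion is eligible,
#' `NOT_ELIGIBLE` when none is, `UNDETERMINED` otherwise (the available
#' information genuinely underdetermines the outcome).
#'
#' @inheritParams evaluate_open_world
#' @param max_unknowns Refuse to enumerate more than this many unknown
#'   statuses (default 20, i.e. about a million completions).
#' @return `"ELIGIBLE"`, `"NOT_ELIGIBLE"` or `"UNDETERMINED"`.
#' @export
completion_oracle <- function(trial, patient, max_unknowns = 20) {
  assert_validated_trial(trial)
  stopifnot(inherits(patient, "patient_record"))
  ids <- c(trial$inclusion, trial$exclusion)
  s <- patient_status_vec(patient, ids)
  unknown_idx <- which(is.na(s))
  u <- length(unknown_idx)
  if (u > max_unknowns) {
    stop("completion_oracle: ", u, " unknown statuses exceed the enumeration ",
         "limit of ", max_unknowns, call. = FALSE)
  }
  n_inc <- length(trial$inclusion)
  eligible_classical <- function(v) {
    inc <- if (n_inc) v[seq_len(n_inc)] else logical()
    exc <- if (length(v) > n_inc) v[(n_inc + 1):length(v)] else logical()
    all(inc) && !any(exc)
  }
  if (u == 0) {
    return(if (eligible_classical(s)) "ELIGIBLE" else "NOT_ELIGIBLE")
  }
  outcomes <- vapply(seq_len(2^u) - 1L, function(mask) {
    v <- s
    v[unknown_idx] <- bitwAnd(bitwShiftR(mask, seq_len(u) - 1L), 1L) == 1L
    eligible_classical(v)
  }, logical(1))
  if (all(outcomes)) "ELIGIBLE" else if (!any(outcomes)) "NOT_ELIGIBLE" else "UNDETERMINED"
}

#' Classify a cohort against one trial
#'
#' Applies [evaluate_open_world()] to every patient, preserving input order,
#' and aggregates the decision counts.
#'
#' @inheritParams evaluate_open_world
#' @param patients List of [patient_record()]s with unique patient ids.
#' @return An object of class `cohort_classification` with fields `trial_id`,
#'   `results` (list of `eligibility_result`) and `counts` (named integer
#'   vector over `ELIGIBLE`, `NOT_ELIGIBLE`, `UNDETERMINED`).
#' @examples
#' trial <- validate_trial(trial_definition("ct", "I0", "E0"))
#' cohort <- list(
#'   patient_record("a", c(I0 = TRUE, E0 = FALSE)),
#'   patient_record("b", c(I0 = TRUE))
#' )
#' classify_cohort(trial, cohort)$counts
#' @export
classify_cohort <- function(trial, patients) {
  assert_validated_trial(trial)
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate patient id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  results <- lapply(patients, function(p) evaluate_open_world(trial, p))
  decisions <- vapply(results, function(r) r$decision, character(1))
  counts <- vapply(c("ELIGIBLE", "NOT_ELIGIBLE", "UNDETERMINED"),
                   function(d) sum(decisions == d), integer(1))
  structure(list(trial_id = trial$trial_id, results = results, counts = counts),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf("cohort classification for trial '%s' (%d patients)\n",
              x$trial_id, length(x$results)))
  for (d in names(x$counts)) {
    cat(sprintf("  %-20s %d\n", decision_label(d), x$counts[[d]]))
  }
  invisible(x)
}

#' Tabulate a cohort classification
#'
#' @param x A `cohort_classification`.
#' @param ... Unused.
#' @return A `data.frame` with one row per patient: `patient_id`, `decision`,
#'   and the cause/unknown criterion lists joined with `";"`.
#' @export
as.data.frame.cohort_classification <- function(x, ...) {
  join <- function(v) paste(v, collapse = ";")
  data.frame(
    patient_id = vapply(x$results, function(r) r$patient_id, character(1)),
    decision = vapply(x$results, function(r) r$decision, character(1)),
    failed_inclusions = vapply(x$results, function(r) join(r$failed_inclusions), character(1)),
    matched_exclusions = vapply(x$results, function(r) join(r$matched_exclusions), character(1)),
    unknown_inclusions = vapply(x$results, function(r) join(r$unknown_inclusions), character(1)),
    unknown_exclusions = vapply(x$results, function(r) join(r$unknown_exclusions), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Patients over-rejected by the closed-world policy
#'
#' Returns the ids of the patients whom the negation-as-failure baseline
#' rejects (`EXCLUDE`) while the open-world evaluation leaves them
#' undetermined — the patients a closed-world screening system would wrongly
#' drop even though the missing information might well make them eligible.
#' Patients on whom the two policies agree are not returned. On fully-known
#' records the two policies always coincide, so the set is empty.
#'
#' @inheritParams classify_cohort
#' @return Character vector of patient ids (possibly empty).
#' @export
compare_policies <- function(trial, patients) {
  assert_validated_trial(trial)
  conflict <- vapply(patients, function(p) {
    evaluate_closed_world(trial, p) == "EXCLUDE" &&
      evaluate_open_world(trial, p)$decision == "UNDETERMINED"
  }, logical(1))
  vapply(patients[conflict], function(p) p$patient_id, character(1))
}
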