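# Fictitious validation trial: two inclusion criteria (I0, I1) and two
# exclusion criteria (E0, E1), and the nine patients covering all
# true/false/unknown combinations of I1 and E1 (I0 always true, E0 always
# false). Unknown statuses are represented by omission.
validation_registry <- function() {
  criterion_registry(c("I0", "I1", "E0", "E1"),
                     c("prostate adenocarcinoma", "absence of metastasis",
                       "older than 70 years", "evidence of diabetes"))
}

validation_trial <- function() {
  validate_trial(trial_definition("ct", c("I0", "I1"), c("E0", "E1")),
                 validation_registry())
}

validation_patients <- function() {
  list(
    patient_record("p0", c(I0 = TRUE, I1 = TRUE, E0 = FALSE, E1 = TRUE)),
    patient_record("p1", c(I0 = TRUE, I1 = TRUE, E0 = FALSE, E1 = FALSE)),
    patient_record("p2", c(I0 = TRUE, I1 = TRUE, E0 = FALSE)),
    patient_record("p3", c(I0 = TRUE, I1 = FALSE, E0 = FALSE, E1 = TRUE)),
    patient_record("p4", c(I0 = TRUE, I1 = FALSE, E0 = FALSE, E1 = FALSE)),
    patient_record("p5", c(I0 = TRUE, I1 = FALSE, E0 = FALSE)),
    patient_record("p6", c(I0 = TRUE, E0 = FALSE, E1 = TRUE)),
    patient_record("p7", c(I0 = TRUE, E0 = FALSE, E1 = FALSE)),
    patient_record("p8", c(I0 = TRUE, E0 = FALSE))
  )
}

# Expected decisions and causes of the validation set, by patient id.
validation_expectations <- function() {
  list(
    p0 = list(decision = "NOT_ELIGIBLE", failed = character(), matched = "E1"),
    p1 = list(decision = "ELIGIBLE", failed = character(), matched = character()),
    p2 = list(decision = "UNDETERMINED", failed = character(), matched = character(),
              unknown_inc = character(), unknown_exc = "E1"),
    p3 = list(decision = "NOT_ELIGIBLE", failed = "I1", matched = "E1"),
    p4 = list(decision = "NOT_ELIGIBLE", failed = "I1", matched = character()),
    p5 = list(decision = "NOT_ELIGIBLE", failed = "I1", matched = character()),
    p6 = list(decision = "NOT_ELIGIBLE", failed = character(), matched = "E1"),
    p7 = list(decision = "UNDETERMINED", failed = character(), matched = character(),
              unknown_inc = "I1", unknown_exc = character()),
    p8 = list(decision = "UNDETERMINED", failed = character(), matched = character(),
              unknown_inc = "I1", unknown_exc = "E1")
  )
}

# Every status vector in {TRUE, FALSE, NA}^k, as a list of logical vectors.
all_status_vectors <- function(k) {
  if (k == 0) return(list(logical(0)))
  grid <- do.call(expand.grid, rep(list(c(TRUE, FALSE, NA)), k))
  lapply(seq_len(nrow(grid)), function(i) as.logical(unlist(grid[i, ])))
}

# Patient record from a status vector over the ids, omitting unknowns.
record_from_vector <- function(pid, ids, v) {
  known <- !is.na(v)
  patient_record(pid, stats::setNames(v[known], ids[known]))
}

random_cohort <- function(n, ids, p_known = 0.6, seed = 1) {
  generate_cohort(simulation_config(n, ids, p_known = p_known, seed = seed))
}
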