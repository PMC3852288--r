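test_that("open-world evaluation reproduces the nine-patient validation set", {
  trial <- validation_trial()
  exp <- validation_expectations()
  for (p in validation_patients()) {
    r <- evaluate_open_world(trial, p)
    e <- exp[[p$patient_id]]
    expect_identical(r$decision, e$decision, label = p$patient_id)
    expect_setequal(r$failed_inclusions, e$failed)
    expect_setequal(r$matched_exclusions, e$matched)
    if (r$decision == "UNDETERMINED") {
      expect_setequal(r$unknown_inclusions, e$unknown_inc)
      expect_setequal(r$unknown_exclusions, e$unknown_exc)
    }
  }
})

test_that("rejected patients still report their residual unknowns", {
  trial <- validation_trial()
  p5 <- validation_patients()[[6]]
  r <- evaluate_open_world(trial, p5)
  expect_identical(r$decision, "NOT_ELIGIBLE")
  expect_identical(r$unknown_exclusions, "E1")
})

test_that("closed-world baseline includes only fully-proven patients", {
  trial <- validation_trial()
  pats <- validation_patients()
  decisions <- vapply(pats, function(p) evaluate_closed_world(trial, p),
                      character(1))
  names(decisions) <- vapply(pats, function(p) p$patient_id, character(1))
  expect_identical(unname(decisions["p1"]), "INCLUDE")
  expect_identical(sum(decisions == "EXCLUDE"), 8L)
  # unknowns fail both positive and negated conjuncts
  expect_identical(unname(decisions["p2"]), "EXCLUDE")
  expect_identical(unname(decisions["p8"]), "EXCLUDE")
})

test_that("completion oracle aggregates the classical completions", {
  trial <- validation_trial()
  pats <- validation_patients()
  expect_identical(completion_oracle(trial, pats[[3]]), "UNDETERMINED") # p2
  expect_identical(completion_oracle(trial, pats[[6]]), "NOT_ELIGIBLE") # p5
  expect_identical(completion_oracle(trial, pats[[2]]), "ELIGIBLE")     # p1
  expect_error(completion_oracle(trial, pats[[9]], max_unknowns = 1),
               "enumeration limit")
})

test_that("engine decision equals the completion oracle on every small trial", {
  # every trial shape with n + m <= 6 criteria, every status vector
  for (n_inc in 0:6) {
    for (n_exc in 0:(6 - n_inc)) {
      k <- n_inc + n_exc
      ids <- if (k) sprintf("c%d", seq_len(k)) else character()
      trial <- validate_trial(trial_definition(
        "t",
        inclusion = if (n_inc) ids[seq_len(n_inc)] else character(),
        exclusion = if (n_exc) ids[n_inc + seq_len(n_exc)] else character()
      ))
      for (v in all_status_vectors(k)) {
        p <- record_from_vector("p", ids, v)
        engine <- evaluate_open_world(trial, p)$decision
        expect_identical(engine, completion_oracle(trial, p),
                         label = sprintf("n=%d m=%d v=%s", n_inc, n_exc,
                                         paste(v, collapse = ",")))
        # closed-world INCLUDE if and only if open-world ELIGIBLE
        cw <- evaluate_closed_world(trial, p)
        expect_identical(cw == "INCLUDE", engine == "ELIGIBLE")
      }
    }
  }
})

test_that("knowledge monotonicity: resolving an unknown never flips a decision", {
  trial <- validate_trial(trial_definition("t", c("a", "b", "c"), c("d", "e")))
  ids <- c("a", "b", "c", "d", "e")
  for (v in all_status_vectors(5)) {
    base <- evaluate_open_world(trial, record_from_vector("p", ids, v))$decision
    if (base == "UNDETERMINED") next
    for (i in which(is.na(v))) {
      for (val in c(TRUE, FALSE)) {
        w <- v
        w[i] <- val
        refined <- evaluate_open_world(trial, record_from_vector("p", ids, w))$decision
        expect_identical(refined, base)
      }
    }
  }
})

test_that("causes are sound and decisions are permutation-invariant", {
  trial <- validate_trial(trial_definition("t", c("a", "b"), c("c", "d")))
  shuffled <- validate_trial(trial_definition("t", c("b", "a"), c("d", "c")))
  ids <- c("a", "b", "c", "d")
  for (v in all_status_vectors(4)) {
    p <- record_from_vector("p", ids, v)
    r <- evaluate_open_world(trial, p)
    for (id in r$failed_inclusions) expect_false(patient_status(p, id))
    for (id in r$matched_exclusions) expect_true(patient_status(p, id))
    expect_true(all(r$failed_inclusions %in% trial$inclusion))
    expect_true(all(r$matched_exclusions %in% trial$exclusion))
    expect_identical(r$decision, evaluate_open_world(shuffled, p)$decision)
  }
})

test_that("classify_cohort aggregates counts and preserves order", {
  trial <- validation_trial()
  pats <- validation_patients()
  cl <- classify_cohort(trial, pats)
  expect_identical(cl$counts,
                   c(ELIGIBLE = 1L, NOT_ELIGIBLE = 5L, UNDETERMINED = 3L))
  expect_identical(sum(cl$counts), length(cl$results))
  expect_identical(vapply(cl$results, function(r) r$patient_id, character(1)),
                   vapply(pats, function(p) p$patient_id, character(1)))

  expect_identical(unname(classify_cohort(trial, list())$counts), c(0L, 0L, 0L))
  expect_error(classify_cohort(trial, c(pats, pats[1])), "duplicate patient")

  # fully-known cohorts always decide
  full <- Filter(function(p) length(p$statuses) == 4, pats)
  expect_identical(classify_cohort(trial, full)$counts[["UNDETERMINED"]], 0L)
})

test_that("compare_policies returns exactly the over-rejected patients", {
  trial <- validation_trial()
  expect_setequal(compare_policies(trial, validation_patients()),
                  c("p2", "p7", "p8"))
  full <- Filter(function(p) length(p$statuses) == 4, validation_patients())
  expect_length(compare_policies(trial, full), 0)

  # cross-check against the completion oracle on a random partial cohort
  ids <- sprintf("c%d", 1:5)
  trial2 <- validate_trial(trial_definition("t2", ids[1:3], ids[4:5]))
  cohort <- random_cohort(60, ids, p_known = 0.6, seed = 7)
  expected <- vapply(cohort, function(p) {
    evaluate_closed_world(trial2, p) == "EXCLUDE" &&
      completion_oracle(trial2, p) == "UNDETERMINED"
  }, logical(1))
  expect_setequal(compare_policies(trial2, cohort),
                  vapply(cohort[expected], function(p) p$patient_id, character(1)))
})

test_that("evaluation requires a validated trial", {
  raw <- trial_definition("t", "a", "b")
  p <- patient_record("p", c(a = TRUE))
  expect_error(evaluate_open_world(raw, p), "validate")
  expect_error(evaluate_closed_world(raw, p), "validate")
  expect_error(classify_cohort(raw, list(p)), "validate")
})
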