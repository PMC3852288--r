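test_that("comparators decide correctly on present values", {
  expect_false(evaluate_binding(binding_rule("g", "gleason", "ge", 7),
                                list(gleason = 6)))
  expect_true(evaluate_binding(binding_rule("g", "gleason", "ge", 7),
                               list(gleason = 7)))
  expect_false(evaluate_binding(binding_rule("a", "age", "gt", 70),
                                list(age = 70))) # strict boundary
  expect_true(evaluate_binding(binding_rule("a", "age", "le", 70),
                               list(age = 70)))
  expect_true(evaluate_binding(binding_rule("s", "sex", "eq", "M"),
                               list(sex = "M")))
  expect_true(evaluate_binding(binding_rule("s", "stage", "in", c("T1", "T2")),
                               list(stage = "T2")))
  expect_false(evaluate_binding(binding_rule("s", "stage", "not_in", c("T1", "T2")),
                                list(stage = "T2")))
  # numeric-faithful equality: "7.0" equals 7
  expect_true(evaluate_binding(binding_rule("g", "gleason", "eq", 7),
                               list(gleason = "7.0")))
})

test_that("missing fields are unknown, except for present/absent", {
  r <- binding_rule("a", "age", "gt", 70)
  expect_identical(evaluate_binding(r, list()), NA)
  expect_identical(evaluate_binding(r, list(age = NA)), NA)
  expect_identical(evaluate_binding(r, list(age = "not specified")), NA)
  expect_identical(evaluate_binding(r, list(age = "")), NA)
  expect_true(evaluate_binding(binding_rule("h", "age", "absent"), list()))
  expect_false(evaluate_binding(binding_rule("h", "age", "present"), list()))
  expect_true(evaluate_binding(binding_rule("h", "age", "present"),
                               list(age = 50)))
})

test_that("rule validation catches bad comparators and operands", {
  expect_error(binding_rule("x", "f", "contains", "a"), "unknown comparator")
  expect_error(binding_rule("x", "f", "ge", "seven"), "numeric operand")
  expect_error(binding_rule("x", "f", "ge"), "requires an operand")
  expect_error(binding_rule("x", "f", "present", operand = 1), "no operand")
  expect_error(
    evaluate_binding(binding_rule("x", "f", "ge", 7), list(f = "high"), "pt9"),
    "pt9.*'f'")
})

test_that("bind_cohort derives one record per row with rule-wise statuses", {
  tab <- data.frame(patient_id = c("a", "b", "c"),
                    age = c(75, 60, NA),
                    gleason = c(7, 6, 8))
  rules <- list(binding_rule("age_over_70", "age", "gt", 70),
                binding_rule("gleason_ge_7", "gleason", "ge", 7))
  recs <- bind_cohort(rules, tab)
  expect_length(recs, 3)
  expect_identical(vapply(recs, function(r) patient_status(r, "age_over_70"),
                          logical(1)),
                   c(TRUE, FALSE, NA))
  expect_identical(vapply(recs, function(r) patient_status(r, "gleason_ge_7"),
                          logical(1)),
                   c(TRUE, FALSE, TRUE))
  # criteria without rules stay unknown
  expect_identical(patient_status(recs[[1]], "unbound"), NA)

  expect_error(bind_cohort(c(rules, rules[1]), tab), "more than one binding rule")
  expect_error(bind_cohort(rules, data.frame(patient_id = c("a", "a"),
                                             age = c(1, 2))),
               "duplicate patient")
  # empty rule list: records with empty status maps
  empty <- bind_cohort(list(), tab)
  expect_identical(lengths(lapply(empty, function(r) r$statuses)),
                   rep(0L, 3))
})

test_that("binding is deterministic and conserves missingness", {
  cfg <- simulation_config(200, c("gleason", "psa"), p_known = c(0.5, 0.8),
                           seed = 11)
  tab <- generate_field_table(cfg, list(
    gleason = list(kind = "uniform_int", min = 6, max = 10),
    psa = list(kind = "uniform_int", min = 0, max = 40)))
  rules <- list(binding_rule("gleason_ge_7", "gleason", "ge", 7),
                binding_rule("psa_lt_20", "psa", "lt", 20))
  recs1 <- bind_cohort(rules, tab)
  recs2 <- bind_cohort(rules, tab)
  expect_identical(recs1, recs2)
  for (rule in rules) {
    n_missing <- sum(is.na(tab[[rule$field]]))
    n_unknown <- sum(vapply(recs1, function(r)
      is.na(patient_status(r, rule$criterion_id)), logical(1)))
    expect_identical(n_unknown, n_missing)
  }
})
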