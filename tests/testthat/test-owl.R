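test_that("the compiled ontology follows the design pattern", {
  trial <- validation_trial()
  pats <- validation_patients()
  m <- build_ontology(trial, validation_registry(), pats)

  # 1 root + 2 classes per criterion + 5 per trial
  expect_length(m$classes, 1 + 2 * 4 + 5 * 1)
  expect_true(all(c("Criterion", "C_I0", "Not_C_I0", "Ct_ct", "Ct_ct_include",
                    "Ct_ct_exclude",
                    "Ct_ct_exclude_at_least_one_exclusion_criterion",
                    "Ct_ct_exclude_at_least_one_failed_inclusion_criterion")
                  %in% m$classes))

  # p1 fully known: four criterion type assertions (plus the root)
  expect_setequal(m$individuals$p1,
                  c("Criterion", "C_I0", "C_I1", "Not_C_E0", "Not_C_E1"))
  # p2: nothing asserted about E1
  expect_setequal(m$individuals$p2, c("Criterion", "C_I0", "C_I1", "Not_C_E0"))
  expect_false(any(grepl("E1", m$individuals$p2)))

  # axiom-count formula over several shapes: 1 + 2c + 5t classes
  reg <- criterion_registry(sprintf("x%d", 1:7))
  trials <- list(
    validate_trial(trial_definition("a", c("x1", "x2"), c("x3")), reg),
    validate_trial(trial_definition("b", c("x4"), character()), reg),
    validate_trial(trial_definition("c", character(), c("x5", "x6", "x7")), reg)
  )
  m2 <- build_ontology(trials, reg)
  expect_length(m2$classes, 1 + 2 * 7 + 5 * 3)
})

test_that("ids are sanitized into IRI fragments; illegal names are rejected", {
  reg <- criterion_registry("weird id (v2)")
  trial <- validate_trial(trial_definition("t", "weird id (v2)"), reg)
  m <- build_ontology(trial, reg)
  expect_true("C_weird_id__v2_" %in% m$classes)
  # a patient id that sanitizes to a digit-leading fragment is not a legal NCName
  expect_error(
    build_ontology(trial, reg, list(patient_record("9lives", c(weird_id__v2_ = TRUE)))),
    "IRI-illegal")
})

test_that("RDF/XML serialization round-trips with identical counts", {
  trial <- validation_trial()
  pats <- validation_patients()
  m <- build_ontology(trial, validation_registry(), pats)
  doc <- serialize_ontology(m, "rdfxml")
  back <- parse_ontology(doc)
  expect_setequal(back$classes, m$classes)
  n_eq <- sum(vapply(m$axioms, function(a) a$type == "equivalent", logical(1)))
  n_sub <- sum(vapply(m$axioms, function(a) a$type == "subclass", logical(1)))
  expect_length(back$equivalences, n_eq)
  expect_length(back$subclasses, n_sub)
  expect_identical(sort(names(back$individuals)),
                   sort(names(m$individuals)))
  for (pid in names(m$individuals)) {
    expect_setequal(back$individuals[[pid]], m$individuals[[pid]])
  }

  # empty model: only the root class declaration
  empty <- build_ontology(list(), criterion_registry(character()))
  back_empty <- parse_ontology(serialize_ontology(empty))
  expect_identical(back_empty$classes, "Criterion")

  expect_error(serialize_ontology(m, "n3!"), "unsupported")
})

test_that("Turtle and RDF/XML serializations denote isomorphic graphs", {
  trial <- validation_trial()
  m <- build_ontology(trial, validation_registry(), validation_patients()[1:3])
  rdf_file <- tempfile(fileext = ".rdf")
  ttl_file <- tempfile(fileext = ".ttl")
  on.exit(unlink(c(rdf_file, ttl_file)), add = TRUE)
  writeLines(serialize_ontology(m, "rdfxml"), rdf_file)
  writeLines(serialize_ontology(m, "turtle"), ttl_file)
  script <- paste(
    "import sys, rdflib",
    "from rdflib.compare import isomorphic",
    "g1 = rdflib.Graph(); g1.parse(sys.argv[1], format='xml')",
    "g2 = rdflib.Graph(); g2.parse(sys.argv[2], format='turtle')",
    "print('ISO' if isomorphic(g1, g2) else 'DIFF')",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), rdf_file, ttl_file),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(out[length(out)], "ISO")
})

test_that("the classifier reproduces the reasoning of the validation set", {
  trial <- validation_trial()
  pats <- validation_patients()
  m <- build_ontology(trial, validation_registry(), pats)
  cls <- classify_with_reasoner(serialize_ontology(m, "rdfxml"))

  expect_true("Ct_ct_include" %in% cls$memberships$p1)
  for (pid in c("p0", "p3", "p6")) {
    expect_true("Ct_ct_exclude_at_least_one_exclusion_criterion" %in%
                  cls$memberships[[pid]], label = pid)
  }
  for (pid in c("p3", "p4", "p5")) {
    expect_true("Ct_ct_exclude_at_least_one_failed_inclusion_criterion" %in%
                  cls$memberships[[pid]], label = pid)
  }
  # the undetermined patients are members of no include/exclude class
  for (pid in c("p2", "p7", "p8")) {
    expect_false(any(grepl("^Ct_ct_(include|exclude)", cls$memberships[[pid]])),
                 label = pid)
  }
  # no patient is both included and excluded
  for (pid in names(cls$memberships)) {
    m_p <- cls$memberships[[pid]]
    expect_false("Ct_ct_include" %in% m_p && "Ct_ct_exclude" %in% m_p)
  }
})

test_that("patients with unknown relevant criteria are never inferred eligible", {
  ids <- c("a", "b", "c", "d")
  trial <- validate_trial(trial_definition("t", ids[1:2], ids[3:4]))
  for (v in all_status_vectors(4)) {
    if (!anyNA(v)) next
    p <- record_from_vector("p", ids, v)
    cls <- classify_with_reasoner(build_ontology(trial, patients = list(p)))
    expect_false("Ct_t_include" %in% cls$memberships$p)
  }
})

test_that("contradictory type assertions raise a consistency error", {
  trial <- validation_trial()
  m <- build_ontology(trial, validation_registry(),
                      list(patient_record("px", c(I0 = TRUE))))
  m$individuals$px <- c(m$individuals$px, "Not_C_I0") # assert both C and Not_C
  expect_error(classify_with_reasoner(serialize_ontology(m)),
               "inconsistent.*px")
})

test_that("engine and classifier agree on the validation set and beyond", {
  trial <- validation_trial()
  expect_identical(
    nrow(crosscheck_engine_vs_reasoner(trial, validation_registry(),
                                       validation_patients())), 0L)

  # exhaustive over a 2+2-criterion trial: all 81 records
  ids <- c("i1", "i2", "e1", "e2")
  trial4 <- validate_trial(trial_definition("t4", ids[1:2], ids[3:4]))
  pats <- lapply(seq_along(all_status_vectors(4)), function(i)
    record_from_vector(sprintf("q%d", i), ids, all_status_vectors(4)[[i]]))
  expect_identical(nrow(crosscheck_engine_vs_reasoner(trial4, patients = pats)), 0L)

  # sampled 6-criterion cohort, partially known
  ids6 <- sprintf("c%d", 1:6)
  trial6 <- validate_trial(trial_definition("t6", ids6[1:3], ids6[4:6]))
  cohort <- random_cohort(50, ids6, p_known = 0.55, seed = 42)
  expect_identical(nrow(crosscheck_engine_vs_reasoner(trial6, patients = cohort)), 0L)

  # fully-known random cohort: both semantics classical
  full <- random_cohort(30, ids6, p_known = 1, seed = 9)
  expect_identical(nrow(crosscheck_engine_vs_reasoner(trial6, patients = full)), 0L)
})

test_that("multiple trials over a shared registry classify independently", {
  reg <- criterion_registry(c("A", "B", "C"))
  t1 <- validate_trial(trial_definition("t1", inclusion = "A", exclusion = "B"), reg)
  t2 <- validate_trial(trial_definition("t2", inclusion = "B", exclusion = "A"), reg)
  pats <- list(patient_record("p", c(A = TRUE, B = FALSE)))
  expect_identical(nrow(crosscheck_engine_vs_reasoner(list(t1, t2), reg, pats)), 0L)
  cls <- classify_with_reasoner(build_ontology(list(t1, t2), reg, pats))
  expect_identical(unname(reasoner_decisions(cls, t1)), "ELIGIBLE")
  expect_identical(unname(reasoner_decisions(cls, t2)), "NOT_ELIGIBLE")
})
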