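#' Classify patient individuals with the built-in OWL instance classifier
#'
#' A sound and complete instance classifier for the fragment of OWL 2 DL the
#' eligibility design pattern lives in: Boolean class expressions
#' (intersection, union, complement, `owl:Thing`/`owl:Nothing`) over named
#' classes, with no object or data properties. On this role-free fragment,
#' instance checking reduces to propositional entailment: every axiom is a
#' pointwise constraint between class memberships, individuals do not
#' interact, and an individual is an inferred instance of class `X` exactly
#' when `X` holds in *every* interpretation of the named classes that
#' satisfies the axioms and the individual's asserted types. The classifier
#' decides this by explicit enumeration of interpretations: equivalence axioms
#' whose definitions are acyclic are evaluated by substitution and the
#' remaining (free) classes are enumerated exhaustively.
#'
#' Consistency is verified first: an individual whose assertions admit no
#' satisfying interpretation (e.g. asserted both `C_x` and `Not_C_x`) raises
#' an error naming the individual.
#'
#' @param document A serialized ontology (RDF/XML text or file path, as
#'   produced by `serialize_ontology(model, "rdfxml")`), or an
#'   `ontology_model`, or the result of [parse_ontology()].
#' @param max_free_classes Guard on the enumeration size: refuse ontologies
#'   with more than this many undefined (free) named classes (default 20).
#' @return An object of class `reasoner_classification`: a named list mapping
#'   each individual to the character vector of named classes it is an
#'   inferred instance of.
#' @examples
#' trial <- validate_trial(trial_definition("ct", c("I0", "I1"), c("E0", "E1")))
#' m <- build_ontology(trial, patients = list(
#'   patient_record("p1", c(I0 = TRUE, I1 = TRUE, E0 = FALSE, E1 = FALSE))))
#' cls <- classify_with_reasoner(serialize_ontology(m))
#' "Ct_ct_include" %in% cls$memberships$p1
#' @export
classify_with_reasoner <- function(document, max_free_classes = 20) {
  parsed <- if (inherits(document, "ontology_model")) {
    parse_ontology(serialize_rdfxml(document))
  } else if (is.list(document) && !is.null(document$equivalences)) {
    document
  } else {
    parse_ontology(document)
  }

  atoms <- unique(c(parsed$classes,
                    unlist(lapply(parsed$equivalences, function(a)
                      c(a$lhs, expr_atoms(a$rhs)))),
                    unlist(lapply(parsed$subclasses, function(a) c(a$sub, a$sup))),
                    unlist(parsed$individuals)))

  # Equivalence axioms with a unique, acyclically-defined left-hand side are
  # treated as definitions (evaluated by substitution); any others remain
  # constraints checked on every interpretation.
  lhs_all <- vapply(parsed$equivalences, function(a) a$lhs, character(1))
  defs <- list()
  constraints <- list()
  for (a in parsed$equivalences) {
    if (sum(lhs_all == a$lhs) == 1 && !a$lhs %in% expr_atoms(a$rhs)) {
      defs[[a$lhs]] <- a$rhs
    } else {
      constraints[[length(constraints) + 1]] <- a
    }
  }
  order <- topo_order_defs(defs)
  if (is.null(order)) { # cyclic definitions: fall back to pure constraints
    constraints <- c(constraints, lapply(names(defs), function(l)
      list(lhs = l, rhs = defs[[l]])))
    defs <- list()
    order <- character()
  }
  free <- setdiff(atoms, names(defs))
  if (length(free) > max_free_classes) {
    stop("ontology has ", length(free), " free named classes; enumeration ",
         "limit is ", max_free_classes, call. = FALSE)
  }

  # All 2^f interpretations of the free classes, as columns of logicals.
  n_rows <- 2^length(free)
  env <- list()
  for (k in seq_along(free)) {
    env[[free[k]]] <- rep(c(FALSE, TRUE), each = 2^(k - 1),
                          length.out = n_rows)
  }
  for (d in order) env[[d]] <- eval_expr(defs[[d]], env, n_rows)

  ok <- rep(TRUE, n_rows)
  for (a in constraints) {
    ok <- ok & (env[[a$lhs]] == eval_expr(a$rhs, env, n_rows))
  }
  for (s in parsed$subclasses) {
    ok <- ok & (!env[[s$sub]] | env[[s$sup]])
  }

  memberships <- lapply(parsed$individuals, function(types) {
    sat <- ok
    for (ty in types) sat <- sat & env[[ty]]
    if (!any(sat)) return(NULL) # flagged below
    entailed <- vapply(atoms, function(cl) all(env[[cl]][sat]), logical(1))
    atoms[entailed]
  })
  inconsistent <- names(memberships)[vapply(memberships, is.null, logical(1))]
  if (length(inconsistent)) {
    stop("inconsistent ontology: individual(s) ",
         paste(inconsistent, collapse = ", "),
         " have unsatisfiable type assertions", call. = FALSE)
  }
  structure(list(base_iri = parsed$base_iri, memberships = memberships),
            class = "reasoner_classification")
}

expr_atoms <- function(expr) {
  switch(expr$kind,
    named = expr$name,
    and = , or = unlist(lapply(expr$args, expr_atoms)),
    not = expr_atoms(expr$arg),
    character()
  )
}

eval_expr <- function(expr, env, n_rows) {
  switch(expr$kind,
    named = {
      v <- env[[expr$name]]
      if (is.null(v)) stop("undeclared class in expression: ", expr$name,
                           call. = FALSE)
      v
    },
    thing = rep(TRUE, n_rows),
    nothing = rep(FALSE, n_rows),
    and = Reduce(`&`, lapply(expr$args, eval_expr, env = env, n_rows = n_rows),
                 rep(TRUE, n_rows)),
    or = Reduce(`|`, lapply(expr$args, eval_expr, env = env, n_rows = n_rows),
                rep(FALSE, n_rows)),
    not = !eval_expr(expr$arg, env, n_rows)
  )
}

# Kahn-style topological order of definition names; NULL on a cycle.
topo_order_defs <- function(defs) {
  if (!length(defs)) return(character())
  names_d <- names(defs)
  deps <- lapply(defs, function(e) intersect(expr_atoms(e), names_d))
  order <- character()
  remaining <- names_d
  repeat {
    ready <- remaining[vapply(remaining, function(n)
      !any(deps[[n]] %in% remaining), logical(1))]
    if (!length(ready)) {
      return(if (length(remaining)) NULL else order)
    }
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) return(order)
  }
}

#' @export
print.reasoner_classification <- function(x, ...) {
  cat(sprintf("reasoner classification of %d individual(s)\n",
              length(x$memberships)))
  invisible(x)
}

#' Map reasoner memberships to eligibility decisions
#'
#' For one trial, converts the inferred class memberships of each individual
#' into a screening decision: membership in the trial's `_include` class means
#' `ELIGIBLE`; membership in `Ct_k_exclude` or either of its cause subclasses
#' means `NOT_ELIGIBLE`; membership in neither means `UNDETERMINED`.
#'
#' @param classification A `reasoner_classification`.
#' @param trial A validated [trial_definition()].
#' @return Named character vector of decisions, one per individual.
#' @export
reasoner_decisions <- function(classification, trial) {
  assert_validated_trial(trial)
  tf <- sanitize_fragment(trial$trial_id)
  include_cls <- paste0("Ct_", tf, "_include")
  exclude_cls <- paste0("Ct_", tf, c(
    "_exclude", "_exclude_at_least_one_exclusion_criterion",
    "_exclude_at_least_one_failed_inclusion_criterion"))
  vapply(classification$memberships, function(m) {
    if (include_cls %in% m) "ELIGIBLE"
    else if (any(exclude_cls %in% m)) "NOT_ELIGIBLE"
    else "UNDETERMINED"
  }, character(1))
}

#' Cross-check the Kleene engine against the OWL classifier
#'
#' Compiles the trials and patients into the ontology design pattern,
#' serializes and re-parses the document, classifies every patient individual
#' with the built-in instance classifier, maps memberships to decisions, and
#' diffs those against [evaluate_open_world()]. The two routes are
#' independent — three-valued evaluation of the criterion lists versus
#' classical entailment over the compiled axioms — and are expected to agree
#' on every patient; any deviation is returned.
#'
#' @param trials List of validated [trial_definition()]s (or a single trial).
#' @param registry Optional [criterion_registry()] (see [build_ontology()]).
#' @param patients List of [patient_record()]s.
#' @param base_iri Base IRI for the generated ontology.
#' @return A `data.frame` of deviations with columns `trial_id`, `patient_id`,
#'   `engine_decision`, `reasoner_decision`; zero rows when the two routes
#'   agree everywhere.
#' @examples
#' trial <- validate_trial(trial_definition("ct", "I0", "E0"))
#' pts <- list(patient_record("a", c(I0 = TRUE)))
#' nrow(crosscheck_engine_vs_reasoner(trial, patients = pts)) # 0
#' @export
crosscheck_engine_vs_reasoner <- function(trials, registry = NULL,
                                          patients = list(),
                                          base_iri = "http://example.org/eligibility") {
  if (inherits(trials, "trial_definition")) trials <- list(trials)
  model <- build_ontology(trials, registry, patients, base_iri)
  classification <- classify_with_reasoner(serialize_ontology(model, "rdfxml"))
  deviations <- data.frame(trial_id = character(), patient_id = character(),
                           engine_decision = character(),
                           reasoner_decision = character(),
                           stringsAsFactors = FALSE)
  for (trial in trials) {
    rd <- reasoner_decisions(classification, trial)
    for (p in patients) {
      engine <- evaluate_open_world(trial, p)$decision
      reasoner <- rd[[sanitize_fragment(p$patient_id)]]
      if (!identical(engine, reasoner)) {
        deviations <- rbind(deviations, data.frame(
          trial_id = trial$trial_id, patient_id = p$patient_id,
          engine_decision = engine, reasoner_decision = reasoner,
          stringsAsFactors = FALSE))
      }
    }
  }
  deviations
}
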