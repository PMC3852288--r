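# Class-expression constructors used by the ontology model. Expressions are
# plain lists: named classes, intersections, unions, complements, and the two
# constants owl:Thing / owl:Nothing.
ce_named <- function(name) list(kind = "named", name = name)
ce_and <- function(args) list(kind = "and", args = args)
ce_or <- function(args) list(kind = "or", args = args)
ce_not <- function(arg) list(kind = "not", arg = arg)
ce_thing <- function() list(kind = "thing")
ce_nothing <- function() list(kind = "nothing")

# Sanitize an id into an OWL class-name fragment: non-alphanumerics become
# underscores. The result must be a legal NCName once prefixed.
sanitize_fragment <- function(id) {
  gsub("[^A-Za-z0-9_]", "_", as.character(id))
}

assert_ncname <- function(name) {
  bad <- !grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)
  if (any(bad)) {
    stop("IRI-illegal name(s) after sanitization: ",
         paste(sQuote(name[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(name)
}

#' Compile trials and patients into the eligibility ontology design pattern
#'
#' Builds an OWL 2 ontology model realizing the eligibility design pattern:
#'
#' * one root class `Criterion`;
#' * per criterion `x`, a class `C_x` and a class `Not_C_x` axiomatized as
#'   `Not_C_x == Criterion and not C_x` — the *certain absence* of the
#'   criterion, distinct (under the open world assumption) from the mere
#'   absence of a `C_x` assertion;
#' * per trial `k`, a placeholder class `Ct_k` and under it:
#'   `Ct_k_include` equivalent to the intersection of all inclusion `C`
#'   classes and all exclusion `Not_C` classes; a placeholder `Ct_k_exclude`;
#'   and its two subclasses `Ct_k_exclude_at_least_one_exclusion_criterion`
#'   (equivalent to the union of the exclusion `C` classes) and
#'   `Ct_k_exclude_at_least_one_failed_inclusion_criterion` (equivalent to
#'   the union of the inclusion `Not_C` classes);
#' * one named individual per patient, asserted an instance of `C_x` for every
#'   criterion known true, of `Not_C_x` for every criterion known false, and of
#'   nothing at all for unknown criteria. Each patient is also asserted an
#'   instance of the `Criterion` root so that the `Not_C_x` definitions can
#'   classify it.
#'
#' A model with `c` criteria and `t` trials declares `1 + 2c + 5t` classes.
#'
#' @param trials List of validated [trial_definition()]s (a single trial may
#'   be passed bare).
#' @param registry A [criterion_registry()] covering all criteria to declare;
#'   if `NULL`, the union of the trials' criteria and the patients' status
#'   keys is used.
#' @param patients List of [patient_record()]s (may be empty).
#' @param base_iri Base IRI of the ontology; class and individual IRIs are
#'   `base_iri#fragment`.
#' @return An object of class `ontology_model` with fields `base_iri`,
#'   `classes`, `axioms` (equivalence and subclass axioms over class
#'   expressions) and `individuals` (named list: patient id -> character
#'   vector of asserted class names).
#' @examples
#' trial <- validate_trial(trial_definition("ct", c("I0", "I1"), c("E0", "E1")))
#' m <- build_ontology(trial, patients = list(
#'   patient_record("p1", c(I0 = TRUE, I1 = TRUE, E0 = FALSE, E1 = FALSE))))
#' length(m$classes) # 1 + 2*4 + 5*1 = 14
#' @export
build_ontology <- function(trials, registry = NULL, patients = list(),
                           base_iri = "http://example.org/eligibility") {
  if (inherits(trials, "trial_definition")) trials <- list(trials)
  lapply(trials, assert_validated_trial)
  if (is.null(registry)) {
    ids <- unique(c(
      unlist(lapply(trials, function(t) c(t$inclusion, t$exclusion))),
      unlist(lapply(patients, function(p) names(p$statuses)))
    ))
    registry <- criterion_registry(ids)
  }
  crit <- sanitize_fragment(registry$id)
  if (anyDuplicated(crit)) {
    stop("criterion ids collide after sanitization: ",
         paste(unique(crit[duplicated(crit)]), collapse = ", "), call. = FALSE)
  }
  frag_of <- stats::setNames(crit, registry$id)

  classes <- "Criterion"
  axioms <- list()
  add_axiom <- function(ax) axioms[[length(axioms) + 1]] <<- ax

  for (f in crit) {
    c_cls <- paste0("C_", f)
    not_cls <- paste0("Not_C_", f)
    classes <- c(classes, c_cls, not_cls)
    add_axiom(list(type = "equivalent", lhs = not_cls,
                   rhs = ce_and(list(ce_named("Criterion"),
                                     ce_not(ce_named(c_cls))))))
  }

  for (trial in trials) {
    tf <- sanitize_fragment(trial$trial_id)
    ct <- paste0("Ct_", tf)
    ct_inc <- paste0(ct, "_include")
    ct_exc <- paste0(ct, "_exclude")
    ct_exc_e <- paste0(ct, "_exclude_at_least_one_exclusion_criterion")
    ct_exc_i <- paste0(ct, "_exclude_at_least_one_failed_inclusion_criterion")
    classes <- c(classes, ct, ct_inc, ct_exc, ct_exc_e, ct_exc_i)
    inc_c <- lapply(unname(frag_of[trial$inclusion]),
                    function(f) ce_named(paste0("C_", f)))
    exc_notc <- lapply(unname(frag_of[trial$exclusion]),
                       function(f) ce_named(paste0("Not_C_", f)))
    exc_c <- lapply(unname(frag_of[trial$exclusion]),
                    function(f) ce_named(paste0("C_", f)))
    inc_notc <- lapply(unname(frag_of[trial$inclusion]),
                       function(f) ce_named(paste0("Not_C_", f)))
    add_axiom(list(type = "equivalent", lhs = ct_inc,
                   rhs = ce_and(c(inc_c, exc_notc))))
    add_axiom(list(type = "subclass", sub = ct_inc, sup = ct))
    add_axiom(list(type = "equivalent", lhs = ct_exc_e, rhs = ce_or(exc_c)))
    add_axiom(list(type = "equivalent", lhs = ct_exc_i, rhs = ce_or(inc_notc)))
    add_axiom(list(type = "subclass", sub = ct_exc_e, sup = ct_exc))
    add_axiom(list(type = "subclass", sub = ct_exc_i, sup = ct_exc))
    add_axiom(list(type = "subclass", sub = ct_exc, sup = ct))
  }
  if (anyDuplicated(classes)) {
    stop("trial ids collide after sanitization", call. = FALSE)
  }
  assert_ncname(classes)

  individuals <- list()
  for (p in patients) {
    pid <- sanitize_fragment(p$patient_id)
    assert_ncname(pid)
    if (pid %in% names(individuals)) {
      stop("duplicate patient id after sanitization: ", pid, call. = FALSE)
    }
    unknown_crit <- setdiff(names(p$statuses), registry$id)
    if (length(unknown_crit)) {
      stop("patient '", p$patient_id, "' references unregistered criterion ",
           "id(s): ", paste(unknown_crit, collapse = ", "), call. = FALSE)
    }
    s <- p$statuses
    types <- c(
      "Criterion",
      paste0("C_", unname(frag_of[names(s)[!is.na(s) & s]])),
      paste0("Not_C_", unname(frag_of[names(s)[!is.na(s) & !s]]))
    )
    individuals[[pid]] <- types
  }

  structure(list(base_iri = base_iri, classes = classes, axioms = axioms,
                 individuals = individuals),
            class = "ontology_model")
}

#' @export
print.ontology_model <- function(x, ...) {
  n_eq <- sum(vapply(x$axioms, function(a) a$type == "equivalent", logical(1)))
  n_sub <- sum(vapply(x$axioms, function(a) a$type == "subclass", logical(1)))
  cat(sprintf(
    "ontology model <%s>: %d classes, %d equivalence + %d subclass axioms, %d individuals\n",
    x$base_iri, length(x$classes), n_eq, n_sub, length(x$individuals)))
  invisible(x)
}
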