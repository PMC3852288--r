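OWL_NS <- "http://www.w3.org/2002/07/owl#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"

iri_of <- function(model, name) paste0(model$base_iri, "#", name)

#' Serialize an ontology model
#'
#' Writes an [build_ontology()] model as a standards-conformant OWL 2
#' document. Three serializations are supported: RDF/XML (the default and the
#' format [parse_ontology()] reads back), Turtle, and OWL functional syntax.
#' The RDF/XML and Turtle serializations denote the same RDF graph (class
#' expressions become the usual `owl:intersectionOf` / `owl:unionOf` /
#' `owl:complementOf` structures with blank nodes and RDF collections); output
#' is deterministic so serializations are diff-stable.
#'
#' @param model An `ontology_model`.
#' @param format One of `"rdfxml"` (aliases `"rdf/xml"`, `"xml"`),
#'   `"turtle"` (`"ttl"`) or `"ofn"` (`"functional"`).
#' @return A single string containing the document.
#' @examples
#' trial <- validate_trial(trial_definition("ct", "I0", "E0"))
#' cat(substr(serialize_ontology(build_ontology(trial), "turtle"), 1, 200))
#' @export
serialize_ontology <- function(model, format = "rdfxml") {
  stopifnot(inherits(model, "ontology_model"))
  fmt <- tolower(format)
  if (fmt %in% c("rdfxml", "rdf/xml", "xml")) {
    serialize_rdfxml(model)
  } else if (fmt %in% c("turtle", "ttl")) {
    serialize_turtle(model)
  } else if (fmt %in% c("ofn", "functional", "owl-functional")) {
    serialize_ofn(model)
  } else {
    stop("unsupported serialization format: ", sQuote(format), call. = FALSE)
  }
}

# ---- RDF/XML ----------------------------------------------------------------

serialize_rdfxml <- function(model) {
  doc <- xml2::xml_new_root("rdf:RDF",
    "xmlns:rdf" = RDF_NS, "xmlns:owl" = OWL_NS, "xmlns:rdfs" = RDFS_NS)
  xml2::xml_add_child(doc, "owl:Ontology", "rdf:about" = model$base_iri)

  eq_by_lhs <- split_axioms(model, "equivalent")
  sub_by_lhs <- split_axioms(model, "subclass")

  for (cls in model$classes) {
    node <- xml2::xml_add_child(doc, "owl:Class",
                                "rdf:about" = iri_of(model, cls))
    for (ax in eq_by_lhs[[cls]]) {
      eq <- xml2::xml_add_child(node, "owl:equivalentClass")
      add_expr_xml(eq, ax$rhs, model)
    }
    for (ax in sub_by_lhs[[cls]]) {
      xml2::xml_add_child(node, "rdfs:subClassOf",
                          "rdf:resource" = iri_of(model, ax$sup))
    }
  }
  for (pid in names(model$individuals)) {
    node <- xml2::xml_add_child(doc, "owl:NamedIndividual",
                                "rdf:about" = iri_of(model, pid))
    for (ty in model$individuals[[pid]]) {
      xml2::xml_add_child(node, "rdf:type", "rdf:resource" = iri_of(model, ty))
    }
  }
  as.character(doc)
}

split_axioms <- function(model, type) {
  axs <- Filter(function(a) a$type == type, model$axioms)
  keys <- vapply(axs, function(a) if (type == "equivalent") a$lhs else a$sub,
                 character(1))
  split(axs, factor(keys, levels = unique(keys)))
}

# Serialize a class expression under `parent`. Intersections/unions of one
# member collapse to the member; empty ones are owl:Thing / owl:Nothing.
add_expr_xml <- function(parent, expr, model) {
  expr <- simplify_expr(expr)
  switch(expr$kind,
    named = {
      # as attribute when parent expects a resource (equivalentClass,
      # complementOf), as node inside collections
      if (xml2::xml_name(parent) %in% c("equivalentClass", "complementOf")) {
        xml2::xml_set_attr(parent, "rdf:resource", iri_of(model, expr$name))
      } else {
        xml2::xml_add_child(parent, "owl:Class",
                            "rdf:about" = iri_of(model, expr$name))
      }
    },
    thing = xml2::xml_set_attr(parent, "rdf:resource", paste0(OWL_NS, "Thing")),
    nothing = xml2::xml_set_attr(parent, "rdf:resource", paste0(OWL_NS, "Nothing")),
    and = ,
    or = {
      cls <- xml2::xml_add_child(parent, "owl:Class")
      coll <- xml2::xml_add_child(
        cls, if (expr$kind == "and") "owl:intersectionOf" else "owl:unionOf",
        "rdf:parseType" = "Collection")
      for (a in expr$args) add_expr_xml(coll, a, model)
    },
    not = {
      cls <- xml2::xml_add_child(parent, "owl:Class")
      comp <- xml2::xml_add_child(cls, "owl:complementOf")
      add_expr_xml(comp, expr$arg, model)
    }
  )
  invisible(parent)
}

simplify_expr <- function(expr) {
  if (expr$kind == "and") {
    if (length(expr$args) == 0) return(ce_thing())
    if (length(expr$args) == 1) return(simplify_expr(expr$args[[1]]))
  }
  if (expr$kind == "or") {
    if (length(expr$args) == 0) return(ce_nothing())
    if (length(expr$args) == 1) return(simplify_expr(expr$args[[1]]))
  }
  expr
}

# ---- Turtle -----------------------------------------------------------------

serialize_turtle <- function(model) {
  lines <- c(
    sprintf("@prefix : <%s#> .", model$base_iri),
    sprintf("@prefix owl: <%s> .", OWL_NS),
    sprintf("@prefix rdf: <%s> .", RDF_NS),
    sprintf("@prefix rdfs: <%s> .", RDFS_NS),
    "",
    sprintf("<%s> a owl:Ontology .", model$base_iri),
    ""
  )
  eq_by_lhs <- split_axioms(model, "equivalent")
  sub_by_lhs <- split_axioms(model, "subclass")
  for (cls in model$classes) {
    parts <- "a owl:Class"
    for (ax in eq_by_lhs[[cls]]) {
      parts <- c(parts, paste0("owl:equivalentClass ", expr_ttl(ax$rhs)))
    }
    for (ax in sub_by_lhs[[cls]]) {
      parts <- c(parts, paste0("rdfs:subClassOf :", ax$sup))
    }
    lines <- c(lines, paste0(":", cls, " ", paste(parts, collapse = " ;\n    "), " ."))
  }
  lines <- c(lines, "")
  for (pid in names(model$individuals)) {
    types <- c("owl:NamedIndividual",
               paste0(":", model$individuals[[pid]]))
    lines <- c(lines, paste0(":", pid, " a ", paste(types, collapse = ", "), " ."))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

expr_ttl <- function(expr) {
  expr <- simplify_expr(expr)
  switch(expr$kind,
    named = paste0(":", expr$name),
    thing = "owl:Thing",
    nothing = "owl:Nothing",
    and = paste0("[ a owl:Class ; owl:intersectionOf ( ",
                 paste(vapply(expr$args, expr_ttl, character(1)), collapse = " "),
                 " ) ]"),
    or = paste0("[ a owl:Class ; owl:unionOf ( ",
                paste(vapply(expr$args, expr_ttl, character(1)), collapse = " "),
                " ) ]"),
    not = paste0("[ a owl:Class ; owl:complementOf ", expr_ttl(expr$arg), " ]")
  )
}

# ---- OWL functional syntax --------------------------------------------------

serialize_ofn <- function(model) {
  pfx <- function(name) paste0(":", name)
  lines <- c(
    sprintf("Prefix(:=<%s#>)", model$base_iri),
    sprintf("Prefix(owl:=<%s>)", OWL_NS),
    sprintf("Ontology(<%s>", model$base_iri),
    paste0("Declaration(Class(", pfx(model$classes), "))")
  )
  for (ax in model$axioms) {
    lines <- c(lines, if (ax$type == "equivalent") {
      sprintf("EquivalentClasses(%s %s)", pfx(ax$lhs), expr_ofn(ax$rhs))
    } else {
      sprintf("SubClassOf(%s %s)", pfx(ax$sub), pfx(ax$sup))
    })
  }
  for (pid in names(model$individuals)) {
    lines <- c(lines,
               paste0("Declaration(NamedIndividual(", pfx(pid), "))"),
               sprintf("ClassAssertion(%s %s)",
                       pfx(model$individuals[[pid]]), pfx(pid)))
  }
  paste0(paste(c(lines, ")"), collapse = "\n"), "\n")
}

expr_ofn <- function(expr) {
  expr <- simplify_expr(expr)
  switch(expr$kind,
    named = paste0(":", expr$name),
    thing = "owl:Thing",
    nothing = "owl:Nothing",
    and = paste0("ObjectIntersectionOf(",
                 paste(vapply(expr$args, expr_ofn, character(1)), collapse = " "), ")"),
    or = paste0("ObjectUnionOf(",
                paste(vapply(expr$args, expr_ofn, character(1)), collapse = " "), ")"),
    not = paste0("ObjectComplementOf(", expr_ofn(expr$arg), ")")
  )
}

# ---- Parse-back (RDF/XML) ---------------------------------------------------

#' Parse an RDF/XML eligibility ontology back into an axiom model
#'
#' Reads an RDF/XML document produced by [serialize_ontology()] (or any
#' document restricted to the same vocabulary: class declarations, equivalence
#' axioms over Boolean class expressions, subclass axioms between named
#' classes, and named individuals with named-class type assertions) and
#' returns its axioms. This is the input format of the built-in instance
#' classifier, [classify_with_reasoner()].
#'
#' @param text RDF/XML document as a single string, or a file path.
#' @return A list with elements `base_iri`, `classes` (character),
#'   `equivalences` (list of `lhs`/`rhs` expression pairs), `subclasses`
#'   (list of `sub`/`sup` pairs) and `individuals` (named list: individual ->
#'   character vector of asserted class names).
#' @export
parse_ontology <- function(text) {
  doc <- xml2::read_xml(text)
  ns <- c(rdf = RDF_NS, owl = OWL_NS, rdfs = RDFS_NS)

  frag <- function(iri) sub("^.*#", "", iri)
  top_classes <- xml2::xml_find_all(doc, "./owl:Class[@rdf:about]", ns)
  classes <- vapply(top_classes, function(n)
    frag(xml2::xml_attr(n, "rdf:about", ns)), character(1))

  equivalences <- list()
  subclasses <- list()
  for (node in top_classes) {
    lhs <- frag(xml2::xml_attr(node, "rdf:about", ns))
    for (eq in xml2::xml_find_all(node, "./owl:equivalentClass", ns)) {
      equivalences[[length(equivalences) + 1]] <-
        list(lhs = lhs, rhs = parse_expr_xml(eq, ns))
    }
    for (sc in xml2::xml_find_all(node, "./rdfs:subClassOf", ns)) {
      sup <- xml2::xml_attr(sc, "rdf:resource", ns)
      if (is.na(sup)) stop("subClassOf with a non-named superclass is not supported",
                           call. = FALSE)
      subclasses[[length(subclasses) + 1]] <- list(sub = lhs, sup = frag(sup))
    }
  }

  individuals <- list()
  for (node in xml2::xml_find_all(doc, "./owl:NamedIndividual[@rdf:about]", ns)) {
    pid <- frag(xml2::xml_attr(node, "rdf:about", ns))
    types <- vapply(xml2::xml_find_all(node, "./rdf:type", ns), function(t) {
      r <- xml2::xml_attr(t, "rdf:resource", ns)
      if (is.na(r)) stop("type assertions must reference named classes", call. = FALSE)
      frag(r)
    }, character(1))
    individuals[[pid]] <- types
  }

  base_iri <- xml2::xml_attr(
    xml2::xml_find_first(doc, "./owl:Ontology", ns), "about", ns)
  list(base_iri = base_iri, classes = classes, equivalences = equivalences,
       subclasses = subclasses, individuals = individuals)
}

# Parse the class expression held by `node` (an equivalentClass/complementOf
# element or a member of a collection).
parse_expr_xml <- function(node, ns) {
  res <- xml2::xml_attr(node, "rdf:resource", ns)
  if (!is.na(res)) return(named_or_constant(res))
  about <- xml2::xml_attr(node, "rdf:about", ns)
  if (!is.na(about) && xml2::xml_name(node) == "Class") {
    return(named_or_constant(about))
  }
  # descend into a bnode owl:Class (or we are already at one)
  cls <- if (xml2::xml_name(node) == "Class") node else {
    xml2::xml_find_first(node, "./owl:Class", ns)
  }
  if (inherits(cls, "xml_missing")) {
    stop("unsupported class expression in document", call. = FALSE)
  }
  inter <- xml2::xml_find_first(cls, "./owl:intersectionOf", ns)
  if (!inherits(inter, "xml_missing")) {
    return(ce_and(lapply(xml2::xml_children(inter), parse_expr_xml, ns = ns)))
  }
  un <- xml2::xml_find_first(cls, "./owl:unionOf", ns)
  if (!inherits(un, "xml_missing")) {
    return(ce_or(lapply(xml2::xml_children(un), parse_expr_xml, ns = ns)))
  }
  comp <- xml2::xml_find_first(cls, "./owl:complementOf", ns)
  if (!inherits(comp, "xml_missing")) {
    return(ce_not(parse_expr_xml(comp, ns)))
  }
  stop("unsupported class expression in document", call. = FALSE)
}

named_or_constant <- function(iri) {
  if (iri == paste0(OWL_NS, "Thing")) return(ce_thing())
  if (iri == paste0(OWL_NS, "Nothing")) return(ce_nothing())
  ce_named(sub("^.*#", "", iri))
}
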