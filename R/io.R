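#' Read trial definitions from a YAML or JSON file
#'
#' The document is either one trial object or a list of them; each object has
#' `trial_id`, optional `inclusion` and `exclusion` arrays of criterion ids,
#' and an optional `labels` map (criterion id -> free text) contributing to
#' the returned registry.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with `trials` (list of validated [trial_definition()]s) and
#'   `registry` (a [criterion_registry()] of every referenced criterion).
#' @export
read_trial_definitions <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(doc$trial_id)) doc <- list(doc)
  labels <- list()
  trials <- lapply(doc, function(d) {
    if (is.null(d$trial_id)) stop("trial entry without trial_id in ", path,
                                  call. = FALSE)
    for (nm in names(d$labels)) labels[[nm]] <<- d$labels[[nm]]
    trial_definition(d$trial_id,
                     inclusion = as.character(unlist(d$inclusion)),
                     exclusion = as.character(unlist(d$exclusion)))
  })
  ids <- unique(c(unlist(lapply(trials, function(t) c(t$inclusion, t$exclusion))),
                  normalize_criterion_id(names(labels))))
  lab <- vapply(ids, function(i) {
    v <- labels[[i]]
    if (is.null(v)) i else as.character(v)
  }, character(1))
  registry <- criterion_registry(ids, lab)
  trials <- lapply(trials, validate_trial, registry = registry)
  list(trials = trials, registry = registry)
}

#' Read patient criterion statuses from a CSV file
#'
#' Expected layout: a header row with `patient_id` followed by one column per
#' criterion id; cells use the [parse_truth_value()] alphabet (`T`/`F`/`?`,
#' `yes`/`no`/`not specified`, `1`/`0`, empty = unknown).
#'
#' @param path Path to the CSV file.
#' @param registry Optional [criterion_registry()] to check column names
#'   against.
#' @return List of [patient_record()]s in file order.
#' @export
read_patient_statuses <- function(path, registry = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!"patient_id" %in% names(tab)) {
    stop("status file must have a patient_id column: ", path, call. = FALSE)
  }
  crit <- setdiff(names(tab), "patient_id")
  lapply(seq_len(nrow(tab)), function(i) {
    statuses <- parse_truth_value(unlist(tab[i, crit, drop = FALSE]))
    names(statuses) <- crit
    patient_record(tab$patient_id[i], statuses[!is.na(statuses)],
                   registry = registry)
  })
}

#' Write patient criterion statuses to CSV
#'
#' Inverse of [read_patient_statuses()]: unknown statuses (absent or `NA`)
#' are written as `"?"`, known ones as `"T"`/`"F"`.
#'
#' @param patients List of [patient_record()]s.
#' @param path Output CSV path.
#' @param ids Criterion columns to write; defaults to the union of all status
#'   keys, in first-seen order.
#' @return `path`, invisibly.
#' @export
write_patient_statuses <- function(patients, path, ids = NULL) {
  if (is.null(ids)) {
    ids <- unique(unlist(lapply(patients, function(p) names(p$statuses))))
  }
  rows <- lapply(patients, function(p) {
    v <- patient_status_vec(p, ids)
    c(p$patient_id, ifelse(is.na(v), "?", ifelse(v, "T", "F")))
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- c("patient_id", ids)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read binding rules from a YAML file
#'
#' The document is a list of `{criterion, field, comparator, operand}`
#' entries; `operand` may be a scalar or (for `in`/`not_in`) a list.
#'
#' @param path Path to the YAML file.
#' @return List of [binding_rule()]s.
#' @export
read_binding_rules <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc, function(d) {
    binding_rule(d$criterion, d$field, d$comparator,
                 operand = if (is.null(d$operand)) NULL else unlist(d$operand))
  })
}

#' Read a raw patient field table from CSV
#'
#' Cells equal to the empty string, `NA` or `"not specified"`
#' (case-insensitive) are read as missing.
#'
#' @param path Path to the CSV file (must have a `patient_id` column).
#' @return A `data.frame`.
#' @export
read_field_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  if (!"patient_id" %in% names(tab)) {
    stop("field table must have a patient_id column: ", path, call. = FALSE)
  }
  tab
}

#' Export a cohort classification
#'
#' `write_classification_tsv()` writes one row per patient (`patient_id`,
#' `decision`, cause lists joined with `";"`). `write_classification_json()`
#' writes the same content plus the decision counts as JSON.
#'
#' @param classification A [classify_cohort()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(classification, path) {
  utils::write.table(as.data.frame(classification), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_classification_tsv
#' @export
write_classification_json <- function(classification, path) {
  df <- as.data.frame(classification)
  doc <- list(trial_id = classification$trial_id,
              counts = as.list(classification$counts),
              patients = df)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
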