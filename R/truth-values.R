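#' Three-valued criterion statuses
#'
#' A criterion status for a patient is one of *true* (the criterion is known
#' to be met), *false* (known not to be met) or *unknown* (the record does not
#' allow a decision). `owascreen` represents the three states as an R logical
#' scalar: `TRUE`, `FALSE` or `NA`. Base R's logical operators on `NA` follow
#' exactly the strong Kleene truth tables, which is the semantics used
#' throughout the package: a conjunction is false as soon as one conjunct is
#' false, unknown if no conjunct is false but at least one is unknown, and
#' true otherwise.
#'
#' `parse_truth_value()` maps the textual encodings found in status tables and
#' case-report forms onto the three states (case-insensitively, after
#' trimming):
#'
#' * `"T"`, `"true"`, `"yes"`, `"1"` -> `TRUE`
#' * `"F"`, `"false"`, `"no"`, `"0"` -> `FALSE`
#' * `"?"`, `"U"`, `"unknown"`, `"not specified"`, `""` (and `NA`) -> `NA`
#'
#' Any other token is an error: silent coercion of an unrecognized answer to
#' one of the three states would defeat the point of tracking ignorance.
#'
#' @param x Character vector of status tokens.
#' @return `parse_truth_value()`: a logical vector the same length as `x`.
#'   `format_truth_value()`: a character vector with elements `"TRUE"`,
#'   `"FALSE"` or `"UNKNOWN"`.
#' @examples
#' parse_truth_value(c("T", "no", "not specified", ""))
#' format_truth_value(c(TRUE, NA))
#' @export
parse_truth_value <- function(x) {
  x <- as.character(x)
  tok <- tolower(trimws(x))
  tok[is.na(x)] <- ""
  out <- rep(NA, length(tok))
  true_tokens <- c("t", "true", "yes", "1")
  false_tokens <- c("f", "false", "no", "0")
  unknown_tokens <- c("?", "u", "unknown", "not specified", "")
  out[tok %in% true_tokens] <- TRUE
  out[tok %in% false_tokens] <- FALSE
  bad <- !(tok %in% c(true_tokens, false_tokens, unknown_tokens))
  if (any(bad)) {
    stop("unrecognized truth value token(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname parse_truth_value
#' @export
format_truth_value <- function(x) {
  ifelse(is.na(x), "UNKNOWN", ifelse(x, "TRUE", "FALSE"))
}

#' Strong Kleene connectives
#'
#' Negation and conjunction lifted to three-valued statuses (logical vectors
#' with `NA` standing for *unknown*). `kleene_not()` swaps `TRUE` and `FALSE`
#' and leaves `NA` fixed: negation preserves ignorance. `kleene_and()` returns
#' `FALSE` if any element is `FALSE`, otherwise `NA` if any element is `NA`,
#' otherwise `TRUE`; the empty conjunction is `TRUE`.
#'
#' These are the semantics of eligibility as a uniform conjunction of the
#' inclusion criteria and the negated exclusion criteria: a single criterion
#' known to fail decides the patient regardless of any remaining unknowns,
#' while unknowns alone can only withhold the decision, never force it.
#'
#' @param v,vs Logical vectors (`NA` = unknown). `kleene_and()` takes the
#'   conjunction over all elements of `vs`.
#' @return A logical scalar (`kleene_and`) or vector (`kleene_not`).
#' @examples
#' kleene_not(c(TRUE, NA, FALSE))
#' kleene_and(c(TRUE, FALSE, NA)) # FALSE: a failed conjunct decides
#' kleene_and(c(TRUE, NA))        # NA: undetermined
#' kleene_and(logical(0))         # TRUE: empty conjunction
#' @export
kleene_and <- function(vs) {
  stopifnot(is.logical(vs))
  all(vs) # base R all() on logicals with NA is strong Kleene conjunction
}

#' @rdname kleene_and
#' @export
kleene_not <- function(v) {
  stopifnot(is.logical(v))
  !v
}
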