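#' Simulation configuration for synthetic cohorts
#'
#' Describes a synthetic pre-screening cohort: how many patients, which
#' criterion/field ids, the per-id probability that a value is observed at all
#' (`p_known`), the per-id probability that an observed status is true
#' (`p_true`), the ids that are always observed (e.g. administrative fields a
#' form never leaves blank), and the RNG seed. Statuses are independent across
#' ids and across patients; missingness is completely at random.
#'
#' @param n_patients Positive integer.
#' @param ids Character vector of criterion or field ids.
#' @param p_known Probability in `[0, 1]` that a value is observed; scalar or
#'   one per id.
#' @param p_true Probability in `[0, 1]` that an observed status is `TRUE`;
#'   scalar or one per id.
#' @param seed Integer seed; every draw is reproducible from it.
#' @param always_known Subset of `ids` forced to be observed.
#' @return An object of class `simulation_config`. The RNG algorithm used by
#'   the generators is recorded in the `rng_kind` field for provenance.
#' @examples
#' simulation_config(20, c("I0", "I1", "E0"), p_known = 0.5, seed = 1)
#' @export
simulation_config <- function(n_patients, ids, p_known = 1, p_true = 0.5,
                              seed = 1, always_known = character()) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 0) {
    stop("n_patients must be a non-negative integer", call. = FALSE)
  }
  ids <- normalize_criterion_id(ids)
  if (anyDuplicated(ids)) stop("duplicate ids in simulation config", call. = FALSE)
  check_prob <- function(p, what) {
    if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
      stop(what, " must be probabilities in [0, 1]", call. = FALSE)
    }
    if (!length(p) %in% c(1L, length(ids))) {
      stop(what, " must be a scalar or one value per id", call. = FALSE)
    }
    stats::setNames(rep_len(p, length(ids)), ids)
  }
  p_known <- check_prob(p_known, "p_known")
  p_true <- check_prob(p_true, "p_true")
  always_known <- if (length(always_known)) normalize_criterion_id(always_known) else character()
  if (!all(always_known %in% ids)) {
    stop("always_known must be a subset of ids", call. = FALSE)
  }
  p_known[always_known] <- 1
  structure(list(n_patients = n_patients, ids = ids, p_known = p_known,
                 p_true = p_true, seed = as.integer(seed),
                 always_known = always_known,
                 rng_kind = "Mersenne-Twister"),
            class = "simulation_config")
}

#' Study-like simulation preset
#'
#' Configuration emulating the missingness structure observed in the
#' retrospective prostate-cancer pre-screening study the package's defaults
#' are modeled on: a case-report form of 65 fields of which 6 administrative
#' fields (patient identifier, meeting date, birth date, gender, tumor
#' anatomic site, primary histological type) are always filled, 286 cases, and
#' a global observation probability for the remaining 59 fields calibrated so
#' that the expected overall fraction of unspecified values is 0.609.
#'
#' @param n_patients Number of cases (default 286).
#' @param seed Integer seed.
#' @param unknown_fraction Target expected overall fraction of missing values
#'   (default 0.609).
#' @return A [simulation_config()].
#' @examples
#' cfg <- mdm_like_config(seed = 42)
#' length(cfg$ids)            # 65
#' length(cfg$always_known)   # 6
#' @export
mdm_like_config <- function(n_patients = 286, seed = 1,
                            unknown_fraction = 0.609) {
  always <- c("patient_identifier", "mdm_date", "birth_date", "gender",
              "tumor_anatomic_site", "primary_histological_type")
  others <- sprintf("field_%02d", seq_len(65 - length(always)))
  ids <- c(always, others)
  # expected missing fraction = (59/65) * (1 - p); solve for p
  p_other <- 1 - unknown_fraction * 65 / 59
  if (p_other < 0 || p_other > 1) {
    stop("unknown_fraction not attainable with 6 of 65 fields always known",
         call. = FALSE)
  }
  p_known <- c(rep(1, length(always)), rep(p_other, length(others)))
  simulation_config(n_patients, ids, p_known = p_known, p_true = 0.5,
                    seed = seed, always_known = always)
}

with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Generate a synthetic cohort of patient records
#'
#' Draws `n_patients` records over the configured ids: each status is observed
#' independently with probability `p_known[id]` (always, for `always_known`
#' ids); an observed status is `TRUE` with probability `p_true[id]` and
#' `FALSE` otherwise; unobserved ids are *absent* from the record's status
#' map, i.e. unknown. The draw is fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List of [patient_record()]s with ids `"p1"`, `"p2"`, ...
#' @examples
#' cohort <- generate_cohort(simulation_config(3, c("I0", "E0"),
#'                                             p_known = 0.5, seed = 7))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  k <- length(config$ids)
  with_sim_seed(config$seed, {
    lapply(seq_len(config$n_patients), function(i) {
      observed <- stats::runif(k) < config$p_known
      values <- stats::runif(k) < config$p_true
      statuses <- stats::setNames(values[observed], config$ids[observed])
      patient_record(paste0("p", i), statuses)
    })
  })
}

#' Generate a synthetic patient field table
#'
#' Tabular counterpart of [generate_cohort()]: one row per patient, one column
#' per field, with cells drawn from a per-field value model and missing
#' (`NA`) where unobserved. Value models:
#'
#' * `list(kind = "uniform_int", min =, max =)` — uniform integers;
#' * `list(kind = "categorical", levels =, weights =)` — weighted categories
#'   (weights default to uniform).
#'
#' Fields without an entry in `value_model` default to uniform integers 0–1.
#'
#' @param config A [simulation_config()] (its `ids` are the field names).
#' @param value_model Named list of per-field distribution specs.
#' @return A `data.frame` with a `patient_id` column followed by one column
#'   per field.
#' @examples
#' cfg <- simulation_config(5, "gleason", p_known = 1, seed = 3)
#' generate_field_table(cfg, list(gleason = list(kind = "uniform_int",
#'                                               min = 6, max = 10)))
#' @export
generate_field_table <- function(config, value_model = list()) {
  stopifnot(inherits(config, "simulation_config"))
  unknown_fields <- setdiff(names(value_model), config$ids)
  if (length(unknown_fields)) {
    stop("value_model references unknown field(s): ",
         paste(unknown_fields, collapse = ", "), call. = FALSE)
  }
  n <- config$n_patients
  draw_column <- function(field) {
    spec <- value_model[[field]]
    if (is.null(spec)) spec <- list(kind = "uniform_int", min = 0, max = 1)
    if (is.null(spec$kind)) stop("value model for field '", field,
                                 "' has no kind", call. = FALSE)
    switch(spec$kind,
      uniform_int = {
        stopifnot(is.numeric(spec$min), is.numeric(spec$max),
                  spec$min <= spec$max)
        sample(seq(spec$min, spec$max), n, replace = TRUE)
      },
      categorical = {
        w <- spec$weights
        if (is.null(w)) w <- rep(1, length(spec$levels))
        sample(spec$levels, n, replace = TRUE, prob = w)
      },
      stop("unknown value-model kind for field '", field, "': ",
           sQuote(spec$kind), call. = FALSE)
    )
  }
  with_sim_seed(config$seed, {
    tab <- data.frame(patient_id = paste0("p", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (field in config$ids) {
      col <- draw_column(field)
      observed <- stats::runif(n) < config$p_known[[field]]
      col[!observed] <- NA
      tab[[field]] <- col
    }
    tab
  })
}
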