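# Declarative score definitions and evaluation.
#
# Scores are point-based: a list of items, each a predicate over patient
# fields worth a nonnegative number of points. Definitions live in a YAML
# file so clinical corrections never touch code.

# Fields a predicate may reference. Mirrors the per-child record contract.
.patient_fields <- c(
  "child_id", "site", "age_months", "muac_cm", "oedema", "waz",
  "temperature_c", "heart_rate", "resp_rate", "spo2_pct", "cap_refill",
  "consciousness", "convulsions", "deep_breathing", "chest_indrawing",
  "wheeze", "stridor", "prostration", "unable_to_drink", "vomits_everything",
  "refusal_to_feed", "hiv_status", "diarrhoea", "pneumonia_lrti", "malaria",
  "severe_anaemia", "stratum", "pop_weight", "died_inpatient",
  "day_of_death", "day_of_discharge"
)

#' Declared patient-record field names
#'
#' The column contract shared by the score calculators, the cohort
#' simulator and the validation engine.
#'
#' @return Character vector of field names.
#' @export
patient_fields <- function() .patient_fields

.valid_ops <- c("lt", "le", "gt", "ge", "eq", "in", "never")

# ---- predicate DSL ---------------------------------------------------------

# Collect the fields a condition references (for schema validation).
.cond_fields <- function(cond) {
  if (!is.null(cond$all)) return(unlist(lapply(cond$all, .cond_fields)))
  if (!is.null(cond$any)) return(unlist(lapply(cond$any, .cond_fields)))
  fields <- cond$field
  if (!is.null(cond$value_by_age)) fields <- c(fields, "age_months")
  fields
}

.validate_cond <- function(cond, score, item) {
  fail <- function(msg) {
    stop(sprintf("score '%s', item '%s': %s", score, item, msg), call. = FALSE)
  }
  if (!is.null(cond$all) || !is.null(cond$any)) {
    sub <- if (is.null(cond$all)) cond$any else cond$all
    if (!length(sub)) fail("empty composite predicate")
    lapply(sub, .validate_cond, score = score, item = item)
    return(invisible(TRUE))
  }
  op <- cond$op
  if (is.null(op) || !op %in% .valid_ops) {
    fail(sprintf("unknown predicate op '%s'", if (is.null(op)) "<none>" else op))
  }
  if (op == "never") return(invisible(TRUE))
  if (is.null(cond$field) || !cond$field %in% .patient_fields) {
    fail(sprintf("predicate references undeclared field '%s'",
                 if (is.null(cond$field)) "<none>" else cond$field))
  }
  if (is.null(cond$value) && is.null(cond$value_by_age)) {
    fail("predicate needs 'value' or 'value_by_age'")
  }
  if (!is.null(cond$value_by_age)) {
    for (band in cond$value_by_age) {
      if (is.null(band$age_lt) || is.null(band$value)) {
        fail("each age band needs 'age_lt' and 'value'")
      }
    }
  }
  invisible(TRUE)
}

# Evaluate a condition over a cohort data frame. Returns logical, NA where
# a referenced value is missing.
.cond_eval <- function(cond, df) {
  n <- nrow(df)
  if (!is.null(cond$all)) {
    return(Reduce(`&`, lapply(cond$all, .cond_eval, df = df)))
  }
  if (!is.null(cond$any)) {
    return(Reduce(`|`, lapply(cond$any, .cond_eval, df = df)))
  }
  if (cond$op == "never") return(rep(FALSE, n))
  x <- df[[cond$field]]
  if (is.null(x)) x <- rep(NA, n)
  if (!is.null(cond$value_by_age)) {
    age <- df[["age_months"]]
    val <- rep(NA_real_, n)
    # first matching band wins; bands are ordered by age_lt
    for (band in cond$value_by_age[order(vapply(cond$value_by_age,
                                                function(b) b$age_lt, 0))]) {
      val[is.na(val) & !is.na(age) & age < band$age_lt] <- band$value
    }
  } else {
    val <- cond$value
  }
  switch(cond$op,
    lt = x < val,
    le = x <= val,
    gt = x > val,
    ge = x >= val,
    eq = x == val,
    `in` = {
      out <- as.character(x) %in% as.character(unlist(val))
      out[is.na(x)] <- NA
      out
    }
  )
}

# ---- registry --------------------------------------------------------------

.validate_definition <- function(def) {
  name <- def$name
  if (is.null(name) || !nzchar(name)) stop("score definition without a name",
                                           call. = FALSE)
  if (length(def$range) != 2 || def$range[1] != 0) {
    stop(sprintf("score '%s': range must be [0, max]", name), call. = FALSE)
  }
  if (!length(def$items)) {
    stop(sprintf("score '%s': no items", name), call. = FALSE)
  }
  for (item in def$items) {
    if (is.null(item$id)) stop(sprintf("score '%s': item without id", name),
                               call. = FALSE)
    pts <- item$points
    if (is.null(pts) || pts < 0 || pts != round(pts)) {
      stop(sprintf("score '%s', item '%s': points must be a nonnegative integer",
                   name, item$id), call. = FALSE)
    }
    .validate_cond(item$when, name, item$id)
  }
  if (!is.null(def$applicability)) {
    .validate_cond(def$applicability, name, "<applicability>")
  }
  # attainable maximum: ungrouped items sum; grouped items are mutually
  # exclusive levels, only the largest counts
  grp <- vapply(def$items, function(it) {
    if (is.null(it$group)) NA_character_ else it$group
  }, "")
  pts <- vapply(def$items, function(it) as.numeric(it$points), 0)
  max_pts <- sum(pts[is.na(grp)]) +
    sum(vapply(split(pts[!is.na(grp)], grp[!is.na(grp)]), max, 0))
  if (max_pts > def$range[2]) {
    stop(sprintf(
      "score '%s': attainable maximum %d exceeds declared range max %d",
      name, as.integer(max_pts), as.integer(def$range[2])), call. = FALSE)
  }
  def$max_attainable <- max_pts
  class(def) <- "score_definition"
  def
}

#' Load a score registry from a YAML definitions file
#'
#' Parses and validates a declarative score-definition file. Each entry
#' declares a name, score range, optional predefined cutoff, optional
#' applicability predicate (e.g. RISC applies to HIV-negative children
#' only), optional target population (syndrome the score was designed
#' for), and a list of scored items.
#'
#' @param path Path to the YAML file. Defaults to the bundled definitions
#'   of the ten validated scores (eleven entries: PEDIA early and late are
#'   separate).
#' @return A named list of `score_definition` objects, invisibly locked
#'   (treat as immutable).
#' @examples
#' reg <- load_score_registry()
#' names(reg)
#' @export
load_score_registry <- function(path = system.file("extdata", "scores.yaml",
                                                   package = "pewsval")) {
  if (!file.exists(path)) stop("definitions file not found: ", path,
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$scores) || !length(doc$scores)) {
    stop("definitions file declares no scores", call. = FALSE)
  }
  defs <- lapply(doc$scores, .validate_definition)
  nm <- vapply(defs, function(d) d$name, "")
  if (anyDuplicated(nm)) {
    stop("duplicate score names: ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(defs, nm)
}

# ---- evaluation ------------------------------------------------------------

# Vectorised core: evaluate one definition over a cohort data frame.
# Returns data.frame(total_points, n_items_missing, applicable).
.evaluate_def <- function(def, cohort) {
  n <- nrow(cohort)
  total <- rep(0, n)
  n_missing <- rep(0L, n)
  propagate <- rep(FALSE, n)
  for (item in def$items) {
    hit <- .cond_eval(item$when, cohort)
    miss <- is.na(hit)
    n_missing <- n_missing + miss
    if (identical(item$missing, "propagate")) propagate <- propagate | miss
    hit[miss] <- FALSE            # score_zero policy: absent sign scores 0
    total <- total + item$points * hit
  }
  total[propagate] <- NA_real_
  applicable <- if (is.null(def$applicability)) rep(TRUE, n) else {
    ap <- .cond_eval(def$applicability, cohort)
    ap[is.na(ap)] <- FALSE
    ap
  }
  data.frame(total_points = as.integer(total),
             n_items_missing = n_missing,
             applicable = applicable)
}

#' Evaluate one score for one patient
#'
#' @param def A `score_definition` from [load_score_registry()].
#' @param patient A one-row data frame (or coercible list) with
#'   [patient_fields()] columns; missing fields count as missing values.
#' @return A list with `score_name`, `total_points` (integer, `NA` only if
#'   an item with `missing: propagate` had missing inputs),
#'   `n_items_missing`, and `applicable`.
#' @examples
#' reg <- load_score_registry()
#' kid <- data.frame(age_months = 10, consciousness = "pain",
#'                   prostration = TRUE, deep_breathing = FALSE)
#' evaluate_score(reg$LODS, kid)
#' @export
evaluate_score <- function(def, patient) {
  stopifnot(inherits(def, "score_definition"))
  patient <- as.data.frame(patient)
  if (nrow(patient) != 1) stop("evaluate_score expects a single record",
                               call. = FALSE)
  res <- .evaluate_def(def, patient)
  list(score_name = def$name,
       total_points = res$total_points,
       n_items_missing = res$n_items_missing,
       applicable = res$applicable)
}

#' Score every child in a cohort against every score in a registry
#'
#' @param registry Named list from [load_score_registry()].
#' @param cohort Data frame of patient records, one row per child, with a
#'   `child_id` column.
#' @return Long data frame with one row per (child, score):
#'   `child_id`, `score_name`, `total_points`, `n_items_missing`,
#'   `applicable`. Row count is `nrow(cohort) * length(registry)`.
#' @export
score_cohort <- function(registry, cohort) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  out <- lapply(registry, function(def) {
    res <- .evaluate_def(def, cohort)
    cbind(data.frame(child_id = cohort$child_id,
                     score_name = def$name,
                     stringsAsFactors = FALSE),
          res)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
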