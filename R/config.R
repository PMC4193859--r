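#' Define a prioritization criterion
#'
#' A criterion is one dimension along which stakeholders agree a zoonosis can
#' be judged important, e.g. severity of illness in humans or bioterrorism
#' potential. Each criterion is later represented by exactly one categorical
#' question.
#'
#' @param id Short unique token used in tables and column names.
#' @param label Human-readable name; defaults to `id`.
#' @param description Optional free text.
#' @return An object of class `zp_criterion`.
#' @export
#' @examples
#' criterion("severity", "Severity of illness in humans")
criterion <- function(id, label = id, description = NULL) {
  if (!is_string(id)) stop_validation("criterion id must be a non-empty string")
  if (!is_string(label)) stop_validation("criterion label must be a non-empty string (id: ", id, ")")
  structure(list(id = id, label = label, description = description),
            class = "zp_criterion")
}

#' Define an answer scale for a categorical question
#'
#' Two kinds of scale are supported. A *binomial* scale has exactly two
#' answers; the answer named in `full_score_category` scores 1 and the other
#' scores 0. A *multinomial* scale has 2--5 ordered categories (lowest first);
#' the k-th of m categories scores k/m.
#'
#' @param kind `"binomial"` or `"multinomial"`.
#' @param categories Character vector of category labels, ordinal order,
#'   lowest first.
#' @param full_score_category For binomial scales, the label that receives
#'   score 1. Ignored (must be `NULL`) for multinomial scales.
#' @param strict Promote the >5-category recommendation to an error.
#' @return An object of class `zp_answer_scale`.
#' @export
#' @examples
#' answer_scale("binomial", c("no", "yes"), full_score_category = "yes")
#' answer_scale("multinomial", c("neither", "at least one", "both"))
answer_scale <- function(kind = c("binomial", "multinomial"), categories,
                         full_score_category = NULL, strict = FALSE) {
  if (!is.character(kind) || !kind[1L] %in% c("binomial", "multinomial"))
    stop_validation("unknown answer-scale kind: ", deparse1(kind[1L]),
                    " (expected 'binomial' or 'multinomial')")
  kind <- kind[1L]
  if (!is.character(categories) || length(categories) < 2L || anyNA(categories))
    stop_validation("answer scale needs at least 2 non-missing category labels")
  if (anyDuplicated(categories))
    stop_validation("duplicate category labels in answer scale: ",
                    paste(unique(categories[duplicated(categories)]), collapse = ", "))
  if (kind == "binomial") {
    if (length(categories) != 2L)
      stop_validation("binomial scale must have exactly 2 categories, got ",
                      length(categories))
    if (!is_string(full_score_category) || !full_score_category %in% categories)
      stop_validation("binomial scale needs full_score_category equal to one of: ",
                      paste(categories, collapse = ", "))
  } else {
    if (!is.null(full_score_category))
      stop_validation("full_score_category applies only to binomial scales")
    if (length(categories) > 5L)
      warn_soft(paste0("answer scale has ", length(categories),
                       " categories; no more than 5 ordinal categories are recommended"),
                strict)
  }
  structure(list(kind = kind, categories = categories,
                 full_score_category = full_score_category),
            class = "zp_answer_scale")
}

#' Define the categorical question attached to a criterion
#'
#' @param criterion_id Id of the criterion the question measures.
#' @param text The question as put to the data sources.
#' @param scale An [answer_scale()].
#' @param source_note Free text recording the agreed data source
#'   (e.g. "OIE website").
#' @return An object of class `zp_question`.
#' @export
question <- function(criterion_id, text, scale, source_note = NULL) {
  if (!is_string(criterion_id)) stop_validation("question needs a criterion_id")
  if (!is_string(text)) stop_validation("question text must be a non-empty string (criterion: ",
                                        criterion_id, ")")
  if (!inherits(scale, "zp_answer_scale"))
    stop_validation("scale must be an answer_scale() (criterion: ", criterion_id, ")")
  structure(list(criterion_id = criterion_id, text = text, scale = scale,
                 source_note = source_note),
            class = "zp_question")
}

#' Assemble and validate a prioritization configuration
#'
#' Binds together the agreed criteria, one question per criterion, and the
#' disease list. Hard rules (>= 2 criteria, unique ids and disease names,
#' exactly one question per criterion) always error. Soft recommendations
#' (5--9 criteria, 15--30 diseases) warn, or error when `strict = TRUE`.
#'
#' @param criteria List of [criterion()] objects, in the agreed order.
#' @param questions List of [question()] objects, one per criterion.
#' @param diseases Character vector of unique disease / pathogen / group names.
#' @param metadata Optional named list (purpose, jurisdiction, ...).
#' @param strict Promote recommendation warnings to errors.
#' @return An object of class `zp_config`.
#' @export
prioritization_config <- function(criteria, questions, diseases,
                                  metadata = list(), strict = FALSE) {
  if (inherits(criteria, "zp_criterion")) criteria <- list(criteria)
  if (inherits(questions, "zp_question")) questions <- list(questions)
  problems <- character()
  if (!all(vapply(criteria, inherits, logical(1L), "zp_criterion")))
    problems <- c(problems, "criteria must all be criterion() objects")
  if (!all(vapply(questions, inherits, logical(1L), "zp_question")))
    problems <- c(problems, "questions must all be question() objects")
  fail_if_any(problems, "invalid configuration")

  ids <- vapply(criteria, `[[`, character(1L), "id")
  if (length(ids) < 2L)
    problems <- c(problems, paste0("at least 2 criteria are required, got ", length(ids)))
  if (anyDuplicated(ids))
    problems <- c(problems, paste0("duplicate criterion id: ",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  qids <- vapply(questions, `[[`, character(1L), "criterion_id")
  for (id in setdiff(ids, qids))
    problems <- c(problems, paste0("criterion '", id, "' has no question"))
  for (id in unique(qids[duplicated(qids)]))
    problems <- c(problems, paste0("criterion '", id, "' has more than one question"))
  for (id in setdiff(qids, ids))
    problems <- c(problems, paste0("question refers to unknown criterion '", id, "'"))
  if (!is.character(diseases) || length(diseases) < 1L || anyNA(diseases) ||
      !all(nzchar(diseases)))
    problems <- c(problems, "diseases must be a non-empty character vector")
  else if (anyDuplicated(diseases))
    problems <- c(problems, paste0("duplicate disease name: ",
                                   paste(unique(diseases[duplicated(diseases)]), collapse = ", ")))
  fail_if_any(problems, "invalid configuration")

  n_crit <- length(ids)
  if (n_crit < 5L || n_crit > 9L)
    warn_soft(paste0(n_crit, " criteria configured; 5-9 are recommended for the ",
                     "pairwise ranking step"), strict)
  n_dis <- length(diseases)
  if (n_dis < 15L || n_dis > 30L)
    warn_soft(paste0(n_dis, " diseases configured; a list of about 15-30 is recommended"),
              strict)

  questions <- questions[match(ids, qids)]  # question order follows criteria order
  structure(list(criteria = criteria, questions = questions,
                 diseases = diseases, metadata = metadata),
            class = "zp_config")
}

criteria_ids <- function(config) vapply(config$criteria, `[[`, character(1L), "id")

config_question <- function(config, criterion_id) {
  config$questions[[match(criterion_id, criteria_ids(config))]]
}

#' @export
print.zp_config <- function(x, ...) {
  cat("Prioritization configuration\n")
  cat("  criteria:", length(x$criteria), "--", paste(criteria_ids(x), collapse = ", "), "\n")
  cat("  diseases:", length(x$diseases), "\n")
  if (length(x$metadata)) {
    for (k in names(x$metadata))
      cat("  ", k, ": ", as.character(x$metadata[[k]])[1L], "\n", sep = "")
  }
  invisible(x)
}

#' Build a validated disease-by-question answer table
#'
#' @param answers Data frame with a `disease` column and one column per
#'   criterion id holding category labels.
#' @param config A [prioritization_config()].
#' @param missing_as_lowest Map missing cells to the lowest ordinal category
#'   (with a per-cell message) instead of erroring.
#' @return An object of class `zp_answer_table`: the validated data frame
#'   with diseases in configuration order.
#' @export
answer_table <- function(answers, config, missing_as_lowest = FALSE) {
  stopifnot(is.data.frame(answers), inherits(config, "zp_config"))
  problems <- character()
  if (!"disease" %in% names(answers)) {
    fail_if_any("answer table must have a 'disease' column", "invalid answer table")
  }
  ids <- criteria_ids(config)
  # structural problems and label problems are accumulated together so a bad
  # file is reported in full on the first attempt
  missing_cols <- setdiff(ids, names(answers))
  for (id in missing_cols)
    problems <- c(problems, paste0("missing answer column for criterion '", id, "'"))
  for (d in setdiff(config$diseases, answers$disease))
    problems <- c(problems, paste0("missing answer row for disease '", d, "'"))
  for (d in setdiff(answers$disease, config$diseases))
    problems <- c(problems, paste0("answer row for unconfigured disease '", d, "'"))
  for (d in unique(answers$disease[duplicated(answers$disease)]))
    problems <- c(problems, paste0("duplicate answer row for disease '", d, "'"))

  answers <- answers[, c("disease", setdiff(intersect(ids, names(answers)),
                                            missing_cols)), drop = FALSE]
  for (id in setdiff(ids, missing_cols)) {
    scale <- config_question(config, id)$scale
    col <- as.character(answers[[id]])
    miss <- is.na(col) | !nzchar(trimws(col))
    if (any(miss)) {
      if (isTRUE(missing_as_lowest)) {
        message("filling ", sum(miss), " missing answer(s) for '", id,
                "' with lowest category '", scale$categories[1L], "': ",
                paste(answers$disease[miss], collapse = ", "))
        col[miss] <- scale$categories[1L]
      } else {
        problems <- c(problems, paste0("missing answer for disease '",
                                       answers$disease[miss], "', question '", id, "'"))
      }
    }
    bad <- !miss & !col %in% scale$categories
    if (any(bad))
      problems <- c(problems,
                    paste0("disease '", answers$disease[bad], "', question '", id,
                           "': label '", col[bad], "' not in {",
                           paste(scale$categories, collapse = ", "), "}"))
    answers[[id]] <- col
  }
  fail_if_any(problems, "invalid answer table")
  answers <- answers[match(config$diseases, answers$disease),
                     c("disease", ids), drop = FALSE]
  rownames(answers) <- NULL
  structure(answers, class = c("zp_answer_table", "data.frame"))
}
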