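#' Read a prioritization configuration from YAML
#'
#' The dialect has top-level keys `criteria` (a list of
#' `{id, label, description, question, source, scale: {kind, categories,
#' full_score_category}}`), `diseases` (a list of names) and optional
#' `metadata`.
#'
#' @param path Path to a YAML file.
#' @param strict Promote recommendation warnings (criteria outside 5--9,
#'   diseases outside 15--30, more than 5 categories) to errors.
#' @return A validated [prioritization_config()].
#' @export
load_config <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop_validation("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(raw$criteria) || is.null(raw$diseases))
    stop_validation("configuration must define 'criteria' and 'diseases': ", path)
  crit <- vector("list", length(raw$criteria))
  ques <- vector("list", length(raw$criteria))
  for (i in seq_along(raw$criteria)) {
    entry <- raw$criteria[[i]]
    if (!is.list(entry) || is.null(entry$id))
      stop_validation("criteria entry ", i, " lacks an 'id' field")
    crit[[i]] <- criterion(as.character(entry$id),
                           label = as.character(entry$label %||% entry$id),
                           description = entry$description)
    sc <- entry$scale
    if (!is.list(sc))
      stop_validation("criterion '", entry$id, "' lacks a 'scale' block")
    scale <- answer_scale(as.character(sc$kind %||% ""),
                          as.character(unlist(sc$categories)),
                          full_score_category =
                            if (!is.null(sc$full_score_category))
                              as.character(sc$full_score_category),
                          strict = strict)
    ques[[i]] <- question(as.character(entry$id),
                          text = as.character(entry$question %||% entry$id),
                          scale = scale, source_note = entry$source)
  }
  prioritization_config(crit, ques,
                        diseases = as.character(unlist(raw$diseases)),
                        metadata = raw$metadata %||% list(),
                        strict = strict)
}

#' Write a prioritization configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces an equivalent configuration.
#'
#' @param config A [prioritization_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "zp_config"))
  entries <- lapply(seq_along(config$criteria), function(i) {
    cr <- config$criteria[[i]]
    q <- config$questions[[i]]
    sc <- list(kind = q$scale$kind, categories = as.list(q$scale$categories))
    if (!is.null(q$scale$full_score_category))
      sc$full_score_category <- q$scale$full_score_category
    out <- list(id = cr$id, label = cr$label)
    if (!is.null(cr$description)) out$description <- cr$description
    out$question <- q$text
    if (!is.null(q$source_note)) out$source <- q$source_note
    out$scale <- sc
    out
  })
  doc <- list(criteria = entries, diseases = as.list(config$diseases))
  if (length(config$metadata)) doc$metadata <- config$metadata
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a disease-by-question answer table from CSV
#'
#' Column 1 must be `disease`; the remaining columns carry one category label
#' per criterion id. Every violation in the file is reported at once.
#'
#' @inheritParams answer_table
#' @param path Path to a CSV file.
#' @return A validated [answer_table()].
#' @export
load_answers <- function(path, config, missing_as_lowest = FALSE) {
  if (!file.exists(path)) stop_validation("answers file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (nrow(df) == 0L && length(config$diseases) > 0L) {
    fail_if_any(paste0("missing answer row for disease '", config$diseases, "'"),
                "invalid answer table")
  }
  answer_table(df, config, missing_as_lowest = missing_as_lowest)
}

#' Write an answer table to CSV
#'
#' @param answers A [answer_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_answers <- function(answers, path) {
  stopifnot(inherits(answers, "zp_answer_table"))
  utils::write.csv(as.data.frame(answers), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read per-participant pairwise-comparison judgments
#'
#' Accepts either a directory of `<participant>.csv` files or a single CSV.
#' Each file holds columns `criterion_a, criterion_b, ratio`, one row per
#' compared pair, with `ratio` the judged importance of `criterion_a`
#' relative to `criterion_b` on the Saaty 1--9 scale. A single combined CSV
#' may carry an extra `participant` column. Reciprocals and the diagonal are
#' filled in automatically; every unordered pair must be supplied.
#'
#' @param path Directory of CSVs, or one CSV file.
#' @param config A [prioritization_config()]; judgments are checked against
#'   its criteria.
#' @return A list of `participant_judgment` objects (see
#'   [participant_judgment()]), one per participant, named by participant id.
#' @export
load_judgments <- function(path, config) {
  stopifnot(inherits(config, "zp_config"))
  ids <- criteria_ids(config)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L)
      stop_validation("no judgment CSV files found in directory: ", path)
    judgments <- lapply(files, function(f) {
      df <- utils::read.csv(f, strip.white = TRUE)
      pid <- sub("\\.csv$", "", basename(f))
      participant_judgment(pid, matrix_from_pairs(df, ids))
    })
  } else if (file.exists(path)) {
    df <- utils::read.csv(path, strip.white = TRUE)
    if (!"participant" %in% names(df))
      df$participant <- "participant1"
    judgments <- lapply(split(df, df$participant), function(d) {
      participant_judgment(as.character(d$participant[1L]),
                           matrix_from_pairs(d, ids))
    })
  } else {
    stop_validation("judgments path not found: ", path)
  }
  names(judgments) <- vapply(judgments, `[[`, character(1L), "participant_id")
  n <- length(judgments)
  if (n < 6L || n > 12L)
    warning(n, " participant(s); 6-12 are recommended for balanced group input",
            call. = FALSE)
  judgments
}

#' Write group criterion weights to JSON
#'
#' Emits the ranking, group priorities, sequential weights, and (when
#' supplied) per-participant consistency ratios.
#'
#' @param weights A `zp_criterion_weights` object from [assign_weights()].
#' @param path Output path.
#' @param participant_cr Optional named numeric vector of per-participant
#'   consistency ratios.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path, participant_cr = NULL) {
  stopifnot(inherits(weights, "zp_criterion_weights"))
  doc <- list(ranking = weights$ranking,
              priorities = as.list(weights$priorities),
              weights = as.list(weights$weights),
              group_consistency_ratio = weights$consistency_ratio,
              tie_notes = weights$tie_notes)
  if (!is.null(participant_cr))
    doc$participant_consistency_ratios <- as.list(participant_cr)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read group criterion weights from JSON
#'
#' @param path A file written by [write_weights()].
#' @return A `zp_criterion_weights` object.
#' @export
load_weights <- function(path) {
  if (!file.exists(path)) stop_validation("weights file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- unlist(doc$weights)
  structure(list(ranking = as.character(doc$ranking),
                 priorities = unlist(doc$priorities),
                 weights = stats::setNames(as.numeric(w), names(w)),
                 consistency_ratio = doc$group_consistency_ratio %||% NA_real_,
                 tie_notes = as.character(doc$tie_notes %||% character())),
            class = "zp_criterion_weights")
}

#' Write the ranked disease list and score traces
#'
#' CSV columns are fixed: `rank, disease, total_score, normalized_score`,
#' then one `q_<criterion_id>` column per criterion in descending-weight
#' order. Floating-point cells are rounded to 6 decimals in CSV and Markdown;
#' JSON keeps full precision. Output is byte-stable for identical inputs.
#'
#' @param ranked A `zp_ranked_list` from [rank_diseases()].
#' @param traces List of `zp_score_trace` objects, one per disease.
#' @param path Output path.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(ranked, traces, path,
                         format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(ranked, "zp_ranked_list"))
  df <- report_frame(ranked, traces)
  if (format == "csv") {
    out <- df
    num <- vapply(out, is.numeric, logical(1L))
    out[num] <- lapply(out[num], round, 6L)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else if (format == "json") {
    doc <- list(t_max = ranked$t_max,
                entries = df,
                traces = lapply(traces[match(df$disease,
                                             vapply(traces, `[[`, character(1L), "disease"))],
                                unclass))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  } else {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x) formatC(round(x, 6L), format = "g", digits = 7))
    lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
               apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
    writeLines(lines, path)
  }
  invisible(path)
}

# Ranked entries joined with per-question weighted scores, one q_<id> column
# per criterion in trace (descending-weight) order.
report_frame <- function(ranked, traces) {
  trace_names <- vapply(traces, `[[`, character(1L), "disease")
  if (!setequal(trace_names, ranked$entries$disease))
    stop_validation("ranked list and traces cover different diseases")
  qcols <- traces[[1L]]$scores$criterion_id
  df <- ranked$entries
  for (id in qcols) {
    df[[paste0("q_", id)]] <- vapply(df$disease, function(d) {
      tr <- traces[[match(d, trace_names)]]
      tr$scores$weighted_score[match(id, tr$scores$criterion_id)]
    }, numeric(1L))
  }
  df
}

#' Read a ranked report back from CSV or JSON
#'
#' Used for round-trip checks and by the `report` command to re-render a
#' saved run in another format.
#'
#' @param path A report written by [write_report()].
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return A data frame of ranked entries.
#' @export
load_report <- function(path, format = NULL) {
  if (!file.exists(path)) stop_validation("report file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    as.data.frame(doc$entries)
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
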