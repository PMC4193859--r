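#' Score a single categorical answer
#'
#' Binomial questions score 1 for the designated full-score answer and 0 for
#' the other. Multinomial questions score k/m, where k is the answer's
#' 1-based ordinal position and m the number of categories, so the lowest
#' category of a 3-category scale scores 1/3 and the highest scores 1. The
#' binomial 0/1 rule is deliberately kept as a special case rather than
#' folded into k/m (which would give 1/2 and 1).
#'
#' @param question A [question()].
#' @param label A category label from the question's scale.
#' @return An object of class `zp_answer_score` with fields `question_id`,
#'   `label`, `ordinal_position` (k), `n_categories` (m), `score` (in
#'   \[0, 1\]).
#' @export
#' @examples
#' q <- question("collaborate", "Lab capacity?",
#'               answer_scale("multinomial", c("neither", "at least one", "both")))
#' answer_score(q, "both")$score  # 1
answer_score <- function(question, label) {
  stopifnot(inherits(question, "zp_question"))
  scale <- question$scale
  k <- match(label, scale$categories)
  if (is.na(k))
    stop_validation("label '", label, "' not in scale of question '",
                    question$criterion_id, "' {",
                    paste(scale$categories, collapse = ", "), "}")
  m <- length(scale$categories)
  s <- if (scale$kind == "binomial") {
    if (identical(label, scale$full_score_category)) 1 else 0
  } else {
    k / m
  }
  structure(list(question_id = question$criterion_id, label = label,
                 ordinal_position = k, n_categories = m, score = s),
            class = "zp_answer_score")
}

#' Multiply an answer score by its criterion weight
#'
#' @param score A [answer_score()].
#' @param weight The criterion's weight (>= 1 for sequential weights; any
#'   positive value is accepted so raw AHP priorities can be used instead).
#' @return The weighted score q = w * s.
#' @export
weighted_question_score <- function(score, weight) {
  stopifnot(inherits(score, "zp_answer_score"))
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0)
    stop_validation("weight must be a positive scalar")
  weight * score$score
}

#' Score one disease through the weighted decision tree
#'
#' The disease's categorical answers are scored question by question, each
#' multiplied by its criterion's weight, and summed. The trace lists
#' criteria in descending-weight order — the order of the decision-tree
#' nodes, whose first node is the highest-ranked criterion. Because every
#' disease traverses every node, node order affects only the presentation of
#' the trace, never the total.
#'
#' @param disease A disease name present in the answer table.
#' @param answers An [answer_table()].
#' @param weights A `zp_criterion_weights` from [assign_weights()], or a
#'   named positive numeric vector of weights.
#' @param config The [prioritization_config()].
#' @return An object of class `zp_score_trace`: `disease`, `scores` (a data
#'   frame with columns criterion_id, weight, label, raw_score,
#'   weighted_score, in tree order), `total`.
#' @export
score_disease <- function(disease, answers, weights, config) {
  stopifnot(inherits(answers, "zp_answer_table"), inherits(config, "zp_config"))
  w <- if (inherits(weights, "zp_criterion_weights")) weights$weights else weights
  ids <- criteria_ids(config)
  if (is.null(names(w)) || !setequal(names(w), ids))
    stop_validation("weights must be named by the configured criterion ids")
  row <- match(disease, answers$disease)
  if (is.na(row))
    stop_validation("disease '", disease, "' not present in the answer table")
  tree_order <- ids[order(-w[ids], seq_along(ids))]
  rows <- lapply(tree_order, function(id) {
    label <- answers[[id]][row]
    if (is.na(label) || !nzchar(label))
      stop_validation("missing answer for disease '", disease, "', question '", id, "'")
    sc <- answer_score(config_question(config, id), label)
    data.frame(criterion_id = id, weight = unname(w[[id]]), label = label,
               raw_score = sc$score,
               weighted_score = weighted_question_score(sc, w[[id]]),
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  structure(list(disease = disease, scores = scores,
                 total = sum(scores$weighted_score)),
            class = "zp_score_trace")
}

#' @export
print.zp_score_trace <- function(x, ...) {
  cat("Score trace:", x$disease, "\n")
  print(x$scores, row.names = FALSE)
  cat("  total:", format(x$total), "\n")
  invisible(x)
}

#' Score every configured disease
#'
#' @inheritParams score_disease
#' @return Named list of `zp_score_trace` objects in configuration order.
#' @export
score_all <- function(answers, weights, config) {
  traces <- lapply(config$diseases, score_disease,
                   answers = answers, weights = weights, config = config)
  stats::setNames(traces, config$diseases)
}

#' Rank diseases by total weighted score
#'
#' Totals are sorted in descending order and normalized against the maximum
#' observed total (the top disease scores 1), or optionally against the
#' maximum attainable total — the sum of the weights. Tied totals share a
#' rank (competition ranking: ranks 1, 1, 3, ...) and fall back on the input
#' order, which [score_all()] sets to the configured disease order, so the
#' result is deterministic.
#'
#' @param traces List of `zp_score_trace` objects.
#' @param normalize `"max-observed"` (default) or `"max-possible"`.
#' @param max_possible The denominator for `"max-possible"`; defaults to the
#'   per-trace sum of weights (they are constant across traces).
#' @return An object of class `zp_ranked_list`: `entries` (data frame rank,
#'   disease, total_score, normalized_score), `t_max`, `normalize`.
#' @export
rank_diseases <- function(traces, normalize = c("max-observed", "max-possible"),
                          max_possible = NULL) {
  normalize <- match.arg(normalize)
  if (length(traces) < 1L) stop_validation("at least one score trace is required")
  if (inherits(traces, "zp_score_trace")) traces <- list(traces)
  totals <- vapply(traces, `[[`, numeric(1L), "total")
  diseases <- vapply(traces, `[[`, character(1L), "disease")
  t_max <- max(totals)
  denom <- if (normalize == "max-observed") t_max else
    max_possible %||% sum(traces[[1L]]$scores$weight)
  if (denom <= 0) {
    warning("all disease totals are zero; normalized scores set to 0", call. = FALSE)
    norm <- rep(0, length(totals))
  } else {
    norm <- totals / denom
  }
  ord <- order(-totals, seq_along(totals))
  sorted_t <- totals[ord]
  # competition ranking: rank = 1 + count of strictly greater totals
  rk <- vapply(sorted_t, function(t) 1L + sum(sorted_t > t), integer(1L))
  entries <- data.frame(rank = rk, disease = diseases[ord],
                        total_score = sorted_t, normalized_score = norm[ord],
                        stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  structure(list(entries = entries, t_max = t_max, normalize = normalize),
            class = "zp_ranked_list")
}

#' @export
print.zp_ranked_list <- function(x, ...) {
  cat("Ranked disease list (normalization: ", x$normalize, ")\n", sep = "")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out criterion sensitivity scan
#'
#' For each criterion in turn the scan drops that criterion, re-assigns
#' sequential weights n-1, ..., 1 over the remaining criteria in their
#' unchanged relative order, re-scores every disease, and counts how many
#' diseases change rank relative to the full ranking. A criterion whose
#' removal reorders many diseases is one the final list is sensitive to.
#'
#' @inheritParams score_disease
#' @return An object of class `zp_sensitivity`: `summary` (data frame
#'   criterion_id, n_rank_changes), `rankings` (named list of
#'   `zp_ranked_list` objects, one per left-out criterion), `baseline`.
#' @export
sensitivity_scan <- function(answers, weights, config) {
  stopifnot(inherits(weights, "zp_criterion_weights"))
  ids <- criteria_ids(config)
  if (length(ids) < 2L)
    stop_validation("sensitivity scan needs at least 2 criteria")
  baseline <- rank_diseases(score_all(answers, weights, config))
  base_rank <- stats::setNames(baseline$entries$rank, baseline$entries$disease)
  rankings <- list()
  changes <- integer(length(ids))
  for (k in seq_along(ids)) {
    drop_id <- ids[k]
    keep <- setdiff(weights$ranking, drop_id)
    sub_w <- stats::setNames(seq(length(keep), 1L), keep)
    sub_config <- config
    sub_config$criteria <- config$criteria[ids != drop_id]
    sub_config$questions <- config$questions[ids != drop_id]
    sub_ranked <- rank_diseases(score_all(answers, sub_w, sub_config))
    sub_rank <- stats::setNames(sub_ranked$entries$rank, sub_ranked$entries$disease)
    changes[k] <- sum(sub_rank[names(base_rank)] != base_rank)
    rankings[[drop_id]] <- sub_ranked
  }
  structure(list(summary = data.frame(criterion_id = ids,
                                      n_rank_changes = changes,
                                      stringsAsFactors = FALSE),
                 rankings = rankings, baseline = baseline),
            class = "zp_sensitivity")
}

#' @export
print.zp_sensitivity <- function(x, ...) {
  cat("Criterion sensitivity (leave-one-out rank changes)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the full prioritization pipeline in memory
#'
#' Convenience wrapper: aggregate the participants' pairwise judgments into
#' group priorities, assign sequential weights, score every disease, and
#' rank. Equivalent to chaining [aggregate_group()], [assign_weights()],
#' [score_all()] and [rank_diseases()].
#'
#' @param config A [prioritization_config()].
#' @param judgments List of [participant_judgment()] objects.
#' @param answers An [answer_table()].
#' @param aggregation,derivation Passed to [aggregate_group()].
#' @param weight_scheme `"sequential"` (integer weights n..1, the default)
#'   or `"raw-priorities"` (the continuous group priorities themselves, for
#'   sensitivity comparisons).
#' @param normalize Passed to [rank_diseases()].
#' @return List with elements `weights`, `traces`, `ranked`,
#'   `participant_cr` (per-participant consistency ratios).
#' @export
prioritize <- function(config, judgments, answers,
                       aggregation = c("aij", "aip"),
                       derivation = c("eigenvector", "geometric_mean"),
                       weight_scheme = c("sequential", "raw-priorities"),
                       normalize = c("max-observed", "max-possible")) {
  weight_scheme <- match.arg(weight_scheme)
  group <- aggregate_group(judgments, method = match.arg(aggregation),
                           derivation = match.arg(derivation))
  weights <- assign_weights(group)
  if (!is.na(weights$consistency_ratio) && weights$consistency_ratio > 0.1)
    warning("group consistency ratio ", signif(weights$consistency_ratio, 3L),
            " exceeds the conventional 0.1 threshold; judgments may be incoherent",
            call. = FALSE)
  score_w <- if (weight_scheme == "sequential") weights else group$priorities
  traces <- score_all(answers, score_w, config)
  ranked <- rank_diseases(traces, normalize = match.arg(normalize))
  participant_cr <- vapply(judgments, function(j) consistency_ratio(j$matrix),
                           numeric(1L))
  names(participant_cr) <- vapply(judgments, `[[`, character(1L), "participant_id")
  list(weights = weights, traces = traces, ranked = ranked,
       participant_cr = participant_cr)
}
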