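#' Construct a pairwise-comparison matrix
#'
#' A positive reciprocal matrix A over the configured criteria, with
#' `A[i, j]` the judged importance of criterion i relative to criterion j on
#' Saaty's ratio scale. The diagonal is forced to 1 and the lower triangle is
#' rebuilt as the exact reciprocal of the upper triangle, so reciprocity
#' holds by construction; supplied values that contradict reciprocity beyond
#' rounding error are rejected.
#'
#' @param values Square numeric matrix of positive ratios.
#' @param criteria_ids Character vector naming the rows/columns, in
#'   configuration order.
#' @return An object of class `zp_pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, criteria_ids) {
  values <- as.matrix(values)
  n <- length(criteria_ids)
  if (!is.numeric(values) || nrow(values) != n || ncol(values) != n)
    stop_validation("pairwise matrix must be ", n, "x", n, " numeric")
  if (anyNA(values) || any(values <= 0))
    stop_validation("pairwise matrix entries must be strictly positive")
  if (any(abs(diag(values) - 1) > 1e-9))
    stop_validation("pairwise matrix diagonal must be 1")
  if (n > 1L) {
    rel <- abs(values * t(values) - 1)
    if (any(rel > 1e-6))
      stop_validation("pairwise matrix violates reciprocity A[j,i] = 1/A[i,j]")
    values[lower.tri(values)] <- t(1 / values)[lower.tri(values)]
    diag(values) <- 1
  }
  dimnames(values) <- list(criteria_ids, criteria_ids)
  structure(list(criteria_ids = criteria_ids, values = values),
            class = "zp_pairwise_matrix")
}

#' Build a pairwise matrix from long-format pair judgments
#'
#' @param pairs Data frame with columns `criterion_a`, `criterion_b`,
#'   `ratio`: the importance of a relative to b. Each unordered pair must be
#'   judged exactly once (a consistent reverse entry is tolerated); every
#'   pair must be present. Ratios outside Saaty's \[1/9, 9\] range warn;
#'   non-positive ratios error.
#' @param criteria_ids Criteria in configuration order.
#' @return A [pairwise_matrix()].
#' @export
#' @examples
#' matrix_from_pairs(
#'   data.frame(criterion_a = "c1", criterion_b = "c2", ratio = 3),
#'   c("c1", "c2"))
matrix_from_pairs <- function(pairs, criteria_ids) {
  stopifnot(is.data.frame(pairs))
  need <- c("criterion_a", "criterion_b", "ratio")
  if (!all(need %in% names(pairs)))
    stop_validation("judgment table needs columns: ", paste(need, collapse = ", "))
  n <- length(criteria_ids)
  A <- diag(n)
  dimnames(A) <- list(criteria_ids, criteria_ids)
  seen <- matrix(FALSE, n, n)
  problems <- character()
  for (r in seq_len(nrow(pairs))) {
    a <- as.character(pairs$criterion_a[r]); b <- as.character(pairs$criterion_b[r])
    v <- as.numeric(pairs$ratio[r])
    i <- match(a, criteria_ids); j <- match(b, criteria_ids)
    if (is.na(i)) { problems <- c(problems, paste0("unknown criterion '", a, "'")); next }
    if (is.na(j)) { problems <- c(problems, paste0("unknown criterion '", b, "'")); next }
    if (i == j) {
      if (!is.na(v) && abs(v - 1) > 1e-9)
        problems <- c(problems, paste0("self-comparison of '", a, "' must be 1"))
      next
    }
    if (is.na(v) || v <= 0) {
      problems <- c(problems, paste0("ratio for (", a, ", ", b, ") must be positive, got ",
                                     pairs$ratio[r]))
      next
    }
    if (v < 1 / 9 - 1e-9 || v > 9 + 1e-9)
      warning("ratio ", signif(v, 4L), " for (", a, ", ", b,
              ") lies outside the Saaty [1/9, 9] scale", call. = FALSE)
    if (seen[i, j]) {
      if (abs(A[i, j] - v) > 1e-9 * max(1, v))
        problems <- c(problems, paste0("conflicting duplicate judgment for (", a, ", ", b,
                                       "): ", signif(A[i, j], 6L), " vs ", signif(v, 6L)))
      next
    }
    A[i, j] <- v; A[j, i] <- 1 / v
    seen[i, j] <- TRUE; seen[j, i] <- TRUE
  }
  if (n > 1L) {
    up <- which(upper.tri(seen) & !seen, arr.ind = TRUE)
    if (nrow(up) > 0L)
      problems <- c(problems,
                    paste0("missing judgment for pair (", criteria_ids[up[, 1L]],
                           ", ", criteria_ids[up[, 2L]], ")"))
  }
  fail_if_any(problems, "invalid pairwise judgments")
  pairwise_matrix(A, criteria_ids)
}

#' Attach a participant id to a pairwise matrix
#'
#' @param participant_id Token identifying the group member.
#' @param matrix A [pairwise_matrix()].
#' @return An object of class `zp_participant_judgment`.
#' @export
participant_judgment <- function(participant_id, matrix) {
  if (!is_string(participant_id)) stop_validation("participant_id must be a non-empty string")
  if (!inherits(matrix, "zp_pairwise_matrix"))
    stop_validation("matrix must be a pairwise_matrix()")
  structure(list(participant_id = participant_id, matrix = matrix),
            class = "zp_participant_judgment")
}

# Saaty random-index table: expected consistency index of random reciprocal
# matrices with entries drawn uniformly from the 17-value scale
# {1/9..1/2, 1, 2..9}. Values for n = 3..15 are the large-sample estimates of
# Alonso & Lamata (2006), which this package's Monte-Carlo tests reproduce;
# RI is 0 for n <= 2 because 1x1 and 2x2 reciprocal matrices are always
# consistent.
RANDOM_INDEX <- c(0, 0, 0.5245, 0.8815, 1.1086, 1.2479, 1.3417, 1.4056,
                  1.4499, 1.4854, 1.5140, 1.5365, 1.5551, 1.5713, 1.5838)

#' Random-index constant for a matrix order
#'
#' @param n Matrix order (number of criteria), 1--15.
#' @return The packaged RI(n) value.
#' @export
ahp_random_index <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n != round(n))
    stop_validation("n must be a positive integer")
  if (n > length(RANDOM_INDEX))
    stop_validation("random-index table covers n <= ", length(RANDOM_INDEX),
                    "; got n = ", n)
  RANDOM_INDEX[n]
}

#' Derive criterion priorities from a pairwise matrix
#'
#' The default method is Saaty's principal right eigenvector, computed by
#' power iteration (L1 change tolerance 1e-12, at most 10,000 iterations);
#' positivity of the matrix guarantees a dominant positive eigenpair. The
#' alternative `geometric_mean` method normalizes the row geometric means;
#' the two agree exactly on consistent matrices. Both populate the principal
#' eigenvalue lambda_max = mean_i (A p)_i / p_i, the consistency index
#' CI = (lambda_max - n) / (n - 1), and the consistency ratio CR = CI / RI(n)
#' (0 whenever RI(n) = 0, i.e. n <= 2).
#'
#' @param matrix A [pairwise_matrix()].
#' @param method `"eigenvector"` (default) or `"geometric_mean"`.
#' @param tol Convergence tolerance on the L1 change between successive
#'   normalized iterates.
#' @param max_iter Iteration cap for the power method.
#' @return An object of class `zp_priority_vector` with fields `priorities`
#'   (named, sums to 1), `lambda_max`, `consistency_index`,
#'   `consistency_ratio`, `method`, `iterations`.
#' @export
priority_vector <- function(matrix, method = c("eigenvector", "geometric_mean"),
                            tol = 1e-12, max_iter = 10000L) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "zp_pairwise_matrix"))
  A <- matrix$values
  n <- nrow(A)
  iterations <- 0L
  if (n == 1L) {
    p <- 1
  } else if (method == "eigenvector") {
    p <- rep(1 / n, n)
    repeat {
      iterations <- iterations + 1L
      p_new <- as.vector(A %*% p)
      p_new <- p_new / sum(p_new)
      delta <- sum(abs(p_new - p))
      p <- p_new
      if (delta < tol) break
      if (iterations >= max_iter)
        stop("power iteration did not converge after ", max_iter,
             " iterations (residual ", format(delta, digits = 3L), ")")
    }
  } else {
    g <- apply(A, 1L, function(row) exp(mean(log(row))))
    p <- g / sum(g)
  }
  lambda_max <- if (n == 1L) 1 else mean(as.vector(A %*% p) / p)
  ci <- if (n == 1L) 0 else (lambda_max - n) / (n - 1)
  if (ci < -1e-9)
    stop("consistency index is negative beyond tolerance (", format(ci), ")")
  ri <- if (n <= length(RANDOM_INDEX)) RANDOM_INDEX[n] else NA_real_
  cr <- if (is.na(ri)) NA_real_ else if (ri == 0) 0 else ci / ri
  names(p) <- matrix$criteria_ids
  structure(list(priorities = p, lambda_max = lambda_max,
                 consistency_index = ci, consistency_ratio = cr,
                 method = method, iterations = iterations),
            class = "zp_priority_vector")
}

#' Consistency ratio of a pairwise matrix
#'
#' CR = CI / RI(n) with CI = (lambda_max - n)/(n - 1) and RI the packaged
#' random-index constant; defined as 0 for n <= 2. CR above 0.1 is the
#' conventional signal of incoherent judgments; this package warns on it
#' downstream but never rejects a matrix for inconsistency.
#'
#' @param matrix A [pairwise_matrix()].
#' @return The consistency ratio (non-negative scalar).
#' @export
consistency_ratio <- function(matrix) {
  priority_vector(matrix, method = "eigenvector")$consistency_ratio
}

#' Aggregate participants into a group priority vector
#'
#' Two group-aggregation conventions are offered. `"aij"` (aggregation of
#' individual judgments, the default) takes the element-wise geometric mean
#' of the participants' matrices — which is again a positive reciprocal
#' matrix — and derives priorities from it. `"aip"` (aggregation of
#' individual priorities) averages the participants' individual priority
#' vectors arithmetically and renormalizes; no group matrix exists in that
#' case, so `lambda_max`/CI/CR are reported as `NA`.
#'
#' @param judgments List of [participant_judgment()] objects over identical
#'   criteria in identical order.
#' @param method `"aij"` or `"aip"`.
#' @param derivation Passed to [priority_vector()].
#' @return A `zp_priority_vector`.
#' @export
aggregate_group <- function(judgments, method = c("aij", "aip"),
                            derivation = c("eigenvector", "geometric_mean")) {
  method <- match.arg(method)
  derivation <- match.arg(derivation)
  if (length(judgments) < 1L) stop_validation("at least one participant judgment is required")
  if (inherits(judgments, "zp_participant_judgment")) judgments <- list(judgments)
  if (!all(vapply(judgments, inherits, logical(1L), "zp_participant_judgment")))
    stop_validation("judgments must be participant_judgment() objects")
  ids <- judgments[[1L]]$matrix$criteria_ids
  for (j in judgments)
    if (!identical(j$matrix$criteria_ids, ids))
      stop_validation("participant '", j$participant_id,
                      "' judged a different criteria set/order")
  if (method == "aij") {
    logs <- lapply(judgments, function(j) log(j$matrix$values))
    G <- exp(Reduce(`+`, logs) / length(logs))
    diag(G) <- 1
    priority_vector(pairwise_matrix(G, ids), method = derivation)
  } else {
    ps <- vapply(judgments,
                 function(j) priority_vector(j$matrix, method = derivation)$priorities,
                 numeric(length(ids)))
    p <- rowMeans(as.matrix(ps))
    p <- p / sum(p)
    names(p) <- ids
    structure(list(priorities = p, lambda_max = NA_real_,
                   consistency_index = NA_real_, consistency_ratio = NA_real_,
                   method = paste0("aip+", derivation), iterations = 0L),
              class = "zp_priority_vector")
  }
}

#' Assign sequential integer weights from group priorities
#'
#' Criteria are ordered by descending group priority and the integers
#' n, n-1, ..., 1 are assigned in that order (the top criterion gets n).
#' Priorities tied within 1e-9 keep the supplied configuration order; ties
#' are recorded in `tie_notes` and warned about, because the sequential rule
#' forces an arbitrary strict order between them.
#'
#' @param group A `zp_priority_vector` (e.g. from [aggregate_group()]).
#' @param criteria_ids Criteria in configuration order; defaults to the
#'   names of the priorities.
#' @return An object of class `zp_criterion_weights` with fields `ranking`
#'   (ids, best to worst), `priorities`, `weights` (named integers summing
#'   to n(n+1)/2), `consistency_ratio`, `tie_notes`.
#' @export
assign_weights <- function(group, criteria_ids = names(group$priorities)) {
  stopifnot(inherits(group, "zp_priority_vector"))
  p <- group$priorities[criteria_ids]
  if (anyNA(p)) stop_validation("criteria_ids do not match the priority vector")
  n <- length(p)
  ord <- order(-p, seq_len(n))  # ties keep configuration order
  ranking <- criteria_ids[ord]
  weights <- stats::setNames(integer(n), criteria_ids)
  weights[ranking] <- seq(n, 1L)
  tie_notes <- character()
  sorted_p <- p[ord]
  tied <- which(abs(diff(sorted_p)) < 1e-9)
  for (k in tied)
    tie_notes <- c(tie_notes,
                   paste0("priorities of '", ranking[k], "' and '", ranking[k + 1L],
                          "' are tied; configuration order breaks the tie"))
  if (length(tie_notes))
    warning(paste(tie_notes, collapse = "; "), call. = FALSE)
  structure(list(ranking = ranking, priorities = p, weights = weights,
                 consistency_ratio = group$consistency_ratio,
                 tie_notes = tie_notes),
            class = "zp_criterion_weights")
}

#' @export
print.zp_criterion_weights <- function(x, ...) {
  cat("Criterion weights (sequential ", length(x$ranking), "..1)\n", sep = "")
  for (id in x$ranking)
    cat(sprintf("  %-20s weight %2d   priority %.4f\n", id, x$weights[[id]],
                x$priorities[[id]]))
  if (!is.na(x$consistency_ratio))
    cat(sprintf("  group consistency ratio: %.4f\n", x$consistency_ratio))
  invisible(x)
}
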