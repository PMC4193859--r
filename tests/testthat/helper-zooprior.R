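# Shared builders for the test suite. Small configurations deliberately sit
# below the 5-criterion recommendation, so constructors are wrapped in
# suppressWarnings; hard validation still applies.

quiet_config <- function(criteria, questions, diseases, ...) {
  suppressWarnings(prioritization_config(criteria, questions, diseases, ...))
}

binomial_scale <- function() answer_scale("binomial", c("no", "yes"),
                                          full_score_category = "yes")

# n_multi criteria get a 3-category ordinal scale, the rest binomial no/yes.
toy_config <- function(n_criteria = 3L, n_diseases = 3L, n_multi = 1L) {
  ids <- sprintf("c%d", seq_len(n_criteria))
  crit <- lapply(ids, criterion)
  ques <- lapply(seq_along(ids), function(i) {
    scale <- if (i <= n_multi)
      answer_scale("multinomial", c("low", "medium", "high"))
    else binomial_scale()
    question(ids[i], paste0("Question ", i, "?"), scale)
  })
  quiet_config(crit, ques, sprintf("d%d", seq_len(n_diseases)))
}

consistent_matrix <- function(v, ids = sprintf("c%d", seq_along(v))) {
  pairwise_matrix(outer(v, v, "/"), ids)
}

random_saaty_matrix <- function(n, ids = sprintf("c%d", seq_len(n))) {
  scale <- c(1 / (9:2), 1:9)
  A <- diag(n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    v <- sample(scale, 1L)
    A[i, j] <- v
    A[j, i] <- 1 / v
  }
  pairwise_matrix(A, ids)
}

# Independent full-spectrum eigendecomposition oracle for priorities.
eigen_oracle <- function(matrix) {
  e <- eigen(matrix$values)
  k <- which.max(Re(e$values))
  p <- Re(e$vectors[, k])
  p <- p / sum(p)
  stats::setNames(p, matrix$criteria_ids)
}

# Random answer table for a config under the current RNG state.
random_answers <- function(config) {
  df <- data.frame(disease = config$diseases, stringsAsFactors = FALSE)
  for (id in vapply(config$criteria, `[[`, character(1L), "id")) {
    cats <- config$questions[[match(id, vapply(config$criteria, `[[`,
                                               character(1L), "id"))]]$scale$categories
    df[[id]] <- sample(cats, length(config$diseases), replace = TRUE)
  }
  answer_table(df, config)
}
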