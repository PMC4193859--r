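test_that("binomial and multinomial answer scores follow the scoring rules", {
  qb <- question("severity", "CFR > 10%?", binomial_scale())
  expect_identical(answer_score(qb, "yes")$score, 1)
  expect_identical(answer_score(qb, "no")$score, 0)
  qm <- question("collaborate", "Lab capacity?",
                 answer_scale("multinomial", c("neither", "at least one", "both")))
  expect_equal(answer_score(qm, "neither")$score, 1 / 3)
  expect_equal(answer_score(qm, "at least one")$score, 2 / 3)
  expect_equal(answer_score(qm, "both")$score, 1)
  q4 <- question("cfr", "Animal CFR?",
                 answer_scale("multinomial", c("0-1%", "10-50%", ">50-75%", ">75%")))
  expect_equal(answer_score(q4, "10-50%")$score, 0.5)  # position 2 of 4
  expect_error(answer_score(qm, "maybe"), "not in scale")
  # weighted scores are plain products
  expect_identical(weighted_question_score(answer_score(qb, "yes"), 5), 5)
  expect_identical(weighted_question_score(answer_score(qm, "both"), 2), 2)
  expect_equal(weighted_question_score(answer_score(q4, "10-50%"), 3), 1.5)
  expect_error(weighted_question_score(answer_score(qb, "yes"), -1), "positive")
})

test_that("disease traces visit criteria in tree order and sum the weighted scores", {
  fx <- fixture_country_x()
  w <- assign_weights(aggregate_group(fx$judgments))
  tr <- score_disease("Rabies", fx$answers, w, fx$config)
  expect_identical(tr$scores$criterion_id,
                   c("severity", "bioterror", "economic", "collaborate", "epidemic"))
  expect_identical(tr$scores$weighted_score, c(5, 0, 0, 2, 1))
  expect_identical(tr$total, 8)
  expect_equal(tr$total, sum(tr$scores$weighted_score), tolerance = 1e-12)
  expect_error(score_disease("Unicorn Flu", fx$answers, w, fx$config),
               "not present")
})

test_that("extreme answer vectors hit the score bounds", {
  cfg <- toy_config(5L, 2L, n_multi = 0L)  # all binomial
  w <- stats::setNames(5:1, sprintf("c%d", 1:5))
  low <- answer_table(data.frame(disease = c("d1", "d2"),
                                 c1 = "no", c2 = "no", c3 = "no",
                                 c4 = "no", c5 = "no"), cfg)
  expect_identical(score_disease("d1", low, w, cfg)$total, 0)
  high <- answer_table(data.frame(disease = c("d1", "d2"),
                                  c1 = "yes", c2 = "yes", c3 = "yes",
                                  c4 = "yes", c5 = "yes"), cfg)
  expect_identical(score_disease("d1", high, w, cfg)$total, 15)  # sum of weights
})

test_that("ranking normalizes against the maximum and applies competition ranks", {
  mk <- function(disease, total) structure(
    list(disease = disease,
         scores = data.frame(criterion_id = "c1", weight = 8, label = "x",
                             raw_score = total / 8, weighted_score = total),
         total = total), class = "zp_score_trace")
  r <- rank_diseases(list(mk("a", 8), mk("b", 4), mk("c", 2)))
  expect_equal(r$entries$normalized_score, c(1, 0.5, 0.25))
  expect_identical(r$entries$rank, c(1L, 2L, 3L))
  # single disease
  r1 <- rank_diseases(list(mk("solo", 3)))
  expect_identical(r1$entries$rank, 1L)
  expect_identical(r1$entries$normalized_score, 1)
  # ties share a rank; the next rank skips
  rt <- rank_diseases(list(mk("a", 8), mk("b", 8), mk("c", 3)))
  expect_identical(rt$entries$rank, c(1L, 1L, 3L))
  expect_identical(rt$entries$disease[1:2], c("a", "b"))  # input order breaks tie
  # all-zero totals: normalized scores defined as 0, with a warning
  expect_warning(rz <- rank_diseases(list(mk("a", 0), mk("b", 0))), "zero")
  expect_identical(rz$entries$normalized_score, c(0, 0))
  # max-possible normalization divides by the weight sum instead
  rmp <- rank_diseases(list(mk("a", 8), mk("b", 4)), normalize = "max-possible")
  expect_equal(rmp$entries$normalized_score, c(1, 0.5))  # weight sum is 8 here
})

test_that("renormalizing an already normalized list changes nothing", {
  fx <- fixture_country_x()
  res <- prioritize(fx$config, fx$judgments, fx$answers)
  n1 <- res$ranked$entries$normalized_score
  expect_equal(n1 / max(n1), n1, tolerance = 1e-15)
  expect_equal(max(n1), 1)
})

test_that("the decision tree is order-invariant: totals do not depend on node order", {
  # scoring with criteria visited in any order must give the same totals
  set.seed(501)
  cfg <- toy_config(4L, 6L, n_multi = 2L)
  ans <- random_answers(cfg)
  w <- stats::setNames(c(4, 3, 2, 1), sprintf("c%d", 1:4))
  totals <- vapply(cfg$diseases, function(d)
    score_disease(d, ans, w, cfg)$total, numeric(1))
  perm_cfg <- cfg
  perm <- c(3L, 1L, 4L, 2L)
  perm_cfg$criteria <- cfg$criteria[perm]
  perm_cfg$questions <- cfg$questions[perm]
  totals_perm <- vapply(perm_cfg$diseases, function(d)
    score_disease(d, ans, w, perm_cfg)$total, numeric(1))
  expect_equal(totals_perm, totals, tolerance = 1e-12)
})

test_that("leave-one-out sensitivity matches a brute-force re-scoring oracle", {
  set.seed(502)
  cfg <- toy_config(5L, 10L, n_multi = 2L)
  ans <- random_answers(cfg)
  jd <- lapply(1:4, function(k)
    participant_judgment(paste0("p", k), random_saaty_matrix(5)))
  w <- suppressWarnings(assign_weights(aggregate_group(jd)))
  scan <- sensitivity_scan(ans, w, cfg)
  # oracle: independently rebuild the reduced problem for each criterion
  ids <- sprintf("c%d", 1:5)
  base <- rank_diseases(score_all(ans, w, cfg))
  base_rank <- stats::setNames(base$entries$rank, base$entries$disease)
  for (k in seq_along(ids)) {
    keep <- setdiff(w$ranking, ids[k])
    oracle_w <- stats::setNames(seq(length(keep), 1L), keep)
    oracle_cfg <- toy_config(5L, 10L, n_multi = 2L)
    oracle_cfg$criteria <- oracle_cfg$criteria[ids != ids[k]]
    oracle_cfg$questions <- oracle_cfg$questions[ids != ids[k]]
    oracle_tot <- vapply(cfg$diseases, function(d) {
      row <- match(d, ans$disease)
      sum(vapply(keep, function(id) {
        sc <- answer_score(config_question(oracle_cfg, id), ans[[id]][row])
        oracle_w[[id]] * sc$score
      }, numeric(1)))
    }, numeric(1))
    ord <- order(-oracle_tot, seq_along(oracle_tot))
    oracle_rank <- stats::setNames(
      vapply(oracle_tot[ord], function(t) 1L + sum(oracle_tot > t), integer(1)),
      cfg$diseases[ord])
    expect_identical(scan$summary$n_rank_changes[k],
                     sum(oracle_rank[names(base_rank)] != base_rank))
  }
  # a constant column is rank-inert
  cfg2 <- toy_config(3L, 5L, n_multi = 0L)
  df <- data.frame(disease = cfg2$diseases,
                   c1 = c("yes", "no", "yes", "no", "no"),
                   c2 = c("yes", "yes", "no", "no", "yes"),
                   c3 = "yes")  # constant
  ans2 <- answer_table(df, cfg2)
  p <- structure(list(priorities = c(c1 = 0.5, c2 = 0.3, c3 = 0.2),
                      consistency_ratio = 0), class = "zp_priority_vector")
  w2 <- assign_weights(p)
  scan2 <- sensitivity_scan(ans2, w2, cfg2)
  expect_identical(scan2$summary$n_rank_changes[3L], 0L)
  # fewer than 2 criteria is rejected
  cfg1 <- toy_config(2L, 5L)
  cfg1$criteria <- cfg1$criteria[1L]
  cfg1$questions <- cfg1$questions[1L]
  expect_error(sensitivity_scan(ans2, w2, cfg1), "at least 2")
})

test_that("sensitivity scan refuses fewer than 2 criteria and single diseases are inert", {
  cfg <- toy_config(3L, 1L)
  ans <- answer_table(data.frame(disease = "d1", c1 = "low", c2 = "yes",
                                 c3 = "no"), cfg)
  p <- structure(list(priorities = c(c1 = 0.5, c2 = 0.3, c3 = 0.2),
                      consistency_ratio = 0), class = "zp_priority_vector")
  scan <- suppressWarnings(sensitivity_scan(ans, assign_weights(p), cfg))
  expect_identical(scan$summary$n_rank_changes, c(0L, 0L, 0L))
})
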