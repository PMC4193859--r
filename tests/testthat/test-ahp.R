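test_that("matrix_from_pairs builds reciprocal matrices and polices the input", {
  m <- matrix_from_pairs(data.frame(criterion_a = "c1", criterion_b = "c2",
                                    ratio = 3), c("c1", "c2"))
  expect_equal(m$values, matrix(c(1, 1 / 3, 3, 1), 2, 2,
                                dimnames = list(c("c1", "c2"), c("c1", "c2"))))
  # single criterion needs no pairs
  m1 <- matrix_from_pairs(data.frame(criterion_a = character(),
                                     criterion_b = character(),
                                     ratio = numeric()), "c1")
  expect_equal(unname(m1$values), matrix(1))
  # contradictory duplicate (c1 vs c2 judged 3 both ways) is rejected
  expect_error(matrix_from_pairs(
    data.frame(criterion_a = c("c1", "c2"), criterion_b = c("c2", "c1"),
               ratio = c(3, 3)), c("c1", "c2")),
    "conflicting duplicate")
  # a consistent reverse entry is tolerated
  expect_silent(matrix_from_pairs(
    data.frame(criterion_a = c("c1", "c2"), criterion_b = c("c2", "c1"),
               ratio = c(3, 1 / 3)), c("c1", "c2")))
  # missing pairs are all named
  err <- tryCatch(matrix_from_pairs(
    data.frame(criterion_a = "c1", criterion_b = "c2", ratio = 2),
    c("c1", "c2", "c3")), error = identity)
  expect_match(conditionMessage(err), "\\(c1, c3\\)")
  expect_match(conditionMessage(err), "\\(c2, c3\\)")
  expect_warning(matrix_from_pairs(
    data.frame(criterion_a = "c1", criterion_b = "c2", ratio = 12),
    c("c1", "c2")), "Saaty")
})

test_that("priority derivation recovers known structure", {
  # total indifference: uniform priorities, zero inconsistency
  id3 <- pairwise_matrix(matrix(1, 3, 3), c("a", "b", "c"))
  pv <- priority_vector(id3)
  expect_equal(unname(pv$priorities), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(pv$consistency_ratio, 0, tolerance = 1e-9)
  # a consistent matrix reproduces its generator exactly
  v <- c(0.6, 0.3, 0.1)
  pv2 <- priority_vector(consistent_matrix(v))
  expect_equal(unname(pv2$priorities), v, tolerance = 1e-9)
  expect_equal(pv2$consistency_ratio, 0, tolerance = 1e-9)
  expect_equal(pv2$lambda_max, 3, tolerance = 1e-9)
  expect_equal(sum(pv2$priorities), 1, tolerance = 1e-12)
})

test_that("power iteration matches a dense eigendecomposition oracle", {
  set.seed(401)
  for (rep in 1:20) {
    n <- sample(3:7, 1L)
    m <- random_saaty_matrix(n)
    expect_equal(priority_vector(m)$priorities, eigen_oracle(m),
                 tolerance = 1e-8)
  }
})

test_that("eigenvector and geometric-mean methods agree on consistent matrices", {
  set.seed(402)
  for (rep in 1:10) {
    v <- runif(5, 0.5, 5)
    m <- consistent_matrix(v)
    expect_equal(priority_vector(m, "eigenvector")$priorities,
                 priority_vector(m, "geometric_mean")$priorities,
                 tolerance = 1e-9)
  }
})

test_that("consistency ratio follows its definition", {
  expect_equal(consistency_ratio(consistent_matrix(c(2, 1))), 0)  # n = 2
  expect_lt(consistency_ratio(consistent_matrix(c(5, 3, 1, 0.5))), 1e-9)
  # inconsistent 3x3: CR from first principles via the eigen oracle
  A <- pairwise_matrix(matrix(c(1, 1 / 2, 3, 2, 1, 1 / 4, 1 / 3, 4, 1), 3, 3,
                              byrow = TRUE), c("a", "b", "c"))
  lam <- max(Re(eigen(A$values, only.values = TRUE)$values))
  expect_equal(consistency_ratio(A),
               ((lam - 3) / 2) / ahp_random_index(3), tolerance = 1e-8)
  expect_gt(consistency_ratio(A), 0.1)
  expect_error(ahp_random_index(40), "table covers")
})

test_that("group aggregation honours its algebraic identities", {
  set.seed(403)
  m <- random_saaty_matrix(4)
  j1 <- participant_judgment("p1", m)
  # aggregating one participant is that participant's priority vector
  expect_equal(aggregate_group(list(j1))$priorities,
               priority_vector(m)$priorities, tolerance = 1e-12)
  # a matrix and its element-wise reciprocal cancel to indifference
  inv <- pairwise_matrix(1 / m$values, m$criteria_ids)
  agg <- aggregate_group(list(j1, participant_judgment("p2", inv)))
  expect_equal(unname(agg$priorities), rep(1 / 4, 4), tolerance = 1e-9)
  # aggregation is idempotent over identical participants
  same <- lapply(1:5, function(k) participant_judgment(paste0("p", k), m))
  expect_equal(aggregate_group(same)$priorities,
               priority_vector(m)$priorities, tolerance = 1e-9)
  # AIP: arithmetic mean of individual priorities, renormalized
  j2 <- participant_judgment("p2", random_saaty_matrix(4))
  aip <- aggregate_group(list(j1, j2), method = "aip")
  manual <- (priority_vector(j1$matrix)$priorities +
               priority_vector(j2$matrix)$priorities) / 2
  expect_equal(aip$priorities, manual / sum(manual), tolerance = 1e-12)
  # mismatched criteria sets are rejected
  j3 <- participant_judgment("p3", random_saaty_matrix(4, ids = letters[1:4]))
  expect_error(aggregate_group(list(j1, j3)), "different criteria")
})

test_that("sequential weights follow the ranking and handle ties deterministically", {
  p <- structure(list(priorities = c(sev = 0.35, bio = 0.30, eco = 0.18,
                                     col = 0.12, epi = 0.05),
                      consistency_ratio = 0),
                 class = "zp_priority_vector")
  w <- assign_weights(p)
  expect_identical(w$ranking, c("sev", "bio", "eco", "col", "epi"))
  expect_identical(unname(w$weights[w$ranking]), 5:1)
  expect_identical(sum(w$weights), 15L)  # n(n+1)/2
  # a single criterion gets weight 1
  p1 <- priority_vector(pairwise_matrix(matrix(1), "only"))
  expect_identical(unname(assign_weights(p1)$weights), 1L)
  # exact ties keep configuration order and are reported
  pt <- structure(list(priorities = c(a = 0.4, b = 0.4, c = 0.2),
                       consistency_ratio = 0),
                  class = "zp_priority_vector")
  expect_warning(wt <- assign_weights(pt), "tied")
  expect_identical(wt$ranking, c("a", "b", "c"))
  expect_identical(unname(wt$weights), c(3L, 2L, 1L))
  expect_gt(length(wt$tie_notes), 0L)
})

test_that("priorities are equivariant under criterion permutation", {
  set.seed(404)
  for (rep in 1:10) {
    n <- sample(3:6, 1L)
    m <- random_saaty_matrix(n)
    perm <- sample(n)
    mp <- pairwise_matrix(m$values[perm, perm], m$criteria_ids[perm])
    p <- priority_vector(m)$priorities
    pp <- priority_vector(mp)$priorities
    expect_equal(pp, p[perm], tolerance = 1e-9)
    # rank order of criteria is preserved
    expect_identical(names(sort(-pp)), names(sort(-p)))
  }
})

test_that("weights always sum to n(n+1)/2 for random group judgments", {
  set.seed(405)
  for (rep in 1:10) {
    n <- sample(2:8, 1L)
    jd <- lapply(1:4, function(k)
      participant_judgment(paste0("p", k), random_saaty_matrix(n)))
    w <- suppressWarnings(assign_weights(aggregate_group(jd)))
    expect_identical(sum(w$weights), as.integer(n * (n + 1) / 2))
    expect_setequal(w$ranking, sprintf("c%d", 1:n))
  }
})
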