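w_default <- metric_weights()

test_that("component distances match their closed forms", {
  expect_equal(trans_distance(list(x = 0, y = 0), list(x = 3, y = 4)), 5)
  expect_equal(trans_distance(list(x = 7, y = 9), list(x = 7, y = 9)), 0)
  # surface diagonal, computed as sqrt(1920^2 + 1080^2) beforehand
  expect_equal(trans_distance(list(x = 0, y = 0), list(x = 1920, y = 1080)),
               2202.9071700823, tolerance = 1e-12)
  expect_equal(rot_distance(10, 350), 20)
  expect_equal(rot_distance(0, 180), 180)
  expect_equal(rot_distance(90, 90), 0)
  # vectorized, and symmetric in its arguments
  expect_equal(rot_distance(c(0, 10, 359), c(350, 200, 1)),
               c(10, 170, 2))
  expect_equal(rot_distance(c(350, 200, 1), c(0, 10, 359)),
               c(10, 170, 2))
})

test_that("per-instrument scores follow the piecewise definition", {
  a <- ts("a", "c1", "I1", 0, 0, 0)
  b <- ts("b", "c2", "I1", 3, 4, 20)
  sc <- instrument_scores(a, b, w_default)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$status, "matched")
  expect_equal(sc$s_inst, 1 * 5 + 1 * 20)

  # disjoint identities: one w_miss per symmetric-difference instance
  d <- ts("d", "c2", "I2", 0, 0, 0)
  sc2 <- instrument_scores(a, d, w_default)
  expect_equal(sc2$status, c("missing", "missing"))
  expect_equal(sc2$s_inst, c(1000, 1000))
  expect_true(all(is.na(sc2$d_trans)))

  # identical setups match everywhere with zero scores
  sc3 <- instrument_scores(a, a, w_default)
  expect_equal(sc3$status, "matched")
  expect_equal(sc3$s_inst, 0)
})

test_that("table similarity reproduces the worked micro-examples", {
  a <- ts("a", "c1", "I1", 0, 0, 0)
  b <- ts("b", "c2", "I1", 3, 4, 20)
  d <- ts("d", "c2", "I2", 0, 0, 0)
  expect_equal(table_similarity(a, b, w_default), 25)
  expect_equal(table_similarity(a, d, w_default), 1000) # (1000+1000)/2
  expect_equal(table_similarity(a, a, w_default), 0)
  expect_equal(table_similarity(b, b, w_default), 0)
})

test_that("similarity of two empty setups is an error", {
  e1 <- ts("e1", "c1")
  e2 <- ts("e2", "c2")
  expect_error(table_similarity(e1, e2, w_default),
               class = "tablesim_validation_error")
  # one-sided empty is fine: all-missing
  a <- ts("a", "c1", "I1", 0, 0, 0, "I2", 5, 5, 5)
  expect_equal(table_similarity(a, e1, w_default), 1000)
})

test_that("normalization strategies divide by the documented denominators", {
  a <- ts("a", "c1", "I1", 0, 0, 0, "I2", 10, 0, 0)
  b <- ts("b", "c2", "I1", 3, 4, 20, "I3", 0, 0, 0, "I4", 1, 1, 0)
  # matched I1 (25), missing I2, I3, I4 -> sum = 25 + 3000, universe 4
  expect_equal(table_similarity(a, b, w_default), 3025 / 4)
  expect_equal(table_similarity(a, b, w_default, normalization = "max_size"),
               3025 / 3)
  expect_equal(table_similarity(a, b, w_default, normalization = "matched_only"),
               3025 / 1)
  disjoint <- ts("d", "c2", "I9", 0, 0, 0)
  expect_error(
    table_similarity(a, disjoint, w_default, normalization = "matched_only"),
    class = "tablesim_validation_error")
})

test_that("duplicate instances are matched by minimum-total-cost assignment", {
  # two I1 instances per side; greedy smallest-edge-first pairing would take
  # (30->25)=5 then (0->1000)=1000, total 1005; the optimal assignment is
  # (0->25)=25 and (30->1000)=970, total 995
  a <- ts("a", "c1", "I1", 0, 0, 0, "I1", 30, 0, 0)
  b <- ts("b", "c2", "I1", 25, 0, 0, "I1", 1000, 0, 0)
  sc <- instrument_scores(a, b, w_default)
  expect_equal(sum(sc$s_inst), 995)
  expect_equal(table_similarity(a, b, w_default), 995 / 2)

  # unequal multiplicity: 2 vs 1 -> one matched pair + one missing
  c2 <- ts("c2", "c2", "I1", 0, 3, 0)
  sc2 <- instrument_scores(a, c2, w_default)
  expect_equal(sort(sc2$status), c("matched", "missing"))
  expect_equal(sum(sc2$s_inst), 3 + 1000)
})

test_that("metric agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:40) {
    a <- random_setup("a", "c1", sample(1:6, 1))
    b <- random_setup("b", "c2", sample(1:6, 1))
    expect_equal(table_similarity(a, b, w_default),
                 oracle_s_tab(a, b, w_default),
                 tolerance = 1e-9)
  }
})

test_that("symmetry is bitwise and identity is exact on random setups", {
  set.seed(202)
  for (i in 1:25) {
    a <- random_setup("a", "c1", sample(1:6, 1))
    b <- random_setup("b", "c2", sample(1:6, 1))
    expect_identical(table_similarity(a, b, w_default),
                     table_similarity(b, a, w_default))
    expect_identical(table_similarity(a, a, w_default), 0)
  }
})

test_that("score respects non-negativity, upper bound and weight linearity", {
  set.seed(303)
  bound <- max(1000, 1 * 2202.9071700823 + 1 * 180)
  for (i in 1:20) {
    a <- random_setup("a", "c1", sample(1:5, 1))
    b <- random_setup("b", "c2", sample(1:5, 1))
    s <- table_similarity(a, b, w_default)
    expect_gte(s, 0)
    expect_lte(s, bound)
  }
  # linearity on fully matched tables: same identity sets, no misses
  for (i in 1:10) {
    base <- random_setup("a", "c1", 4, id_pool = sprintf("I%d", 1:4))
    pb <- base$placements
    pb$x <- pmin(pb$x + runif(4, 0, 50), 1920)
    pb$angle <- (pb$angle + runif(4, -30, 30)) %% 360
    b <- table_setup("b", "c2", pb)
    s1 <- table_similarity(base, b, metric_weights(1, 1, 1000))
    s2 <- table_similarity(base, b, metric_weights(2, 2, 1000))
    s_tr <- table_similarity(base, b, metric_weights(1, 0, 1000))
    s_rot <- table_similarity(base, b, metric_weights(0, 1, 1000))
    expect_equal(s2, 2 * s1, tolerance = 1e-12)
    expect_equal(s_tr + s_rot, s1, tolerance = 1e-12)
  }
})

test_that("raising w_miss or moving a matched instrument away never lowers the score", {
  set.seed(404)
  a <- ts("a", "c1", "I1", 100, 100, 0, "I2", 50, 60, 10)
  b <- ts("b", "c2", "I1", 300, 400, 90, "I3", 5, 5, 5)
  s_lo <- table_similarity(a, b, metric_weights(1, 1, 500))
  s_hi <- table_similarity(a, b, metric_weights(1, 1, 2000))
  expect_gt(s_hi, s_lo)
  # translate the matched I1 on b farther from its counterpart
  for (dx in c(0, 100, 400, 900)) {
    pb <- b$placements
    pb$x[pb$instrument_id == "I1"] <- 300 + dx
    s <- table_similarity(a, table_setup("b", "c2", pb), w_default)
    if (dx == 0) s_prev <- s
    expect_gte(s, s_prev)
    s_prev <- s
  }
})

test_that("similarity_matrix is symmetric, zero-diagonal and matches per-pair calls", {
  set.seed(505)
  col <- random_collection(4, n_clinics = 2)
  M <- similarity_matrix(col, w_default)
  expect_identical(unclass(M), t(unclass(M)))
  expect_equal(diag(M), setNames(rep(0, 4), names(col$setups)))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_identical(M[i, j],
                     table_similarity(col$setups[[i]], col$setups[[j]],
                                      w_default))
  }
  # two identical setups across clinics give a zero block
  a <- ts("a", "c1", "I1", 1, 2, 3)
  b <- ts("b", "c2", "I1", 1, 2, 3)
  M0 <- unclass(similarity_matrix(setup_collection(list(a, b)), w_default))
  attr(M0, "clinic_id") <- NULL
  expect_equal(M0, matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
})

test_that("invalid weights are rejected", {
  expect_error(metric_weights(-1, 1, 1000), class = "tablesim_validation_error")
  expect_error(metric_weights(1, Inf, 1000), class = "tablesim_validation_error")
  expect_error(as_metric_weights("x"), class = "tablesim_validation_error")
})
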