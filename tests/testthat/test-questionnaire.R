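test_that("clinic and total percentages follow the count definitions", {
  r <- response_counts(data.frame(
    clinic_id = rep(c("A", "B", "C"), each = 1),
    question_id = "Q1", yes_count = c(2, 3, 3), n = 5))
  expect_equal(clinic_percent(r, "A", "Q1"), 40)
  expect_equal(clinic_percent(r, "B", "Q1"), 60)
  expect_equal(total_percent(r, "Q1"), 100 * 8 / 15)
  expect_equal(round(total_percent(r, "Q1"), 1), 53.3)
  expect_error(clinic_percent(r, "Z", "Q1"), class = "tablesim_validation_error")
  expect_error(total_percent(r, "Q9"), class = "tablesim_validation_error")
})

test_that("participant-weighted total equals the clinic mean iff sizes are equal", {
  equal_n <- response_counts(data.frame(
    clinic_id = c("A", "B", "C"), question_id = "Q",
    yes_count = c(1, 4, 2), n = c(5, 5, 5)))
  pc <- vapply(c("A", "B", "C"), clinic_percent, numeric(1), r = equal_n, q = "Q")
  expect_equal(total_percent(equal_n, "Q"), mean(pc))
  unequal <- response_counts(data.frame(
    clinic_id = c("A", "B"), question_id = "Q",
    yes_count = c(1, 2), n = c(2, 8)))
  pc2 <- vapply(c("A", "B"), clinic_percent, numeric(1), r = unequal, q = "Q")
  expect_false(isTRUE(all.equal(total_percent(unequal, "Q"), mean(pc2))))
  expect_equal(total_percent(unequal, "Q"), 30)
})

test_that("total percentage is invariant to clinic relabeling", {
  r1 <- response_counts(data.frame(
    clinic_id = c("A", "B", "C"), question_id = "Q",
    yes_count = c(0, 2, 5), n = c(5, 5, 5)))
  r2 <- response_counts(data.frame(
    clinic_id = c("C", "A", "B"), question_id = "Q",
    yes_count = c(0, 2, 5), n = c(5, 5, 5)))
  expect_equal(total_percent(r1, "Q"), total_percent(r2, "Q"))
})

test_that("count validation catches impossible and inconsistent inputs", {
  expect_error(response_counts(data.frame(
    clinic_id = "A", question_id = "Q", yes_count = 6, n = 5)),
    class = "tablesim_validation_error")
  expect_error(response_counts(data.frame(
    clinic_id = c("A", "A"), question_id = c("Q1", "Q2"),
    yes_count = c(1, 1), n = c(5, 4))),
    class = "tablesim_validation_error")
  expect_error(response_counts(data.frame(
    clinic_id = c("A", "A"), question_id = c("Q1", "Q1"),
    yes_count = c(1, 2), n = c(5, 5))),
    class = "tablesim_validation_error")
})

test_that("question specs enforce ordering of dependencies", {
  expect_error(question_specs(data.frame(
    question_id = c("Q2", "Q1"), text = c("b", "a"),
    depends_on = c("Q1", ""))),
    class = "tablesim_validation_error")
  specs <- question_specs(data.frame(
    question_id = c("Q1", "Q2"), text = c("a", "b"),
    depends_on = c("", "Q1")))
  expect_equal(specs$depends_on[[2]], "Q1")
})

test_that("rendering annotates chains and rejects dependency violations", {
  specs <- question_specs(data.frame(
    question_id = c("Q1", "Q2"), text = c("gate", "dependent"),
    depends_on = c("", "Q1")))
  ok <- response_counts(data.frame(
    clinic_id = rep(c("A", "B"), 2),
    question_id = rep(c("Q1", "Q2"), each = 2),
    yes_count = c(2, 1, 1, 1), n = 5))
  out <- render_question_tables(specs, ok)
  expect_equal(nrow(out$csv), 2L)
  expect_match(out$text[3], "Q1 applies & Q2")
  # dependent cell can never exceed its gate
  expect_true(all(out$csv[out$csv$question_id == "Q2", c("A", "B")] <=
                  out$csv[out$csv$question_id == "Q1", c("A", "B")]))
  bad <- response_counts(data.frame(
    clinic_id = rep(c("A", "B"), 2),
    question_id = rep(c("Q1", "Q2"), each = 2),
    yes_count = c(2, 1, 3, 1), n = 5))
  expect_error(render_question_tables(specs, bad),
               class = "tablesim_validation_error")
  # empty question list renders an empty report
  empty <- question_specs(data.frame(question_id = character(),
                                     text = character(),
                                     depends_on = character()))
  expect_equal(length(render_question_tables(empty, ok)$text), 0L)
})

test_that("bundled study counts reproduce every printed percentage", {
  specs <- fess_study_questions()
  r <- fess_study_counts()
  out <- render_question_tables(specs, r)

  # per-clinic percentages, in the published clinic order insel/acqua/ukl
  cell <- function(q, clinic) round(clinic_percent(r, clinic, q), 1)
  per_clinic <- list(
    "Q1.1" = c(40, 60, 60),  "Q1.2" = c(40, 20, 20),
    "Q1.3" = c(40, 20, 20),  "Q1.4" = c(40, 0, 20),
    "Q2.1" = c(40, 20, 40),  "Q2.2" = c(20, 20, 40),
    "Q2.3" = c(20, 0, 40),   "Q2.4" = c(20, 0, 40),
    "Q3"   = c(40, 20, 80),  "Q4"   = c(80, 40, 100),
    "Q5"   = c(80, 40, 100),
    "Q6.1" = c(20, 20, 60),  "Q6.2" = c(0, 0, 0),
    "Q6.3" = c(80, 100, 100), "Q6.4" = c(60, 60, 80),
    "Q6.5" = c(60, 20, 20))
  for (q in names(per_clinic)) {
    expect_equal(vapply(c("insel", "acqua", "ukl"), cell, numeric(1), q = q),
                 setNames(per_clinic[[q]], c("insel", "acqua", "ukl")),
                 info = q)
  }

  totals <- c("Q1.1" = 53.3, "Q1.2" = 26.7, "Q1.3" = 26.7, "Q1.4" = 20.0,
              "Q2.1" = 33.3, "Q2.2" = 26.7, "Q2.3" = 20.0, "Q2.4" = 20.0,
              "Q3" = 46.7, "Q4" = 73.3, "Q5" = 73.3,
              "Q6.1" = 33.3, "Q6.2" = 0.0, "Q6.3" = 93.3, "Q6.4" = 66.7,
              "Q6.5" = 33.3)
  for (q in names(totals)) {
    expect_equal(round(total_percent(r, q), 1), unname(totals[q]), info = q)
  }

  # chains are monotone non-increasing in every clinic and in total
  for (chain in list(c("Q1.1", "Q1.2", "Q1.3", "Q1.4"),
                     c("Q2.1", "Q2.2", "Q2.3", "Q2.4"))) {
    for (clinic in c("insel", "acqua", "ukl")) {
      p <- vapply(chain, clinic_percent, numeric(1), r = r, clinic = clinic)
      expect_true(all(diff(p) <= 0))
    }
    pt <- vapply(chain, total_percent, numeric(1), r = r)
    expect_true(all(diff(pt) <= 0))
  }
})

test_that("questionnaire CSV readers round-trip the bundled files", {
  specs_path <- system.file("extdata", "fess_questions.csv",
                            package = "tablesim")
  counts_path <- system.file("extdata", "fess_question_counts.csv",
                             package = "tablesim")
  expect_equal(read_question_specs(specs_path), fess_study_questions())
  expect_equal(read_question_counts(counts_path), fess_study_counts())
})
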