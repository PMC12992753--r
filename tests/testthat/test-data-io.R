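test_that("confidence ratings are binned at the printed boundaries", {
  expect_equal(as.character(categorize_confidence(c(0, 30, 31, 70, 71, 100))),
               c("low", "low", "moderate", "moderate", "high", "high"))
  expect_error(categorize_confidence(101), "\\[0, 100\\]")
  expect_error(categorize_confidence(-1), "\\[0, 100\\]")
  expect_error(categorize_confidence(30.5), "non-integer")
  expect_equal(as.character(categorize_confidence(30.9, strict = FALSE)),
               "low")
  ## configurable edges
  expect_equal(as.character(categorize_confidence(40, breaks = c(50, 80))),
               "low")
})

test_that("trial aggregation produces a model-ready table", {
  empty <- aggregate_trials(
    data.frame(participant = integer(), condition = character(),
               lineup_type = character(), response = character(),
               confidence = integer()),
    conditions = c("negative", "positive"))
  expect_identical(nrow(empty), 36L)
  expect_true(all(empty$count == 0))
  expect_identical(empty$category, lineup_feedback_counts()$category)

  rec <- data.frame(
    participant = c(1, 2, 3),
    condition = "negative",
    lineup_type = "culprit-present",
    response = "suspect",
    confidence = c(80, 75, 90))
  tab <- aggregate_trials(rec, conditions = c("negative", "positive"))
  expect_identical(sum(tab$count), 3)
  expect_identical(
    tab$count[tab$category == "negative.CP.suspect.H"], 3)

  dup <- rbind(rec, rec[1, ])
  expect_error(aggregate_trials(dup, conditions = c("negative", "positive")),
               "duplicate")
  bad <- rec
  bad$response <- "shrug"
  expect_error(aggregate_trials(bad, conditions = "negative"), "unknown")
})

test_that("aggregated totals equal the records per tree", {
  m <- lineup_base_model()
  set.seed(33)
  th <- rand_theta(m)
  sim <- simulate_frequencies(m, th, n_per_tree = 120)
  ## expand to trial records and re-aggregate
  lev_mid <- c(L = 10, M = 50, H = 90)
  rows <- sim[rep(seq_len(nrow(sim)), sim$count), ]
  parts <- regmatches(rows$category,
                      regexec("^([a-z]+)\\.(CP|CA)\\.([a-z]+)\\.(L|M|H)$",
                              rows$category))
  rec <- data.frame(
    condition = vapply(parts, `[[`, character(1), 2),
    lineup_type = ifelse(vapply(parts, `[[`, character(1), 3) == "CP",
                         "culprit-present", "culprit-absent"),
    response = vapply(parts, `[[`, character(1), 4),
    confidence = lev_mid[vapply(parts, `[[`, character(1), 5)])
  rec$participant <- stats::ave(seq_len(nrow(rec)),
                                rec$condition, rec$lineup_type,
                                FUN = seq_along)
  tab <- aggregate_trials(rec, conditions = c("negative", "positive"))
  expect_identical(tab$count, sim$count)
})

test_that("the bundled feedback-study counts are intact", {
  counts <- lineup_feedback_counts()
  expect_identical(nrow(counts), 36L)
  get <- function(cat) counts$count[counts$category == cat]
  expect_identical(get("negative.CP.suspect.L"), 142)
  expect_identical(get("negative.CP.suspect.H"), 242)
  expect_identical(get("positive.CA.reject.H"), 327)
  expect_identical(get("positive.CP.suspect.M"), 195)
  totals <- tapply(counts$count, counts$tree, sum)
  expect_true(all(totals == 1565))
  expect_identical(sum(counts$count), 6260)
})

test_that("frequency CSV round-trips losslessly", {
  counts <- lineup_feedback_counts()
  path <- withr::local_tempfile(fileext = ".csv")
  write_freq_csv(counts, path)
  back <- read_freq_csv(path)
  expect_identical(as.data.frame(back), as.data.frame(counts))
})
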