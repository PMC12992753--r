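test_that("guessing splits identifications by the lineup-size constant", {
  m <- lineup_2ht_model()
  th <- c(negative.dP = 0, positive.dP = 0, dA = 0, b = 0,
          negative.g = 1, positive.g = 1)
  p <- mpt_probabilities(m, th)
  for (tn in names(p)) {
    expect_equal(unname(p[[tn]]), c(.16667, .83333, 0), tolerance = 1e-12)
  }

  ## certain culprit-absence detection: certain correct rejection
  th2 <- c(negative.dP = .2, positive.dP = .2, dA = 1, b = .5,
           negative.g = .5, positive.g = .5)
  p2 <- mpt_probabilities(m, th2)
  expect_equal(p2[["negative.CA"]][["negative.CA.reject"]], 1)
})

test_that("culprit identification rate matches hand enumeration", {
  ## dP + (1-dP) b + (1-dP)(1-b) g / 6 at the design's rounded constant
  m <- lineup_2ht_model(lineup_design(conditions = "neg"))
  p <- mpt_probabilities(m, c(neg.dP = .30, neg.dA = .06, neg.b = .06,
                              neg.g = .54))
  expected <- .30 + .70 * .06 + .70 * .94 * .54 * .16667
  expect_equal(p[["neg.CP"]][["neg.CP.suspect"]], expected,
               tolerance = 1e-12)
  expect_equal(expected, .401, tolerance = 1e-3)
})

test_that("lineup-size constant honours the exact-fraction switch", {
  approx <- lineup_2ht_model(lineup_design(conditions = "s"))
  exact <- lineup_2ht_model(lineup_design(conditions = "s",
                                          exact_fraction = TRUE))
  th <- c(s.dP = 0, s.dA = 0, s.b = 0, s.g = 1)
  expect_equal(mpt_probabilities(approx, th)[["s.CP"]][["s.CP.suspect"]],
               .16667)
  expect_equal(mpt_probabilities(exact, th)[["s.CP"]][["s.CP.suspect"]],
               1 / 6)
  expect_error(lineup_design(lineup_size = 1), "integer >= 2")
})

test_that("confidence model marginalizes onto the 2HT model", {
  d <- lineup_design()
  m3 <- lineup_confidence_model(d)
  m1 <- lineup_2ht_model(d)
  set.seed(21)
  for (r in 1:100) {
    th <- rand_theta(m3)
    p3 <- mpt_probabilities(m3, th)
    p1 <- mpt_probabilities(m1, th[free_parameters(m1)])
    for (tn in names(p3)) {
      marg <- tapply(p3[[tn]],
                     sub("\\.(L|M|H)$", "", names(p3[[tn]])), sum)
      expect_equal(as.vector(marg[names(p1[[tn]])]), unname(p1[[tn]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("without bias, suspect picks are 1 in lineup-size of all picks", {
  for (size in c(4L, 6L, 8L)) {
    m <- lineup_2ht_model(lineup_design(lineup_size = size,
                                        conditions = "s",
                                        exact_fraction = TRUE))
    p <- mpt_probabilities(m, c(s.dP = 0, s.dA = 0, s.b = 0, s.g = .63))
    for (tn in names(p)) {
      pick <- p[[tn]][paste0(tn, c(".suspect", ".filler"))]
      expect_equal(unname(pick[1] / sum(pick)), 1 / size,
                   tolerance = 1e-12)
    }
  }
})

test_that("the base model matches the bundled fixture schema", {
  m <- lineup_base_model()
  counts <- lineup_feedback_counts()
  expect_identical(length(m$trees), 4L)
  expect_identical(
    paste(m$comp$cat_tree, m$comp$cat_name),
    paste(counts$tree, counts$category))
  set.seed(2)
  p <- mpt_probabilities(m, rand_theta(m))
  expect_identical(lengths(p), c(negative.CP = 9L, negative.CA = 9L,
                                 positive.CP = 9L, positive.CA = 9L))
})
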