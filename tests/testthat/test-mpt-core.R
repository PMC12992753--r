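test_that("category probabilities follow the branch algebra", {
  d <- lineup_design(conditions = "study")
  m <- lineup_2ht_model(d)

  ## detection certain: all culprit-present mass on the culprit
  p <- mpt_probabilities(m, c(study.dP = 1, study.dA = .2, study.b = .3,
                              study.g = .7))
  expect_equal(unname(p[["study.CP"]]), c(1, 0, 0))

  ## all processes off: certain rejection
  p <- mpt_probabilities(m, c(study.dP = 0, study.dA = 0, study.b = 0,
                              study.g = 0))
  expect_equal(unname(p[["study.CP"]]), c(0, 0, 1))

  ## hand-enumerated: dP = .5, b = 0, g = .6, k = 1/6
  m6 <- lineup_2ht_model(lineup_design(conditions = "study",
                                       exact_fraction = TRUE))
  p <- mpt_probabilities(m6, c(study.dP = .5, study.dA = 0, study.b = 0,
                               study.g = .6))
  expect_equal(unname(p[["study.CP"]]), c(.55, .25, .20), tolerance = 1e-12)
})

test_that("probability evaluation rejects bad parameter vectors", {
  m <- lineup_2ht_model(lineup_design(conditions = "study"))
  expect_error(mpt_probabilities(m, c(study.dP = .5)), "missing parameter")
  expect_error(
    mpt_probabilities(m, c(study.dP = 1.2, study.dA = .1, study.b = .1,
                           study.g = .1)),
    "outside \\[0, 1\\]")
  expect_error(mpt_probabilities(m, c(.1, .2, .3, .4)), "named")
})

test_that("probabilities are normalized and match the brute-force oracle", {
  set.seed(11)
  for (m in list(lineup_2ht_model(), lineup_confidence_model(),
                 lineup_base_model())) {
    for (r in 1:100) {
      th <- rand_theta(m)
      p <- mpt_probabilities(m, th)
      sums <- vapply(p, sum, numeric(1))
      expect_true(all(abs(sums - 1) < 1e-12))
      orac <- oracle_model_probs(m, th)
      for (tn in names(p)) {
        expect_lt(max(abs(p[[tn]] - orac[[tn]][names(p[[tn]])])), 1e-12)
      }
    }
  }
})

test_that("free-parameter counts and degrees of freedom are correct", {
  base <- lineup_base_model()
  expect_identical(n_free_parameters(base), 22L)
  expect_identical(mpt_df(base), 10L)

  unshared <- lineup_confidence_model(lineup_design(share_b = FALSE,
                                                    share_dA = FALSE))
  expect_identical(n_free_parameters(unshared), 24L)
  expect_identical(mpt_df(unshared), 8L)

  single <- lineup_confidence_model(lineup_design(conditions = "study"))
  expect_identical(n_free_parameters(single), 12L)
  expect_identical(mpt_df(single), 4L)

  ## a lone culprit-present tree with dP, b, g free is over-parameterized
  over <- mpt_model(mpt_tree(
    "cp", c("suspect", "filler", "reject"),
    list(mpt_branch("suspect", mpt_par("dP")),
         mpt_branch("suspect", mpt_comp("dP"), mpt_par("b")),
         mpt_branch("suspect", mpt_comp("dP"), mpt_comp("b"), mpt_par("g"),
                    mpt_const(1 / 6)),
         mpt_branch("filler", mpt_comp("dP"), mpt_comp("b"), mpt_par("g"),
                    mpt_const(5 / 6)),
         mpt_branch("reject", mpt_comp("dP"), mpt_comp("b"),
                    mpt_comp("g")))))
  expect_identical(n_free_parameters(over), 3L)
  expect_error(mpt_df(over), "over-parameterized")
})

test_that("equality and fixing constraints behave as substitutions", {
  base <- lineup_base_model()
  eq <- apply_constraints(base, equalities = list(c("negative.dP",
                                                    "positive.dP")))
  expect_identical(n_free_parameters(eq), 21L)

  ## constrained model probabilities equal the original at induced values
  set.seed(5)
  th <- rand_theta(eq)
  induced <- c(th, positive.dP = unname(th[["negative.dP"]]))
  expect_equal(mpt_probabilities(eq, th, flat = TRUE),
               mpt_probabilities(base, induced, flat = TRUE),
               tolerance = 1e-14)

  ## fixing g to zero removes guessing-based filler identifications
  m <- lineup_2ht_model(lineup_design(conditions = "study"))
  fixed <- apply_constraints(m, fixings = c(study.g = 0))
  expect_identical(n_free_parameters(fixed), 3L)
  p <- mpt_probabilities(fixed, c(study.dP = .4, study.dA = .3,
                                  study.b = .2))
  expect_equal(p[["study.CP"]][["study.CP.filler"]], 0)

  expect_error(
    apply_constraints(base, equalities = list(c("negative.dP", "nosuch"))),
    "unknown parameter")
  expect_error(
    mpt_constraints(equalities = list(c("a", "b"), c("b", "c"))),
    "at most one constraint")
})

test_that("shrinkage reparameterization preserves dimensionality exactly", {
  base <- lineup_base_model()
  shr <- apply_constraints(base, shrinkages = list(
    mpt_shrinkage("negative.c_d1", "positive.c_d1", "s_d")))
  expect_identical(n_free_parameters(shr), 22L)
  expect_true("s_d" %in% free_parameters(shr))
  expect_false("negative.c_d1" %in% free_parameters(shr))

  ## probabilities at (s, x_pos) equal the base model's at
  ## (x_neg = s * x_pos, x_pos), exactly
  set.seed(7)
  for (r in 1:20) {
    th <- rand_theta(shr)
    induced <- th[setdiff(names(th), "s_d")]
    induced["negative.c_d1"] <- th[["s_d"]] * th[["positive.c_d1"]]
    expect_identical(mpt_probabilities(shr, th, flat = TRUE),
                     mpt_probabilities(base, induced, flat = TRUE))
  }

  ## cyclic / chained shrinkage graphs are rejected
  expect_error(apply_constraints(base, shrinkages = list(
    mpt_shrinkage("negative.c_d1", "positive.c_d1", "s1"),
    mpt_shrinkage("positive.c_d1", "negative.c_g1", "s2"))),
    "shrink")
  expect_error(mpt_shrinkage("a", "a", "s"), "distinct")
})

test_that("EQN files round-trip the built-in models", {
  for (m in list(lineup_2ht_model(), lineup_base_model())) {
    path <- withr::local_tempfile(fileext = ".eqn")
    write_eqn(m, path)
    m2 <- read_eqn(path)
    expect_setequal(free_parameters(m2), free_parameters(m))
    set.seed(3)
    th <- rand_theta(m)
    p1 <- mpt_probabilities(m, th, flat = TRUE)
    p2 <- mpt_probabilities(m2, th, flat = TRUE)
    ## the reader orders categories by first appearance; compare by name
    expect_equal(p2[names(p1)], p1, tolerance = 1e-12)
  }
})

test_that("the EQN parser understands the standard dialect", {
  path <- withr::local_tempfile(fileext = ".eqn")
  writeLines(c("4",
               "t1 hit d",
               "t1 hit (1-d)*g*0.5",
               "t1 miss (1-d)*(1-g)",
               "t1 miss (1-d)*g*0.5"), path)
  m <- read_eqn(path)
  expect_setequal(free_parameters(m), c("d", "g"))
  p <- mpt_probabilities(m, c(d = .4, g = .6))
  expect_equal(p[["t1"]][["hit"]], .4 + .6 * .6 * .5, tolerance = 1e-14)

  shr <- apply_constraints(lineup_base_model(), shrinkages = list(
    mpt_shrinkage("negative.c_d1", "positive.c_d1", "s_d")))
  expect_error(write_eqn(shr, withr::local_tempfile(fileext = ".eqn")),
               "EQN")
})
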