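binomial_model <- function() {
  mpt_model(mpt_tree("t", c("A", "B"),
                     list(mpt_branch("A", mpt_par("q")),
                          mpt_branch("B", mpt_comp("q")))),
            name = "binomial")
}

test_that("the binomial MLE is recovered in closed form", {
  m <- binomial_model()
  d <- data.frame(tree = "t", category = c("A", "B"), count = c(30, 70))
  f <- mpt_fit(m, d, n_starts = 3, seed = 1)
  expect_equal(unname(coef(f)), .30, tolerance = 1e-8)
  expect_equal(f$g_squared, 0, tolerance = 1e-10)
  expect_identical(f$df, 0L)  # saturated: one free probability, two cells
  ## closed-form binomial standard error sqrt(pq/n)
  expect_equal(unname(f$se), sqrt(.3 * .7 / 100), tolerance = 1e-4)
})

test_that("a fit to (near-)expected frequencies recovers the truth", {
  m <- lineup_base_model()
  set.seed(4)
  th <- .1 + .8 * rand_theta(m)  # interior truth
  p <- mpt_probabilities(m, th, flat = TRUE)
  d <- data.frame(tree = m$comp$cat_tree, category = m$comp$cat_name,
                  count = round(p * 1e7))
  f0 <- mpt_fit(m, d, n_starts = 4, seed = 9, compute_se = FALSE)
  expect_lt(f0$g_squared, 1e-3)   # only count-rounding noise remains
  expect_lt(max(abs(coef(f0) - th)), 1e-4)
})

test_that("frequency tables are validated against the model schema", {
  m <- binomial_model()
  expect_error(mpt_fit(m, data.frame(tree = "t", category = "A",
                                     count = 30), n_starts = 1),
               "missing categories")
  expect_error(
    mpt_fit(m, data.frame(tree = "t", category = c("A", "B", "C"),
                          count = c(1, 2, 3)), n_starts = 1),
    "unknown to the model")
  expect_error(mpt_freq(data.frame(tree = "t", category = c("A", "B"),
                                   count = c(-1, 2))),
               "non-negative")
  expect_error(mpt_freq(data.frame(tree = "t", category = c("A", "A"),
                                   count = c(1, 2))),
               "duplicated")
})

test_that("identifiability check separates identified from unidentified", {
  m <- binomial_model()
  d <- data.frame(tree = "t", category = c("A", "B"), count = c(30, 70))
  ic <- identifiability_check(m, d, n_repeats = 50, seed = 8, tol = 1e-10)
  expect_true(ic$pass)
  expect_lt(ic$spread, 1e-10)

  ## two multiplied parameters that are never separated: only q * r is
  ## identified, so (q, r) lie on a ridge
  bad <- nonidentifiable_model()
  d3 <- data.frame(tree = "t", category = c("A", "B", "C"),
                   count = c(15, 15, 70))
  ic_bad <- identifiability_check(bad, d3, n_repeats = 50, seed = 8)
  expect_false(ic_bad$pass)
  expect_gt(ic_bad$spread, .01)
  ## ... and the (near-)singular information matrix shows up either as a
  ## non-identifiability warning or as exploding standard errors
  f_bad <- suppressWarnings(mpt_fit(bad, d3, n_starts = 3, seed = 1))
  expect_true(!isTRUE(f_bad$identifiable) || any(f_bad$se > 100))
})

test_that("the optimizer never loses to the generating parameters", {
  m <- lineup_confidence_model(lineup_design(conditions = "s"))
  set.seed(31)
  for (r in 1:5) {
    th <- .05 + .9 * rand_theta(m)
    d <- simulate_frequencies(m, th, n_per_tree = 800)
    f <- mpt_fit(m, d, n_starts = 4, compute_se = FALSE)
    aligned <- mptlineup:::align_counts(m, d)
    obj <- mptlineup:::make_objective(m, aligned)
    expect_lte(f$g_squared, obj$g2_of_theta(th) + 1e-8)
  }
})

test_that("equality constraints can only increase the fitted G^2", {
  m <- lineup_base_model()
  fit <- feedback_fit_cache()
  pars <- free_parameters(m)
  set.seed(17)
  for (r in 1:4) {
    pair <- sample(pars, 2L)
    restricted <- apply_constraints(m, equalities = list(pair))
    fr <- mpt_fit(restricted, fit$data, n_starts = 4, seed = r,
                  compute_se = FALSE)
    expect_gte(fr$g_squared, fit$g_squared - 1e-6)
  }
})

test_that("fit methods are mutually consistent", {
  f <- feedback_fit_cache()
  expect_equal(sum(residuals(f, "deviance")^2), f$g_squared,
               tolerance = 1e-8)
  expect_equal(unname(fitted(f)),
               unname(predict(f, "counts")$value))
  expect_equal(sum(fitted(f)), 4 * 1565, tolerance = 1e-6)
  expect_equal(sqrt(diag(vcov(f))), f$se, ignore_attr = TRUE)
  expect_equal(as.numeric(logLik(f)), f$log_likelihood)
  ## simulate() is seed-reproducible and keeps the tree totals
  s1 <- simulate(f, nsim = 2, seed = 99)
  s2 <- simulate(f, nsim = 2, seed = 99)
  expect_identical(s1, s2)
  expect_equal(as.vector(tapply(s1[[1]]$count, s1[[1]]$tree, sum)),
               rep(1565, 4))
})
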