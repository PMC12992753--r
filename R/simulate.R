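#' Simulate a frequency table from an MPT model
#'
#' Draws one independent multinomial per tree at the category
#' probabilities implied by `theta`.
#'
#' @param model An [mpt_model()].
#' @param theta Named parameter vector in `[0, 1]`.
#' @param n_per_tree Number of observations per tree; a scalar or one
#'   value per tree.
#' @param seed Optional integer seed.
#' @return A frequency data frame (`tree`, `category`, `count`).
#' @export
simulate_frequencies <- function(model, theta, n_per_tree, seed = NULL) {
  stopifnot(inherits(model, "mpt_model"))
  probs <- mpt_probabilities(model, theta)
  ntree <- length(probs)
  if (length(n_per_tree) == 1L) n_per_tree <- rep(n_per_tree, ntree)
  stopifnot(length(n_per_tree) == ntree)
  if (any(n_per_tree < 1) || any(n_per_tree != round(n_per_tree))) {
    stop("'n_per_tree' must be positive integers", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- NULL
  for (i in seq_along(probs)) {
    counts <- as.vector(stats::rmultinom(1L, n_per_tree[i], probs[[i]]))
    out <- rbind(out, data.frame(tree = names(probs)[i],
                                 category = names(probs[[i]]),
                                 count = counts))
  }
  mpt_freq(out)
}

#' Parameter-recovery study
#'
#' Simulates `replicates` data sets from the model at `theta_true`, refits
#' each, and summarizes bias, root-mean-square error and the coverage of
#' the 95% Wald intervals. This validates the whole
#' simulate-fit-standard-error pipeline at a given design size.
#'
#' @param model An [mpt_model()].
#' @param theta_true Named generating parameter vector.
#' @param n_per_tree Observations per tree.
#' @param replicates Number of simulated data sets.
#' @param seed Optional integer seed.
#' @param n_starts Starts per replicate fit (the fitting default, 10).
#' @return An object of class `mpt_recovery`: a data frame per parameter
#'   with `true`, `mean_estimate`, `bias`, `rmse`, `coverage`, plus the
#'   estimate matrix and the number of failed fits as attributes.
#' @export
parameter_recovery <- function(model, theta_true, n_per_tree,
                               replicates = 200, seed = NULL,
                               n_starts = 10) {
  stopifnot(inherits(model, "mpt_model"))
  th <- check_theta(model, theta_true)
  if (!is.null(seed)) set.seed(seed)
  k <- length(model$roster)
  est <- matrix(NA_real_, replicates, k,
                dimnames = list(NULL, model$roster))
  cover <- matrix(NA, replicates, k)
  failed <- 0L
  for (r in seq_len(replicates)) {
    dat <- simulate_frequencies(model, th, n_per_tree)
    f <- tryCatch(
      suppressWarnings(mpt_fit(model, dat, n_starts = n_starts)),
      error = function(e) NULL)
    if (is.null(f)) { failed <- failed + 1L; next }
    est[r, ] <- f$estimates
    half <- stats::qnorm(.975) * f$se
    cover[r, ] <- abs(f$estimates - th) <= half
  }
  ok <- stats::complete.cases(est)
  mean_est <- colMeans(est[ok, , drop = FALSE])
  bias <- mean_est - th
  rmse <- sqrt(colMeans((est[ok, , drop = FALSE] -
                           rep(th, each = sum(ok)))^2))
  coverage <- colMeans(cover[ok, , drop = FALSE], na.rm = TRUE)
  tab <- data.frame(parameter = model$roster, true = unname(th),
                    mean_estimate = unname(mean_est),
                    bias = unname(bias), rmse = unname(rmse),
                    coverage = unname(coverage))
  structure(tab, class = c("mpt_recovery", "data.frame"),
            estimates = est, replicates = replicates, failed = failed,
            n_per_tree = n_per_tree)
}

#' Power of a chi-squared test for a given effect size
#'
#' Power of a chi-squared test with `df` degrees of freedom at level
#' `alpha` against an alternative with Cohen's effect size `w` and
#' effective sample size `n_effective`, using the noncentral chi-squared
#' distribution with noncentrality `lambda = n_effective * w^2`.
#'
#' @param w Cohen's effect size.
#' @param n_effective Effective number of observations.
#' @param df Degrees of freedom of the test.
#' @param alpha Significance level.
#' @return The power, in `[0, 1]`.
#' @export
chisq_power <- function(w, n_effective, df = 1, alpha = .05) {
  stopifnot(w >= 0, n_effective > 0, df >= 1, alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = n_effective * w^2, lower.tail = FALSE)
}

#' Minimal detectable effect size of a chi-squared test
#'
#' Sensitivity analysis: the smallest Cohen's `w` that a chi-squared test
#' with `df` degrees of freedom detects with the requested power at level
#' `alpha`, given `n_effective` observations. Solved by root-finding on
#' the noncentral chi-squared survival function with noncentrality
#' `lambda = n_effective * w^2`.
#'
#' @param n_effective Effective number of observations (participants times
#'   responses per participant, when responses are pooled).
#' @param alpha Significance level.
#' @param power Target power (`1 - beta`).
#' @param df Degrees of freedom of the test.
#' @return The minimal detectable `w`.
#' @examples
#' minimal_detectable_w(n_effective = 6260)
#' @export
minimal_detectable_w <- function(n_effective, alpha = .05, power = .95,
                                 df = 1) {
  stopifnot(n_effective > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  f <- function(w) chisq_power(w, n_effective, df, alpha) - power
  upper <- 1
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 10
  if (f(upper) < 0) {
    stop("requested power unattainable at this sample size", call. = FALSE)
  }
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}
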