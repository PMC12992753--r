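## ---- frequency data ------------------------------------------------------

#' Validate a frequency table
#'
#' A frequency table is a data frame with columns `tree`, `category` and
#' `count` (non-negative integers), one row per response category, holding
#' one multinomial per tree.
#'
#' @param data A data frame.
#' @return The validated data frame (invisibly classed `mpt_freq`).
#' @export
mpt_freq <- function(data) {
  data <- as.data.frame(data)
  need <- c("tree", "category", "count")
  if (!all(need %in% names(data))) {
    stop("frequency data needs columns tree, category, count",
         call. = FALSE)
  }
  if (any(is.na(data$count)) || any(data$count < 0) ||
      any(data$count != round(data$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  key <- paste(data$tree, data$category, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (tree, category) rows in frequency data",
         call. = FALSE)
  }
  data$tree <- as.character(data$tree)
  data$category <- as.character(data$category)
  data$count <- as.numeric(data$count)
  class(data) <- c("mpt_freq", "data.frame")
  data
}

## Align observed counts with the model's category order.
align_counts <- function(model, data) {
  data <- mpt_freq(data)
  mkey <- paste(model$comp$cat_tree, model$comp$cat_name, sep = "\r")
  dkey <- paste(data$tree, data$category, sep = "\r")
  idx <- match(mkey, dkey)
  if (anyNA(idx)) {
    stop("data is missing categories required by the model, e.g. ",
         sub("\r", " / ", mkey[which(is.na(idx))[1L]]), call. = FALSE)
  }
  extra <- setdiff(dkey, mkey)
  if (length(extra)) {
    stop("data contains categories unknown to the model, e.g. ",
         sub("\r", " / ", extra[1L]), call. = FALSE)
  }
  n <- data$count[idx]
  tree_f <- factor(model$comp$cat_tree, levels = model$comp$tree_names)
  Ntree <- tapply(n, tree_f, sum)
  if (any(Ntree <= 0)) {
    stop("every tree needs a positive total count", call. = FALSE)
  }
  list(n = n, Ntot = as.vector(Ntree)[as.integer(tree_f)],
       tree_totals = Ntree)
}

## ---- G-squared objective -------------------------------------------------

## Builds closures for G^2 and its gradient on the logit scale.
make_objective <- function(model, aligned) {
  comp <- model$comp
  map <- model$param_map
  roster <- model$roster
  n <- aligned$n
  Ntot <- aligned$Ntot
  pos <- n > 0
  npos <- n[pos]
  const_term <- 2 * sum(npos * log(npos / Ntot[pos]))

  g2_of_theta <- function(theta) {
    s <- resolve_structural(map, theta)
    ev <- eval_categories_grad(comp, s)
    p <- pmax(ev$p, 1e-300)
    const_term - 2 * sum(npos * log(p[pos]))
  }
  ## Hu-Batchelder EM is available whenever every structural parameter is
  ## either free or constant (no shrinkage products): the likelihood is
  ## then of beta form in each free parameter and the M-step is a ratio of
  ## expected branch counts. EM is monotone and keeps parameters interior,
  ## which makes it robust to the boundary traps gradient methods can fall
  ## into from poor random starts.
  em_compatible <- all(vapply(map, function(m) m$kind != "prod",
                              logical(1)))
  em_step <- NULL
  if (em_compatible) {
    cat_of_branch <- apply(comp$Cmat, 2L, which.max)
    Fmat <- matrix(0, length(map), length(roster),
                   dimnames = list(names(map), roster))
    for (i in seq_along(map)) {
      if (map[[i]]$kind == "free") Fmat[i, map[[i]]$name] <- 1
    }
    tAF <- crossprod(Fmat, t(comp$A))          # k x nb
    tABF <- crossprod(Fmat, t(comp$A + comp$B))
    em_step <- function(theta) {
      s <- resolve_structural(map, theta)
      s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
      branch <- comp$cb * exp(as.vector(comp$A %*% log(s) +
                                          comp$B %*% log1p(-s)))
      p <- pmax(as.vector(comp$Cmat %*% branch), 1e-300)
      m <- branch * (n / p)[cat_of_branch]
      num <- as.vector(tAF %*% m)
      den <- as.vector(tABF %*% m)
      new <- ifelse(den > 0, num / den, theta)
      names(new) <- roster
      new
    }
  }

  list(
    fn = function(eta) {
      theta <- stats::plogis(eta)
      names(theta) <- roster
      g2_of_theta(theta)
    },
    gr = function(eta) {
      theta <- stats::plogis(eta)
      names(theta) <- roster
      s <- resolve_structural(map, theta)
      ev <- eval_categories_grad(comp, s)
      p <- pmax(ev$p, 1e-300)
      J <- map_jacobian(map, theta, roster)
      dp_free <- ev$dp %*% J
      g_theta <- -2 * as.vector(crossprod(dp_free[pos, , drop = FALSE],
                                          npos / p[pos]))
      g_theta * theta * (1 - theta)
    },
    g2_of_theta = g2_of_theta,
    em_step = em_step,
    roster = roster
  )
}

one_start <- function(obj, eta0, maxit = 1000L) {
  if (!is.null(obj$em_step)) {
    theta <- stats::plogis(eta0)
    names(theta) <- obj$roster
    for (it in seq_len(500L)) {
      new <- obj$em_step(theta)
      if (max(abs(new - theta)) < 1e-9) { theta <- new; break }
      theta <- new
    }
    eta0 <- stats::qlogis(pmin(pmax(theta, 1e-9), 1 - 1e-9))
  }
  o <- stats::optim(eta0, obj$fn, obj$gr, method = "BFGS",
                    control = list(maxit = maxit, reltol = 1e-14))
  o <- polish_newton(obj, o)
  o
}

## Newton refinement of a quasi-Newton solution: drives the analytic
## gradient to (near) machine zero so that independent starts agree to
## ~1e-8 in the estimates, using a central-difference Hessian of the
## gradient on the logit scale. Parameters whose likelihood keeps
## increasing towards 0 or 1 are boundary solutions; they are snapped to
## the exact boundary (the snap is kept only if it does not worsen G^2).
polish_newton <- function(obj, o, max_iter = 12L) {
  eta <- o$par
  val <- o$value
  k <- length(eta)
  h <- 1e-4
  for (it in seq_len(max_iter)) {
    g <- obj$gr(eta)
    if (max(abs(g)) < 1e-10) break
    H <- matrix(0, k, k)
    for (j in seq_len(k)) {
      up <- eta; up[j] <- up[j] + h
      dn <- eta; dn[j] <- dn[j] - h
      H[, j] <- (obj$gr(up) - obj$gr(dn)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    ## backtracking in case the quadratic model overshoots
    accepted <- FALSE
    for (sc in c(1, .5, .25, .1)) {
      cand <- eta + sc * step
      cand_val <- obj$fn(cand)
      if (is.finite(cand_val) && cand_val <= val + 1e-12) {
        eta <- cand; val <- cand_val; accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  ## boundary snap
  theta <- stats::plogis(eta)
  for (j in which(theta > 1 - 1e-7 | theta < 1e-7)) {
    cand <- eta
    cand[j] <- sign(eta[j]) * 40
    cand_val <- obj$fn(cand)
    if (is.finite(cand_val) && cand_val <= val + 1e-10) {
      eta <- cand
      val <- cand_val
    }
  }
  o$par <- eta
  o$value <- val
  o
}

#' Fit an MPT model by maximum likelihood
#'
#' Minimizes the likelihood-ratio statistic
#' `G^2 = 2 * sum(n_i * log(n_i / e_i))` (equivalently, maximizes the
#' multinomial log-likelihood) over the free parameters in `[0, 1]^k`, using
#' multi-start quasi-Newton optimization on the log-odds scale with an
#' analytic gradient. Standard errors come from the inverse observed
#' information matrix of the multinomial log-likelihood at the optimum.
#'
#' @param model An [mpt_model()].
#' @param data A frequency table (see [mpt_freq()]) whose categories match
#'   the model.
#' @param n_starts Number of random starting vectors; the best solution is
#'   kept.
#' @param seed Optional integer seed for reproducible starting vectors.
#' @param start Optional named vector used as first starting value.
#' @param compute_se Compute the observed-information standard errors?
#' @return An object of class `mpt_fit`: a list with `estimates`, `se`,
#'   `vcov`, `g_squared`, `df`, `p_value`, `log_likelihood`, `n_starts`,
#'   `converged`, `start_spread` and bookkeeping fields. Methods: `print`,
#'   `summary`, `coef`, `vcov`, `logLik`, `predict`, `fitted`, `residuals`,
#'   `simulate`.
#' @examples
#' m <- mpt_model(mpt_tree(
#'   "t", c("A", "B"),
#'   list(mpt_branch("A", mpt_par("q")), mpt_branch("B", mpt_comp("q")))))
#' d <- data.frame(tree = "t", category = c("A", "B"), count = c(30, 70))
#' mpt_fit(m, d, n_starts = 2, seed = 1)
#' @export
mpt_fit <- function(model, data, n_starts = 10, seed = NULL, start = NULL,
                    compute_se = TRUE) {
  stopifnot(inherits(model, "mpt_model"))
  df <- mpt_df(model)
  aligned <- align_counts(model, data)
  obj <- make_objective(model, aligned)
  k <- length(model$roster)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  starts <- matrix(stats::runif(n_starts * k), n_starts, k)
  if (!is.null(start)) {
    th0 <- check_theta(model, start)
    starts[1L, ] <- pmin(pmax(th0, 1e-4), 1 - 1e-4)
  }
  best <- NULL
  sols <- matrix(NA_real_, n_starts, k)
  vals <- rep(NA_real_, n_starts)
  conv <- logical(n_starts)
  for (i in seq_len(n_starts)) {
    o <- tryCatch(one_start(obj, stats::qlogis(starts[i, ])),
                  error = function(e) NULL)
    if (is.null(o)) next
    sols[i, ] <- stats::plogis(o$par)
    vals[i] <- o$value
    conv[i] <- o$convergence == 0L
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    stop("all ", n_starts, " optimization starts failed", call. = FALSE)
  }
  theta <- stats::plogis(best$par)
  names(theta) <- model$roster
  g2 <- best$value
  if (g2 < 0 && g2 > -1e-8) g2 <- 0

  ## spread of solutions across starts that reached (close to) the optimum
  near <- which(is.finite(vals) & vals < min(vals, na.rm = TRUE) + 1e-6)
  spread <- if (length(near) > 1L) {
    max(apply(sols[near, , drop = FALSE], 2L,
              function(x) diff(range(x))))
  } else 0

  p <- mpt_probabilities(model, theta, flat = TRUE)
  expected <- p * aligned$Ntot
  ll <- multinomial_loglik(aligned, p)

  fit <- structure(list(
    model = model, data = mpt_freq(data), estimates = theta,
    se = rep(NA_real_, k), vcov = NULL,
    g_squared = g2, df = df,
    p_value = stats::pchisq(g2, df, lower.tail = FALSE),
    log_likelihood = ll,
    n_starts = n_starts, converged = any(conv) && best$convergence == 0L,
    start_spread = spread, start_values = vals,
    expected = expected, observed = aligned$n,
    tree_totals = aligned$tree_totals,
    boundary = theta < 1e-6 | theta > 1 - 1e-6,
    identifiable = NA), class = "mpt_fit")
  names(fit$se) <- model$roster
  if (compute_se) fit <- add_standard_errors(fit)
  fit
}

multinomial_loglik <- function(aligned, p) {
  n <- aligned$n
  tt <- aligned$tree_totals
  sum(lgamma(tt + 1)) - sum(lgamma(n + 1)) +
    sum(n[n > 0] * log(pmax(p[n > 0], 1e-300)))
}

## Score of the multinomial log-likelihood on the probability scale.
loglik_score <- function(model, aligned, theta) {
  s <- resolve_structural(model$param_map, theta)
  ev <- eval_categories_grad(model$comp, s)
  p <- pmax(ev$p, 1e-300)
  J <- map_jacobian(model$param_map, theta, model$roster)
  dp_free <- ev$dp %*% J
  pos <- aligned$n > 0
  as.vector(crossprod(dp_free[pos, , drop = FALSE],
                      aligned$n[pos] / p[pos]))
}

#' Observed-information standard errors
#'
#' Computes the observed information matrix (negative Hessian of the
#' multinomial log-likelihood, by central differences of the analytic
#' score) at the estimates of a fitted model and stores its inverse as the
#' parameter covariance matrix. Called automatically by [mpt_fit()].
#'
#' @param fit An `mpt_fit` object.
#' @return The fit with `se` and `vcov` filled in; a singular information
#'   matrix leaves `se` as `NA` and sets `identifiable = FALSE` with a
#'   warning.
#' @export
add_standard_errors <- function(fit) {
  stopifnot(inherits(fit, "mpt_fit"))
  model <- fit$model
  aligned <- align_counts(model, fit$data)
  theta <- fit$estimates
  k <- length(theta)
  H <- matrix(0, k, k)
  h <- 1e-5
  for (j in seq_len(k)) {
    up <- theta; up[j] <- min(up[j] + h, 1 - 1e-12)
    dn <- theta; dn[j] <- max(dn[j] - h, 1e-12)
    H[, j] <- (loglik_score(model, aligned, up) -
               loglik_score(model, aligned, dn)) / (up[j] - dn[j])
  }
  info <- -(H + t(H)) / 2
  V <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)) {
    warning("observed information matrix is singular or indefinite; ",
            "the model may not be identifiable at the estimates",
            call. = FALSE)
    fit$identifiable <- FALSE
    return(fit)
  }
  dimnames(V) <- list(names(theta), names(theta))
  fit$vcov <- V
  fit$se <- sqrt(diag(V))
  fit$identifiable <- TRUE
  if (any(fit$boundary)) {
    attr(fit$se, "boundary") <- names(theta)[fit$boundary]
  }
  fit
}

#' Multi-start identifiability check
#'
#' Refits the model `n_repeats` times, each from a single independent
#' uniform-random starting vector, and reports the maximum pairwise
#' distance between the resulting estimate vectors. If the likelihood has a
#' unique, well-separated maximum, all repeats land on the same estimates.
#'
#' @param model An [mpt_model()].
#' @param data A frequency table matching the model.
#' @param n_repeats Number of random starting vectors.
#' @param seed Optional integer seed.
#' @param tol Spread below which the check passes.
#' @return An object of class `mpt_ident` with elements `spread` (maximum
#'   absolute pairwise difference across repeats, over parameters), `pass`,
#'   `g2_range`, and the matrix of estimates.
#' @export
identifiability_check <- function(model, data, n_repeats = 1000,
                                  seed = NULL, tol = 1e-6) {
  stopifnot(inherits(model, "mpt_model"))
  aligned <- align_counts(model, data)
  obj <- make_objective(model, aligned)
  k <- length(model$roster)
  if (!is.null(seed)) set.seed(seed)
  est <- matrix(NA_real_, n_repeats, k,
                dimnames = list(NULL, model$roster))
  g2 <- rep(NA_real_, n_repeats)
  for (i in seq_len(n_repeats)) {
    o <- tryCatch(one_start(obj, stats::qlogis(stats::runif(k))),
                  error = function(e) NULL)
    if (is.null(o)) next
    est[i, ] <- stats::plogis(o$par)
    g2[i] <- o$value
  }
  ok <- stats::complete.cases(est)
  spread <- max(apply(est[ok, , drop = FALSE], 2L,
                      function(x) diff(range(x))))
  structure(list(spread = spread, pass = spread < tol, tol = tol,
                 n_repeats = n_repeats, n_failed = sum(!ok),
                 g2_range = range(g2, na.rm = TRUE), estimates = est),
            class = "mpt_ident")
}

#' @export
print.mpt_ident <- function(x, ...) {
  cat(sprintf(
    "Identifiability check: %d random-start fits\n  estimate spread %.3g (tolerance %.1g): %s\n  G^2 range: [%.10g, %.10g]\n",
    x$n_repeats, x$spread, x$tol, if (x$pass) "PASS" else "FAIL",
    x$g2_range[1L], x$g2_range[2L]))
  invisible(x)
}

## ---- methods -------------------------------------------------------------

#' @export
print.mpt_fit <- function(x, digits = 3, ...) {
  cat("Maximum-likelihood fit:", x$model$name, "\n")
  cat(sprintf("  G^2(%d) = %.2f, p = %.3f  (log-likelihood %.2f)\n",
              x$df, x$g_squared, x$p_value, x$log_likelihood))
  cat(sprintf("  %d starts, converged: %s, estimate spread %.2g\n",
              x$n_starts, x$converged, x$start_spread))
  est <- format(round(x$estimates, digits))
  se <- format(round(x$se, digits))
  cat("  estimates:\n")
  print(data.frame(estimate = est, se = se), ...)
  invisible(x)
}

#' @export
summary.mpt_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$estimates, se = object$se,
                    boundary = object$boundary)
  structure(list(model_name = object$model$name, table = tab,
                 g_squared = object$g_squared, df = object$df,
                 p_value = object$p_value,
                 log_likelihood = object$log_likelihood,
                 identifiable = object$identifiable),
            class = "summary.mpt_fit")
}

#' @export
print.summary.mpt_fit <- function(x, digits = 4, ...) {
  cat("Model:", x$model_name, "\n")
  cat(sprintf("Goodness of fit: G^2(%d) = %.4g, p = %.4g\n",
              x$df, x$g_squared, x$p_value))
  print(round(x$table[1:2], digits))
  if (any(x$table$boundary)) {
    cat("Note: estimates at the [0,1] boundary:",
        paste(rownames(x$table)[x$table$boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.mpt_fit <- function(object, ...) object$estimates

#' @export
vcov.mpt_fit <- function(object, ...) object$vcov

#' @export
logLik.mpt_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$estimates),
            class = "logLik")
}

#' Expected probabilities or counts of a fitted MPT model
#'
#' @param object An `mpt_fit`.
#' @param type `"counts"` for expected frequencies (tree total times
#'   category probability) or `"probabilities"`.
#' @param ... Unused.
#' @return A data frame with columns `tree`, `category` and the prediction.
#' @export
predict.mpt_fit <- function(object, type = c("counts", "probabilities"),
                            ...) {
  type <- match.arg(type)
  comp <- object$model$comp
  p <- mpt_probabilities(object$model, object$estimates, flat = TRUE)
  data.frame(tree = comp$cat_tree, category = comp$cat_name,
             value = if (type == "counts") object$expected else unname(p))
}

#' @export
fitted.mpt_fit <- function(object, ...) object$expected

#' Residuals of a fitted MPT model
#'
#' Pearson residuals `(n - e) / sqrt(e)` or deviance residuals
#' `sign(n - e) * sqrt(2 * (n * log(n / e) - (n - e)))`; the squared
#' deviance residuals sum to `G^2`.
#'
#' @param object An `mpt_fit`.
#' @param type `"pearson"` or `"deviance"`.
#' @param ... Unused.
#' @return A numeric vector, one element per category.
#' @export
residuals.mpt_fit <- function(object, type = c("pearson", "deviance"),
                              ...) {
  type <- match.arg(type)
  n <- object$observed
  e <- object$expected
  if (type == "pearson") return((n - e) / sqrt(e))
  term <- ifelse(n > 0, n * log(n / e), 0) - (n - e)
  sign(n - e) * sqrt(pmax(2 * term, 0))
}

#' Simulate frequency tables from a fitted MPT model
#'
#' @param object An `mpt_fit`.
#' @param nsim Number of simulated tables.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` frequency data frames drawn at the fitted
#'   parameter values with the observed tree totals.
#' @export
simulate.mpt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simulate_frequencies(
    object$model, object$estimates,
    n_per_tree = as.vector(object$tree_totals)), simplify = FALSE)
}
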