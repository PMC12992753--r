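#' Convert binary confidence parameters to trichotomous probabilities
#'
#' The confidence cascade is binary: the first split `x1` is the
#' probability of high confidence, the second `x2` the probability of
#' moderate confidence given not-high. The implied trichotomous
#' probabilities are `c_H = x1`, `c_M = (1 - x1) * x2`,
#' `c_L = (1 - x1) * (1 - x2)`. Standard errors are propagated by the
#' first-order delta method from a 2x2 covariance of `(x1, x2)`:
#' `SE(c_H) = SE(x1)`, and for `c_M`/`c_L` the gradients are
#' `(-x2, 1 - x1)` and `(-(1 - x2), -(1 - x1))`.
#'
#' @param x1,x2 Binary split parameters in `[0, 1]`.
#' @param covariance Optional 2x2 covariance matrix of `(x1, x2)`.
#' @return A list with `estimate` (named `low`, `moderate`, `high`,
#'   summing to 1) and `se` (all `NA` without a covariance).
#' @examples
#' binary_to_trichotomous(.5, .5)$estimate
#' @export
binary_to_trichotomous <- function(x1, x2, covariance = NULL) {
  stopifnot(is.numeric(x1), is.numeric(x2), length(x1) == 1L,
            length(x2) == 1L)
  if (x1 < 0 || x1 > 1 || x2 < 0 || x2 > 1) {
    stop("binary confidence parameters must lie in [0, 1]", call. = FALSE)
  }
  est <- c(low = (1 - x1) * (1 - x2), moderate = (1 - x1) * x2, high = x1)
  se <- c(low = NA_real_, moderate = NA_real_, high = NA_real_)
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    stopifnot(all(dim(covariance) == c(2L, 2L)))
    ev <- eigen((covariance + t(covariance)) / 2, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      warning("covariance matrix is not positive semidefinite; ",
              "delta-method standard errors may be unreliable",
              call. = FALSE)
    }
    grads <- list(low = c(-(1 - x2), -(1 - x1)),
                  moderate = c(-x2, 1 - x1),
                  high = c(1, 0))
    se <- vapply(grads, function(g) {
      v <- as.numeric(t(g) %*% covariance %*% g)
      sqrt(max(v, 0))
    }, numeric(1))
  }
  list(estimate = est, se = se)
}

#' Convert trichotomous confidence probabilities to binary parameters
#'
#' Inverse of [binary_to_trichotomous()]: `x1 = c_H`,
#' `x2 = c_M / (1 - c_H)`. When `c_H = 1` the second split is undefined
#' and returned as 0 with attribute `undefined_x2 = TRUE`.
#'
#' @param c_l,c_m,c_h Probabilities of low, moderate and high confidence;
#'   must sum to 1.
#' @return Named vector `c(x1, x2)`.
#' @export
trichotomous_to_binary <- function(c_l, c_m, c_h) {
  vals <- c(c_l, c_m, c_h)
  if (any(vals < -1e-12) || abs(sum(vals) - 1) > 1e-8) {
    stop("confidence probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (c_h >= 1 - 1e-15) {
    out <- c(x1 = 1, x2 = 0)
    attr(out, "undefined_x2") <- TRUE
    return(out)
  }
  c(x1 = c_h, x2 = c_m / (1 - c_h))
}

#' Confidence profiles of a fitted lineup confidence model
#'
#' Transforms the fitted binary confidence parameters of every latent
#' process and condition into probabilities of low, moderate and high
#' confidence with delta-method standard errors. Works for the base model
#' and for the shrinkage reparameterization (the covariance is propagated
#' through the parameter map).
#'
#' @param fit An `mpt_fit` of a model built by
#'   [lineup_confidence_model()] (or a constrained version of one).
#' @return A data frame of class `lineup_confidence_profiles` with columns
#'   `condition`, `process`, `level`, `estimate`, `se`.
#' @export
confidence_profiles <- function(fit) {
  stopifnot(inherits(fit, "mpt_fit"))
  model <- fit$model
  conditions <- if (!is.null(model$design)) model$design$conditions else
    stop("the fitted model does not carry a lineup design", call. = FALSE)
  theta <- fit$estimates
  sv <- resolve_structural(model$param_map, theta)
  J <- map_jacobian(model$param_map, theta, model$roster)
  SV <- if (!is.null(fit$vcov)) J %*% fit$vcov %*% t(J) else NULL
  if (!is.null(SV)) dimnames(SV) <- list(names(model$param_map),
                                         names(model$param_map))
  procs <- c(d = "detection", b = "biased selection",
             g = "guessing-based selection",
             gr = "guessing-based rejection")
  out <- NULL
  for (cond in conditions) {
    for (p in names(procs)) {
      nm <- c(conf_par(cond, p, 1L), conf_par(cond, p, 2L))
      if (!all(nm %in% names(model$param_map))) next
      cv <- if (!is.null(SV)) SV[nm, nm] else NULL
      tri <- binary_to_trichotomous(sv[[nm[1L]]], sv[[nm[2L]]], cv)
      out <- rbind(out, data.frame(
        condition = cond, process = procs[[p]],
        level = c("low", "moderate", "high"),
        estimate = unname(tri$estimate), se = unname(tri$se)))
    }
  }
  structure(out, class = c("lineup_confidence_profiles", "data.frame"))
}

#' Plot confidence profiles
#'
#' Grouped bar chart of the low/moderate/high confidence probabilities,
#' one panel per latent process, bars grouped by condition.
#'
#' @param x A [confidence_profiles()] result.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.lineup_confidence_profiles <- function(x, ...) {
  procs <- unique(x$process)
  conditions <- unique(x$condition)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(procs)),
                      mar = c(3.5, 4, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (p in procs) {
    sub <- x[x$process == p, ]
    m <- matrix(sub$estimate, nrow = length(conditions), byrow = TRUE,
                dimnames = list(conditions, c("low", "moderate", "high")))
    bp <- graphics::barplot(m, beside = TRUE, ylim = c(0, 1), main = p,
                            ylab = "probability",
                            legend.text = p == procs[1L], ...)
    se <- matrix(sub$se, nrow = length(conditions), byrow = TRUE)
    if (all(is.finite(se))) {
      graphics::arrows(bp, m - se, bp, m + se, angle = 90, code = 3,
                       length = 0.03)
    }
  }
  invisible(x)
}
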