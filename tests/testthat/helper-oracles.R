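## Independent closed-form oracles for the built-in lineup models, typed
## directly from the tree diagrams (no shared code with the package's
## compiled evaluator).

## 2HT response probabilities for one condition; returns the category
## probabilities of both trees in the builders' labelling.
oracle_2ht <- function(dP, dA, b, g, k, pfx = "study") {
  cp <- c(suspect = dP + (1 - dP) * b + (1 - dP) * (1 - b) * g * k,
          filler  = (1 - dP) * (1 - b) * g * (1 - k),
          reject  = (1 - dP) * (1 - b) * (1 - g))
  ca <- c(suspect = (1 - dA) * b + (1 - dA) * (1 - b) * g * k,
          filler  = (1 - dA) * (1 - b) * g * (1 - k),
          reject  = dA + (1 - dA) * (1 - b) * (1 - g))
  names(cp) <- paste0(pfx, ".CP.", names(cp))
  names(ca) <- paste0(pfx, ".CA.", names(ca))
  list(CP = cp, CA = ca)
}

## confidence model probabilities for one condition; conf is a list of
## (x1, x2) per process d/b/g/gr, high-first binary cascade.
oracle_confidence <- function(dP, dA, b, g, k, conf, pfx = "study") {
  tri <- function(x) c(L = (1 - x[1]) * (1 - x[2]),
                       M = (1 - x[1]) * x[2], H = x[1])
  td <- tri(conf$d); tb <- tri(conf$b); tg <- tri(conf$g)
  tgr <- tri(conf$gr)
  cp <- c(dP * td + (1 - dP) * b * tb + (1 - dP) * (1 - b) * g * k * tg,
          (1 - dP) * (1 - b) * g * (1 - k) * tg,
          (1 - dP) * (1 - b) * (1 - g) * tgr)
  ca <- c((1 - dA) * b * tb + (1 - dA) * (1 - b) * g * k * tg,
          (1 - dA) * (1 - b) * g * (1 - k) * tg,
          dA * td + (1 - dA) * (1 - b) * (1 - g) * tgr)
  lev <- c("L", "M", "H")
  nm <- as.vector(t(outer(c("suspect", "filler", "reject"), lev, paste,
                          sep = ".")))
  names(cp) <- paste0(pfx, ".CP.", nm)
  names(ca) <- paste0(pfx, ".CA.", nm)
  list(CP = cp, CA = ca)
}

## Oracle for the two-condition models in the builders' parameter naming.
oracle_model_probs <- function(model, theta) {
  design <- model$design
  k <- design$k
  out <- list()
  confidence <- any(grepl("c_d1", names(theta), fixed = TRUE))
  for (cond in design$conditions) {
    pick <- function(base) {
      nm <- paste0(cond, ".", base)
      if (nm %in% names(theta)) theta[[nm]] else theta[[base]]
    }
    if (confidence) {
      conf <- lapply(c(d = "d", b = "b", g = "g", gr = "gr"), function(p) {
        c(pick(paste0("c_", p, "1")), pick(paste0("c_", p, "2")))
      })
      pr <- oracle_confidence(pick("dP"), pick("dA"), pick("b"), pick("g"),
                              k, conf, pfx = cond)
    } else {
      pr <- oracle_2ht(pick("dP"), pick("dA"), pick("b"), pick("g"), k,
                       pfx = cond)
    }
    out[[paste0(cond, ".CP")]] <- pr$CP
    out[[paste0(cond, ".CA")]] <- pr$CA
  }
  out
}

## A deliberately non-identifiable model: q and r enter every branch only
## through their product, so the likelihood has a ridge along q * r = const.
nonidentifiable_model <- function() {
  mpt_model(mpt_tree("t", c("A", "B", "C"),
                     list(mpt_branch("A", mpt_par("q"), mpt_par("r"),
                                     mpt_const(.5)),
                          mpt_branch("B", mpt_par("q"), mpt_par("r"),
                                     mpt_const(.5)),
                          mpt_branch("C", mpt_comp("q")),
                          mpt_branch("C", mpt_par("q"), mpt_comp("r")))),
            name = "product ridge")
}

rand_theta <- function(model) {
  th <- stats::runif(n_free_parameters(model))
  names(th) <- free_parameters(model)
  th
}

## The estimates of the base model fitted to the bundled feedback-study
## counts (computed once per test run, shared across expensive tests).
feedback_fit_cache <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      fit <<- mpt_fit(lineup_base_model(), lineup_feedback_counts(),
                      n_starts = 10, seed = 42)
    }
    fit
  }
})
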