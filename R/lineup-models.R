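#' Lineup design
#'
#' Describes the experimental design the lineup models are built for: the
#' nominal lineup size (one suspect plus fillers), the experimental
#' conditions, and whether the biased-suspect-selection parameter `b` and
#' the culprit-absence-detection parameter `dA` are shared across
#' conditions (the usual assumption: both reflect properties of the lineup
#' materials rather than of the witness's state).
#'
#' When guessing-based selection occurs, the suspect is chosen with
#' probability `1/lineup_size`. By convention this constant is stored as the
#' 5-decimal approximation (`.16667` for a six-person lineup); set
#' `exact_fraction = TRUE` for the exact rational value.
#'
#' @param lineup_size Integer `>= 2`; number of lineup members.
#' @param conditions Character vector of condition labels (at least one).
#' @param share_b,share_dA Share `b` / `dA` across conditions?
#' @param exact_fraction Use exact `1/lineup_size` instead of the rounded
#'   decimal.
#' @return An object of class `lineup_design`.
#' @export
lineup_design <- function(lineup_size = 6,
                          conditions = c("negative", "positive"),
                          share_b = TRUE, share_dA = TRUE,
                          exact_fraction = FALSE) {
  if (!is.numeric(lineup_size) || length(lineup_size) != 1L ||
      lineup_size < 2 || lineup_size != round(lineup_size)) {
    stop("'lineup_size' must be an integer >= 2", call. = FALSE)
  }
  stopifnot(is.character(conditions), length(conditions) >= 1L,
            anyDuplicated(conditions) == 0L)
  k <- if (exact_fraction) 1 / lineup_size else round(1 / lineup_size, 5)
  structure(list(lineup_size = as.integer(lineup_size),
                 conditions = conditions,
                 share_b = isTRUE(share_b), share_dA = isTRUE(share_dA),
                 k = k), class = "lineup_design")
}

## 2HT branch skeletons for one condition. Each element: category suffix,
## factor list, and the latent process feeding the terminal (used by the
## confidence extension).
ht2_branches <- function(pfx, tree, k) {
  P <- function(n) mpt_par(paste0(pfx, n))
  C <- function(n) mpt_comp(paste0(pfx, n))
  if (tree == "CP") {
    list(
      list(cat = "suspect", f = list(P("dP")), proc = "d"),
      list(cat = "suspect", f = list(C("dP"), P("b")), proc = "b"),
      list(cat = "suspect", f = list(C("dP"), C("b"), P("g"),
                                     mpt_const(k)), proc = "g"),
      list(cat = "filler",  f = list(C("dP"), C("b"), P("g"),
                                     mpt_const(1 - k)), proc = "g"),
      list(cat = "reject",  f = list(C("dP"), C("b"), C("g")), proc = "gr"))
  } else {
    list(
      list(cat = "reject",  f = list(P("dA")), proc = "d"),
      list(cat = "suspect", f = list(C("dA"), P("b")), proc = "b"),
      list(cat = "suspect", f = list(C("dA"), C("b"), P("g"),
                                     mpt_const(k)), proc = "g"),
      list(cat = "filler",  f = list(C("dA"), C("b"), P("g"),
                                     mpt_const(1 - k)), proc = "g"),
      list(cat = "reject",  f = list(C("dA"), C("b"), C("g")), proc = "gr"))
  }
}

shared_constraints <- function(design) {
  eq <- list()
  if (length(design$conditions) > 1L) {
    if (design$share_b) {
      eq$b <- paste0(design$conditions, ".b")
    }
    if (design$share_dA) {
      eq$dA <- paste0(design$conditions, ".dA")
    }
  }
  eq
}

#' The two-high-threshold eyewitness identification model
#'
#' Builds the 2HT lineup model: per condition, a culprit-present tree with
#' categories suspect (culprit) identification, filler identification and
#' rejection, and a culprit-absent tree with suspect (innocent)
#' identification, filler identification and rejection. Latent processes are
#' culprit-presence detection `dP`, culprit-absence detection `dA`, biased
#' suspect selection `b` and guessing-based selection `g`; guessing picks
#' the suspect with probability `1/lineup_size`. Parameters are prefixed by
#' condition (`negative.dP`, ...); shared `b`/`dA` appear unprefixed.
#'
#' @param design A [lineup_design()].
#' @return An [mpt_model()] with trees named `<condition>.CP` and
#'   `<condition>.CA` and categories
#'   `<condition>.<CP|CA>.<suspect|filler|reject>`.
#' @examples
#' m <- lineup_2ht_model(lineup_design(conditions = "study"))
#' mpt_probabilities(m, c(study.dP = .3, study.dA = .2, study.b = .05,
#'                        study.g = .5))
#' @export
lineup_2ht_model <- function(design = lineup_design()) {
  stopifnot(inherits(design, "lineup_design"))
  trees <- list()
  for (cond in design$conditions) {
    pfx <- paste0(cond, ".")
    for (tt in c("CP", "CA")) {
      cats <- paste0(pfx, tt, ".", c("suspect", "filler", "reject"))
      br <- lapply(ht2_branches(pfx, tt, design$k), function(b) {
        mpt_branch(paste0(pfx, tt, ".", b$cat), b$f)
      })
      trees <- c(trees, list(mpt_tree(paste0(pfx, tt), cats, br)))
    }
  }
  m <- mpt_model(trees, name = "2HT eyewitness identification model")
  eq <- shared_constraints(design)
  if (length(eq)) m <- apply_constraints(m, mpt_constraints(equalities = eq))
  m$name <- "2HT eyewitness identification model"
  m$design <- design
  m
}

#' The lineup confidence model
#'
#' Extends [lineup_2ht_model()] so that every lineup response carries a
#' low/moderate/high confidence rating whose distribution depends on the
#' latent process that produced the response. Each 2HT terminal branch is
#' split by a binary confidence cascade: the first split parameter is the
#' probability of *high* confidence, the second the probability of
#' *moderate* given not-high, so that
#' `c_H = x1`, `c_M = (1 - x1) * x2`, `c_L = (1 - x1) * (1 - x2)`.
#'
#' Four confidence blocks exist per condition, one per process: detection
#' (`c_d1`, `c_d2`; shared between culprit-presence and culprit-absence
#' detection), biased suspect selection (`c_b1`, `c_b2`), guessing-based
#' selection (`c_g1`, `c_g2`) and guessing-based rejection (`c_gr1`,
#' `c_gr2`). Because a witness who fails to detect cannot distinguish
#' culprit-present from culprit-absent lineups, the non-detection blocks are
#' shared between the two trees of a condition.
#'
#' @param design A [lineup_design()].
#' @return An [mpt_model()] with 9 categories per tree, named
#'   `<condition>.<CP|CA>.<response>.<L|M|H>`.
#' @export
lineup_confidence_model <- function(design = lineup_design()) {
  stopifnot(inherits(design, "lineup_design"))
  lev <- c("L", "M", "H")
  trees <- list()
  for (cond in design$conditions) {
    pfx <- paste0(cond, ".")
    conf_split <- function(proc) {
      x1 <- paste0(pfx, "c_", proc, "1")
      x2 <- paste0(pfx, "c_", proc, "2")
      list(H = list(mpt_par(x1)),
           M = list(mpt_comp(x1), mpt_par(x2)),
           L = list(mpt_comp(x1), mpt_comp(x2)))
    }
    for (tt in c("CP", "CA")) {
      resp <- c("suspect", "filler", "reject")
      cats <- as.vector(t(outer(resp, lev,
                                function(r, l) paste0(pfx, tt, ".", r, ".", l))))
      br <- list()
      for (b in ht2_branches(pfx, tt, design$k)) {
        split <- conf_split(b$proc)
        for (l in lev) {
          br <- c(br, list(mpt_branch(paste0(pfx, tt, ".", b$cat, ".", l),
                                      c(b$f, split[[l]]))))
        }
      }
      trees <- c(trees, list(mpt_tree(paste0(pfx, tt), cats, br)))
    }
  }
  m <- mpt_model(trees, name = "lineup confidence model")
  eq <- shared_constraints(design)
  if (length(eq)) m <- apply_constraints(m, mpt_constraints(equalities = eq))
  m$name <- "lineup confidence model"
  m$design <- design
  m
}

#' The two-condition base model of the feedback study
#'
#' Convenience wrapper: [lineup_confidence_model()] at the default
#' [lineup_design()] — a six-person lineup, conditions `negative` and
#' `positive` (post-response feedback), `b` and `dA` shared across
#' conditions. Four trees of 9 categories each (32 independent), 22 free
#' parameters, 10 degrees of freedom. The category labels match the bundled
#' [lineup_feedback_counts()] fixture.
#'
#' @return An [mpt_model()].
#' @examples
#' m <- lineup_base_model()
#' n_free_parameters(m)  # 22
#' mpt_df(m)             # 10
#' @export
lineup_base_model <- function() {
  lineup_confidence_model(lineup_design())
}
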