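#' Branch factors
#'
#' An MPT branch is a product of factors. Each factor is either a process
#' parameter `p`, the complement `1 - p` of a process parameter, or a fixed
#' constant in `[0, 1]` (such as the probability `1/lineup size` of landing
#' on the suspect when guessing).
#'
#' @param ref Parameter name (a non-empty string).
#' @param value Constant value in `[0, 1]`.
#' @return A factor object, for use inside [mpt_branch()].
#' @seealso [mpt_branch()], [mpt_tree()], [mpt_model()]
#' @export
mpt_par <- function(ref) {
  stopifnot(is.character(ref), length(ref) == 1L, nzchar(ref))
  structure(list(kind = "par", ref = ref), class = "mpt_factor")
}

#' @rdname mpt_par
#' @export
mpt_comp <- function(ref) {
  stopifnot(is.character(ref), length(ref) == 1L, nzchar(ref))
  structure(list(kind = "comp", ref = ref), class = "mpt_factor")
}

#' @rdname mpt_par
#' @export
mpt_const <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    stop("constant factors must be single values in [0, 1]", call. = FALSE)
  }
  structure(list(kind = "const", value = as.numeric(value)),
            class = "mpt_factor")
}

#' Construct an MPT branch
#'
#' @param category Category label the branch terminates in.
#' @param ... Factors created with [mpt_par()], [mpt_comp()] or
#'   [mpt_const()], multiplied left to right.
#' @return A branch object.
#' @export
mpt_branch <- function(category, ...) {
  factors <- list(...)
  if (length(factors) == 1L && is.list(factors[[1L]]) &&
      !inherits(factors[[1L]], "mpt_factor")) {
    factors <- factors[[1L]]
  }
  if (length(factors) == 0L) stop("a branch needs at least one factor",
                                  call. = FALSE)
  ok <- vapply(factors, inherits, logical(1), what = "mpt_factor")
  if (!all(ok)) stop("branch factors must be mpt_par/mpt_comp/mpt_const",
                     call. = FALSE)
  stopifnot(is.character(category), length(category) == 1L)
  structure(list(category = category, factors = factors),
            class = "mpt_branch")
}

#' Construct an MPT tree
#'
#' A tree is one multinomial: an ordered set of response categories and the
#' branches (products of process probabilities) that feed them.
#'
#' @param name Tree label (unique within a model).
#' @param categories Ordered character vector of category labels.
#' @param branches List of [mpt_branch()] objects. Every category must
#'   receive at least one branch.
#' @return A tree object.
#' @export
mpt_tree <- function(name, categories, branches) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(categories), length(categories) >= 2L,
            anyDuplicated(categories) == 0L, is.list(branches))
  ok <- vapply(branches, inherits, logical(1), what = "mpt_branch")
  if (!all(ok)) stop("branches must be mpt_branch objects", call. = FALSE)
  cats_used <- vapply(branches, `[[`, character(1), "category")
  bad <- setdiff(cats_used, categories)
  if (length(bad)) {
    stop("branch categories not in category list: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(categories, cats_used)
  if (length(missing)) {
    stop("categories without branches: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, categories = categories, branches = branches),
            class = "mpt_tree")
}

## Collect structural parameter names in order of first appearance.
structural_names <- function(trees) {
  out <- character(0)
  for (tr in trees) for (br in tr$branches) for (f in br$factors) {
    if (f$kind != "const" && !(f$ref %in% out)) out <- c(out, f$ref)
  }
  out
}

## Compile trees into exponent matrices for fast evaluation:
## branch value = cb * prod_j s_j^A_ij * (1 - s_j)^B_ij over structural
## parameters s.
compile_trees <- function(trees) {
  struct <- structural_names(trees)
  ns <- length(struct)
  nb <- sum(vapply(trees, function(tr) length(tr$branches), integer(1)))
  A <- matrix(0, nb, ns, dimnames = list(NULL, struct))
  B <- matrix(0, nb, ns, dimnames = list(NULL, struct))
  cb <- rep(1, nb)
  cat_tree <- character(0)
  cat_name <- character(0)
  for (tr in trees) {
    cat_tree <- c(cat_tree, rep(tr$name, length(tr$categories)))
    cat_name <- c(cat_name, tr$categories)
  }
  cat_key <- paste(cat_tree, cat_name, sep = "\r")
  cat_of_branch <- integer(nb)
  i <- 0L
  for (tr in trees) {
    for (br in tr$branches) {
      i <- i + 1L
      cat_of_branch[i] <- match(paste(tr$name, br$category, sep = "\r"),
                                cat_key)
      for (f in br$factors) {
        if (f$kind == "par") A[i, f$ref] <- A[i, f$ref] + 1
        else if (f$kind == "comp") B[i, f$ref] <- B[i, f$ref] + 1
        else cb[i] <- cb[i] * f$value
      }
    }
  }
  ncat <- length(cat_key)
  Cmat <- matrix(0, ncat, nb)
  Cmat[cbind(cat_of_branch, seq_len(nb))] <- 1
  list(struct = struct, A = A, B = B, cb = cb, Cmat = Cmat,
       cat_tree = cat_tree, cat_name = cat_name,
       tree_names = vapply(trees, `[[`, character(1), "name"),
       tree_ncat = vapply(trees, function(tr) length(tr$categories),
                          integer(1)))
}

## ---- parameter map -------------------------------------------------------
## Structural parameters (the symbols appearing in the trees) are linked to
## free parameters through a map. Entries:
##   list(kind = "free",  name  = <free parameter name>)
##   list(kind = "const", value = <fixed probability>)
##   list(kind = "prod",  f = c(<free name>, <free name>))   # shrinkage
identity_map <- function(struct) {
  m <- lapply(struct, function(s) list(kind = "free", name = s))
  names(m) <- struct
  m
}

roster_from_map <- function(map) {
  out <- character(0)
  for (m in map) {
    nm <- switch(m$kind, free = m$name, prod = m$f, const = character(0))
    for (n in nm) if (!(n %in% out)) out <- c(out, n)
  }
  out
}

resolve_structural <- function(map, theta) {
  vapply(map, function(m) {
    switch(m$kind,
           free  = theta[[m$name]],
           const = m$value,
           prod  = theta[[m$f[1L]]] * theta[[m$f[2L]]])
  }, numeric(1))
}

## Jacobian d structural / d free, evaluated at theta.
map_jacobian <- function(map, theta, roster) {
  J <- matrix(0, length(map), length(roster),
              dimnames = list(names(map), roster))
  for (i in seq_along(map)) {
    m <- map[[i]]
    if (m$kind == "free") {
      J[i, m$name] <- 1
    } else if (m$kind == "prod") {
      J[i, m$f[1L]] <- J[i, m$f[1L]] + theta[[m$f[2L]]]
      J[i, m$f[2L]] <- J[i, m$f[2L]] + theta[[m$f[1L]]]
    }
  }
  J
}

#' Construct an MPT model
#'
#' Bundles one or more [mpt_tree()]s (one multinomial each) into a model.
#' Category probabilities are sums over branches of products of process
#' probabilities. Parameters with the same name are shared wherever they
#' appear; further equality, fixing and shrinkage constraints can be imposed
#' with [apply_constraints()].
#'
#' @param trees A list of [mpt_tree()] objects (or a single tree).
#' @param name Optional model label, used by the print method.
#' @return An object of class `mpt_model` with elements `trees`, `param_map`
#'   and the derived `roster` of free parameter names.
#' @examples
#' m <- mpt_model(mpt_tree(
#'   "study", c("A", "B"),
#'   list(mpt_branch("A", mpt_par("q")), mpt_branch("B", mpt_comp("q")))))
#' mpt_probabilities(m, c(q = 0.3))
#' @export
mpt_model <- function(trees, name = "mpt model") {
  if (inherits(trees, "mpt_tree")) trees <- list(trees)
  ok <- vapply(trees, inherits, logical(1), what = "mpt_tree")
  if (!length(trees) || !all(ok)) {
    stop("'trees' must be a list of mpt_tree objects", call. = FALSE)
  }
  tn <- vapply(trees, `[[`, character(1), "name")
  if (anyDuplicated(tn)) stop("tree names must be unique", call. = FALSE)
  comp <- compile_trees(trees)
  map <- identity_map(comp$struct)
  new_mpt_model(trees, map, comp, name)
}

new_mpt_model <- function(trees, map, comp = NULL, name = "mpt model") {
  if (is.null(comp)) comp <- compile_trees(trees)
  structure(list(name = name, trees = trees, param_map = map, comp = comp,
                 roster = roster_from_map(map)),
            class = "mpt_model")
}

#' Free parameters and degrees of freedom
#'
#' `free_parameters()` returns the roster of free parameter names after all
#' constraints; `n_free_parameters()` its length. `mpt_df()` returns the
#' degrees of freedom of the goodness-of-fit test,
#' `sum(categories - 1) - n_free`, and throws an error for over-parameterized
#' models (negative df).
#'
#' @param model An [mpt_model()].
#' @return A character vector, an integer, and an integer respectively.
#' @export
free_parameters <- function(model) {
  stopifnot(inherits(model, "mpt_model"))
  model$roster
}

#' @rdname free_parameters
#' @export
n_free_parameters <- function(model) length(free_parameters(model))

#' @rdname free_parameters
#' @export
mpt_df <- function(model) {
  stopifnot(inherits(model, "mpt_model"))
  df <- sum(model$comp$tree_ncat - 1L) - n_free_parameters(model)
  if (df < 0L) {
    stop("model is over-parameterized: ", n_free_parameters(model),
         " free parameters but only ", sum(model$comp$tree_ncat - 1L),
         " independent categories", call. = FALSE)
  }
  as.integer(df)
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("MPT model:", x$name, "\n")
  cat(sprintf("  %d tree(s), %d categories, %d free parameter(s)\n",
              length(x$trees), length(x$comp$cat_name),
              n_free_parameters(x)))
  df <- sum(x$comp$tree_ncat - 1L) - n_free_parameters(x)
  cat("  goodness-of-fit df:", df, if (df < 0L) " (over-parameterized!)",
      "\n", sep = "")
  cat("  parameters:", paste(x$roster, collapse = ", "), "\n")
  invisible(x)
}

check_theta <- function(model, theta) {
  if (is.null(names(theta))) {
    stop("'theta' must be a named vector covering the free parameters",
         call. = FALSE)
  }
  missing <- setdiff(model$roster, names(theta))
  if (length(missing)) {
    stop("missing parameter value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  th <- theta[model$roster]
  if (any(!is.finite(th)) || any(th < 0) || any(th > 1)) {
    bad <- model$roster[!is.finite(th) | th < 0 | th > 1]
    stop("parameter value(s) outside [0, 1]: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  th
}

## Boundary-safe branch/category evaluation (0^0 == 1 in R, so exact 0 and 1
## parameter values are handled without clamping).
eval_categories_safe <- function(comp, s) {
  nb <- nrow(comp$A)
  S <- matrix(s, nb, length(s), byrow = TRUE)
  V <- log(S^comp$A) + log((1 - S)^comp$B)
  branch <- comp$cb * exp(rowSums(V))
  as.vector(comp$Cmat %*% branch)
}

## Fast interior evaluation with gradient with respect to the structural
## parameters; used by the optimizer.
eval_categories_grad <- function(comp, s) {
  s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  lb <- comp$A %*% log(s) + comp$B %*% log1p(-s)
  branch <- comp$cb * exp(as.vector(lb))
  G <- sweep(comp$A, 2L, s, "/") - sweep(comp$B, 2L, 1 - s, "/")
  D <- branch * G
  list(p = as.vector(comp$Cmat %*% branch), dp = comp$Cmat %*% D)
}

#' Category probabilities of an MPT model
#'
#' Evaluates, for every tree, the probability of each response category as
#' the sum over branches of the product of the branch's factors. Within each
#' tree the probabilities sum to one for any admissible parameter vector.
#'
#' @param model An [mpt_model()].
#' @param theta Named numeric vector of free parameter values in `[0, 1]`,
#'   covering [free_parameters()] of the model.
#' @param flat If `TRUE`, return one named vector across all trees instead
#'   of a per-tree list.
#' @return A named list with one probability vector per tree (or a flat
#'   vector).
#' @export
mpt_probabilities <- function(model, theta, flat = FALSE) {
  stopifnot(inherits(model, "mpt_model"))
  th <- check_theta(model, theta)
  s <- resolve_structural(model$param_map, th)
  p <- eval_categories_safe(model$comp, s)
  if (flat) {
    names(p) <- paste(model$comp$cat_tree, model$comp$cat_name, sep = ".")
    return(p)
  }
  split_p <- split(p, factor(model$comp$cat_tree,
                             levels = model$comp$tree_names))
  for (tn in names(split_p)) {
    names(split_p[[tn]]) <-
      model$comp$cat_name[model$comp$cat_tree == tn]
  }
  split_p
}
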