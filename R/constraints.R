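#' Parameter constraints for MPT models
#'
#' Builds a constraint set for [apply_constraints()]. Three kinds are
#' supported:
#'
#' * **equalities** — sets of free parameters forced to a common value. Each
#'   element is a character vector of parameter names; if the element is
#'   named, that name becomes the merged parameter's name, otherwise the
#'   first member does. Reduces the free-parameter count.
#' * **fixings** — a named numeric vector fixing parameters to constants in
#'   `[0, 1]`. Reduces the free-parameter count.
#' * **shrinkages** — order constraints `target = shrinkage * reference`
#'   created with [mpt_shrinkage()]. The target parameter is removed and the
#'   shrinkage parameter (in `[0, 1]`) added, so the free-parameter count is
#'   unchanged while `target <= reference` is enforced.
#'
#' @param equalities List of character vectors of parameter names.
#' @param fixings Named numeric vector of constants in `[0, 1]`.
#' @param shrinkages List of [mpt_shrinkage()] objects.
#' @return An object of class `mpt_constraints`.
#' @export
mpt_constraints <- function(equalities = list(), fixings = numeric(0),
                            shrinkages = list()) {
  if (is.character(equalities)) equalities <- list(equalities)
  stopifnot(is.list(equalities), is.numeric(fixings), is.list(shrinkages))
  if (length(shrinkages) && inherits(shrinkages[[1L]], "character")) {
    stop("shrinkages must be built with mpt_shrinkage()", call. = FALSE)
  }
  if (length(fixings)) {
    if (is.null(names(fixings)) || any(!nzchar(names(fixings)))) {
      stop("'fixings' must be a named numeric vector", call. = FALSE)
    }
    if (any(fixings < 0 | fixings > 1)) {
      stop("fixed values must lie in [0, 1]", call. = FALSE)
    }
  }
  touched <- c(unlist(equalities, use.names = FALSE), names(fixings),
               vapply(shrinkages, `[[`, character(1), "target"))
  if (anyDuplicated(touched)) {
    stop("a parameter may appear in at most one constraint: ",
         paste(unique(touched[duplicated(touched)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(equalities = equalities, fixings = fixings,
                 shrinkages = shrinkages), class = "mpt_constraints")
}

#' @rdname mpt_constraints
#' @param target Free parameter to re-express (removed from the roster).
#' @param reference Free parameter the target is shrunk towards.
#' @param name Name of the new shrinkage parameter.
#' @export
mpt_shrinkage <- function(target, reference, name) {
  stopifnot(is.character(target), is.character(reference),
            is.character(name), length(target) == 1L,
            length(reference) == 1L, length(name) == 1L)
  if (target == reference || name == reference || name == target) {
    stop("target, reference and shrinkage name must be distinct",
         call. = FALSE)
  }
  list(target = target, reference = reference, name = name)
}

## Rename free parameters inside a map (used by equality constraints).
rename_free <- function(map, from, to) {
  for (i in seq_along(map)) {
    m <- map[[i]]
    if (m$kind == "free" && m$name %in% from) map[[i]]$name <- to
    if (m$kind == "prod") {
      m$f[m$f %in% from] <- to
      if (m$f[1L] == m$f[2L]) {
        stop("equality constraint would square a shrinkage product",
             call. = FALSE)
      }
      map[[i]]$f <- m$f
    }
  }
  map
}

#' Apply constraints to an MPT model
#'
#' Returns a new model whose category probabilities equal those of the
#' original model at the induced parameter values. Equalities and fixings
#' reduce the free-parameter count; shrinkage reparameterizations preserve
#' it (the target leaves the roster, the shrinkage parameter enters).
#'
#' @param model An [mpt_model()].
#' @param constraints An [mpt_constraints()] object, or arguments to build
#'   one.
#' @param ... Passed to [mpt_constraints()] when `constraints` is missing.
#' @return A constrained [mpt_model()].
#' @examples
#' m <- lineup_2ht_model(lineup_design(conditions = "study"))
#' apply_constraints(m, fixings = c(study.g = 0))
#' @export
apply_constraints <- function(model, constraints = NULL, ...) {
  stopifnot(inherits(model, "mpt_model"))
  if (is.null(constraints)) constraints <- mpt_constraints(...)
  if (!inherits(constraints, "mpt_constraints")) {
    stop("'constraints' must be an mpt_constraints object", call. = FALSE)
  }
  map <- model$param_map
  roster <- roster_from_map(map)

  all_refs <- c(unlist(constraints$equalities, use.names = FALSE),
                names(constraints$fixings),
                unlist(lapply(constraints$shrinkages,
                              function(s) c(s$target, s$reference))))
  unknown <- setdiff(all_refs, roster)
  if (length(unknown)) {
    stop("constraint references unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  for (i in seq_along(constraints$equalities)) {
    set <- constraints$equalities[[i]]
    if (length(set) < 2L) stop("an equality set needs >= 2 parameters",
                               call. = FALSE)
    canonical <- names(constraints$equalities)[i]
    if (is.null(canonical) || !nzchar(canonical)) canonical <- set[1L]
    map <- rename_free(map, set, canonical)
  }

  for (nm in names(constraints$fixings)) {
    val <- constraints$fixings[[nm]]
    in_prod <- any(vapply(map, function(m) m$kind == "prod" && nm %in% m$f,
                          logical(1)))
    if (in_prod) {
      stop("cannot fix parameter involved in a shrinkage product: ", nm,
           call. = FALSE)
    }
    for (i in seq_along(map)) {
      if (map[[i]]$kind == "free" && map[[i]]$name == nm) {
        map[[i]] <- list(kind = "const", value = val)
      }
    }
  }

  shrunk_targets <- character(0)
  for (s in constraints$shrinkages) {
    cur <- roster_from_map(map)
    if (!(s$target %in% cur) || !(s$reference %in% cur)) {
      stop("shrinkage references resolved away by earlier constraints: ",
           s$target, " <- ", s$name, " * ", s$reference, call. = FALSE)
    }
    if (s$name %in% cur) {
      stop("shrinkage parameter name already in use: ", s$name,
           call. = FALSE)
    }
    ref_is_plain <- all(vapply(map, function(m) {
      !(m$kind == "prod" && s$reference == m$f[1L])
    }, logical(1))) && !(s$reference %in% shrunk_targets)
    if (!ref_is_plain || s$reference %in%
        vapply(constraints$shrinkages, `[[`, character(1), "name")) {
      stop("cyclic or chained shrinkage reference: ", s$reference,
           call. = FALSE)
    }
    replaced <- FALSE
    for (i in seq_along(map)) {
      m <- map[[i]]
      if (m$kind == "free" && m$name == s$target) {
        map[[i]] <- list(kind = "prod", f = c(s$name, s$reference))
        replaced <- TRUE
      } else if (m$kind == "prod" && s$target %in% m$f) {
        stop("shrinkage target is already part of a product: ", s$target,
             call. = FALSE)
      }
    }
    if (!replaced) stop("shrinkage target not free: ", s$target,
                        call. = FALSE)
    shrunk_targets <- c(shrunk_targets, s$target)
  }

  new_mpt_model(model$trees, map, model$comp,
                name = paste0(model$name, " (constrained)"))
}
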