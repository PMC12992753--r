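#' Read an MPT model from an EQN file
#'
#' Parses the EQN text format shared by the standard MPT tools
#' (multiTree, MPTinR, HMMTree). An optional first line gives the number
#' of branch lines; every other non-empty, non-comment line is
#' `tree category branch-term`, where the branch term is a `*`-separated
#' product of parameter names, complements `(1-name)` and numeric
#' constants. Trees and categories are ordered by first appearance.
#'
#' @param path Path to an EQN file.
#' @param name Model label.
#' @return An [mpt_model()].
#' @export
read_eqn <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty EQN file: ", path, call. = FALSE)
  first <- strsplit(lines[1L], "[[:space:]]+")[[1L]]
  if (length(first) == 1L &&
      !is.na(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("EQN file has no branch lines: ", path,
                           call. = FALSE)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("malformed EQN line (expected 'tree category term'): ",
         lines[which(bad)[1L]], call. = FALSE)
  }
  tree_col <- vapply(parts, `[[`, character(1), 1L)
  cat_col <- vapply(parts, `[[`, character(1), 2L)
  term_col <- vapply(parts, `[[`, character(1), 3L)

  parse_term <- function(term) {
    toks <- strsplit(term, "*", fixed = TRUE)[[1L]]
    lapply(toks, function(tk) {
      if (grepl("^\\(1-.+\\)$", tk)) {
        mpt_comp(sub("^\\(1-(.+)\\)$", "\\1", tk))
      } else if (!is.na(suppressWarnings(as.numeric(tk)))) {
        mpt_const(as.numeric(tk))
      } else {
        mpt_par(tk)
      }
    })
  }

  trees <- list()
  for (tn in unique(tree_col)) {
    sel <- tree_col == tn
    cats <- unique(cat_col[sel])
    branches <- mapply(function(cat, term) mpt_branch(cat, parse_term(term)),
                       cat_col[sel], term_col[sel], SIMPLIFY = FALSE)
    trees <- c(trees, list(mpt_tree(tn, cats, unname(branches))))
  }
  mpt_model(trees, name = name)
}

factor_to_eqn <- function(f, map) {
  if (f$kind == "const") return(format(f$value, digits = 15))
  m <- map[[f$ref]]
  nm <- switch(m$kind,
               free = m$name,
               const = return(if (f$kind == "comp") {
                 format(1 - m$value, digits = 15)
               } else {
                 format(m$value, digits = 15)
               }),
               prod = stop("shrinkage products cannot be expressed in ",
                           "EQN; export the unconstrained model",
                           call. = FALSE))
  if (f$kind == "comp") paste0("(1-", nm, ")") else nm
}

#' Write an MPT model to an EQN file
#'
#' Serializes a model in the standard EQN format, substituting equality
#' and fixing constraints into the branch terms (shared parameters appear
#' under their merged name, fixed parameters as numeric constants).
#' Shrinkage reparameterizations have no EQN representation and raise an
#' error. The first line holds the branch count; branches are written in
#' declaration order, so [read_eqn()] round-trips the model.
#'
#' @param model An [mpt_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eqn <- function(model, path) {
  stopifnot(inherits(model, "mpt_model"))
  lines <- character(0)
  for (tr in model$trees) {
    for (br in tr$branches) {
      term <- paste(vapply(br$factors, factor_to_eqn, character(1),
                           map = model$param_map), collapse = "*")
      lines <- c(lines, paste(tr$name, br$category, term))
    }
  }
  writeLines(c(as.character(length(lines)), lines), path)
  invisible(path)
}
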