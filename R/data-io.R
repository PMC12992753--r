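#' Bin raw confidence ratings
#'
#' Maps 0-100 confidence ratings onto the three-level scale used by the
#' lineup confidence model: low (0-30), moderate (31-70), high (71-100).
#' Bin edges are inclusive upper bounds and configurable.
#'
#' @param rating Integer vector of ratings in `[0, 100]`.
#' @param breaks Upper bounds of the low and moderate bins.
#' @param strict If `TRUE` (default), non-integer ratings are an error;
#'   otherwise they are floored.
#' @return A factor with levels `low`, `moderate`, `high`.
#' @examples
#' categorize_confidence(c(0, 30, 31, 70, 71, 100))
#' @export
categorize_confidence <- function(rating, breaks = c(30, 70),
                                  strict = TRUE) {
  stopifnot(is.numeric(rating), length(breaks) == 2L,
            breaks[1L] < breaks[2L])
  if (any(is.na(rating)) || any(rating < 0) || any(rating > 100)) {
    stop("confidence ratings must lie in [0, 100]", call. = FALSE)
  }
  if (any(rating != round(rating))) {
    if (strict) stop("non-integer confidence ratings (use strict = FALSE ",
                     "to floor them)", call. = FALSE)
    rating <- floor(rating)
  }
  lev <- ifelse(rating <= breaks[1L], "low",
                ifelse(rating <= breaks[2L], "moderate", "high"))
  factor(lev, levels = c("low", "moderate", "high"))
}

trial_vocab <- list(
  lineup_type = c("culprit-present", "culprit-absent"),
  response = c("suspect", "filler", "reject"))

#' Aggregate trial-level lineup records into a frequency table
#'
#' Counts responses per condition, lineup type, response and confidence
#' level, producing a frequency table (all cells present, zeros included)
#' whose tree and category labels match [lineup_confidence_model()]:
#' trees `<condition>.CP` / `<condition>.CA`, categories
#' `<condition>.<CP|CA>.<response>.<L|M|H>`.
#'
#' @param records Data frame with columns `participant`, `condition`,
#'   `lineup_type` (`"culprit-present"` / `"culprit-absent"`), `response`
#'   (`"suspect"` / `"filler"` / `"reject"`) and `confidence` (0-100).
#' @param conditions Condition labels defining the output schema; defaults
#'   to the sorted unique conditions present.
#' @param breaks,strict Passed to [categorize_confidence()].
#' @return A frequency data frame (`tree`, `category`, `count`).
#' @export
aggregate_trials <- function(records, conditions = NULL,
                             breaks = c(30, 70), strict = TRUE) {
  records <- as.data.frame(records)
  need <- c("participant", "condition", "lineup_type", "response",
            "confidence")
  if (!all(need %in% names(records))) {
    stop("trial records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(conditions)) {
    conditions <- sort(unique(as.character(records$condition)))
  }
  lev_code <- c(low = "L", moderate = "M", high = "H")
  type_code <- c("culprit-present" = "CP", "culprit-absent" = "CA")
  grid <- expand.grid(level = c("L", "M", "H"),
                      response = trial_vocab$response,
                      type = c("CP", "CA"), condition = conditions,
                      stringsAsFactors = FALSE)
  grid$tree <- paste0(grid$condition, ".", grid$type)
  grid$category <- paste0(grid$tree, ".", grid$response, ".", grid$level)
  grid$count <- 0
  if (nrow(records)) {
    bad_type <- setdiff(unique(records$lineup_type),
                        trial_vocab$lineup_type)
    bad_resp <- setdiff(unique(records$response), trial_vocab$response)
    if (length(bad_type) || length(bad_resp)) {
      stop("unknown lineup_type/response labels: ",
           paste(c(bad_type, bad_resp), collapse = ", "), call. = FALSE)
    }
    if (!all(records$condition %in% conditions)) {
      stop("records contain conditions outside the requested schema",
           call. = FALSE)
    }
    dup <- duplicated(records[c("participant", "condition",
                                "lineup_type")])
    if (any(dup)) {
      stop("duplicate (participant, condition, lineup_type) rows; each ",
           "participant contributes one response per tree", call. = FALSE)
    }
    lv <- lev_code[as.character(categorize_confidence(records$confidence,
                                                      breaks, strict))]
    cat <- paste0(records$condition, ".",
                  type_code[as.character(records$lineup_type)], ".",
                  records$response, ".", lv)
    tab <- table(cat)
    idx <- match(names(tab), grid$category)
    grid$count[idx] <- as.vector(tab)
  }
  mpt_freq(grid[, c("tree", "category", "count")])
}

#' Observed frequencies of the post-identification feedback study
#'
#' Returns the bundled 36-cell frequency table of the large validation
#' study of the lineup confidence model: 1565 participants each responded
#' to two culprit-present and two culprit-absent six-person lineups and
#' received negative feedback on one lineup of each type and positive
#' feedback on the other, then rated confidence (binned low/moderate/high).
#' Every tree totals 1565 responses; grand total 6260.
#'
#' @return A frequency data frame (`tree`, `category`, `count`) matching
#'   [lineup_base_model()].
#' @examples
#' counts <- lineup_feedback_counts()
#' tapply(counts$count, counts$tree, sum)
#' @export
lineup_feedback_counts <- function() {
  path <- system.file("extdata", "feedback_study_counts.csv",
                      package = "mptlineup", mustWork = TRUE)
  read_freq_csv(path)
}

#' Read and write frequency tables as CSV
#'
#' Plain CSV with columns `tree`, `category`, `count`; the round trip is
#' lossless.
#'
#' @param path File path.
#' @param data A frequency data frame.
#' @return `read_freq_csv()` returns a validated frequency data frame;
#'   `write_freq_csv()` returns `path` invisibly.
#' @export
read_freq_csv <- function(path) {
  mpt_freq(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_freq_csv
#' @export
write_freq_csv <- function(data, path) {
  utils::write.csv(mpt_freq(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
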