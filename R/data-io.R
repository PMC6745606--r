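# Reading and filtering collections of published two-sided p-values, and
# conversion to the squared z-value scale consumed by the empirical-Bayes
# fitters.

#' Read a collection of per-study p-values from CSV
#'
#' Expects a comma-separated, UTF-8 file with a header and at least the
#' columns `study_id` and `p_value`; optional columns `is_intercept`,
#' `is_f_test` (logical, default FALSE) and `outcome_rank` (positive
#' integer, default 1) carry the eligibility flags used by
#' [apply_collection_filters()].  Every malformed row (non-numeric p-value
#' such as "NS" or "<0.01", or p outside (0, 1]) is reported with its row
#' number; nothing is silently dropped.
#'
#' @param path Path to the CSV file.
#' @return A data frame of validated records with all five columns.
#' @export
read_collection <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  req <- c("study_id", "p_value")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n <- nrow(raw)
  problems <- character(0)
  p <- suppressWarnings(as.numeric(raw$p_value))
  bad_num <- which(is.na(p))
  if (length(bad_num))
    problems <- c(problems, sprintf(
      "row %d: p_value '%s' is not a number (summaries like 'NS' or '<0.01' cannot be used)",
      bad_num, raw$p_value[bad_num]))
  bad_range <- which(!is.na(p) & (p <= 0 | p > 1))
  if (length(bad_range))
    problems <- c(problems, sprintf("row %d: p_value %g outside (0, 1]",
                                    bad_range, p[bad_range]))
  parse_flag <- function(col) {
    if (!col %in% names(raw)) return(rep(FALSE, n))
    v <- toupper(raw[[col]])
    out <- v %in% c("TRUE", "T", "1", "YES")
    bad <- which(!v %in% c("TRUE", "T", "1", "YES",
                           "FALSE", "F", "0", "NO", ""))
    if (length(bad))
      problems <<- c(problems, sprintf("row %d: %s '%s' is not logical",
                                       bad, col, raw[[col]][bad]))
    out
  }
  is_intercept <- parse_flag("is_intercept")
  is_f_test <- parse_flag("is_f_test")
  if ("outcome_rank" %in% names(raw)) {
    outcome_rank <- suppressWarnings(as.integer(raw$outcome_rank))
    bad <- which(is.na(outcome_rank) | outcome_rank < 1)
    if (length(bad))
      problems <- c(problems, sprintf(
        "row %d: outcome_rank '%s' is not a positive integer",
        bad, raw$outcome_rank[bad]))
  } else {
    outcome_rank <- rep(1L, n)
  }
  if (length(problems))
    stop("invalid rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  data.frame(study_id = raw$study_id, p_value = p,
             is_intercept = is_intercept, is_f_test = is_f_test,
             outcome_rank = outcome_rank)
}

#' Apply the collection eligibility filters
#'
#' Drops records that should not enter the empirical-Bayes fit, labelling
#' each dropped record with the rule that removed it:
#' * `"intercept"` -- p-values for the intercept (the prior centered at
#'   zero is not appropriate for intercepts);
#' * `"f_test"` -- p-values from F tests (not convertible to a signed z);
#' * `"p<0.001"` -- p-values strictly below 0.001 (prior-data conflict
#'   zone; note the boundary p = 0.001 itself is kept);
#' * `"secondary_outcome"` -- `outcome_rank > 1` (only the first reported
#'   outcome is used).
#'
#' The filter is idempotent and loses nothing: `kept` plus `dropped`
#' partition the input.
#'
#' @param records Data frame from [read_collection()] (the flag columns are
#'   optional and default to "keep").
#' @return A list with data frames `kept` and `dropped`, the latter with an
#'   extra `drop_reason` column.
#' @export
apply_collection_filters <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("study_id", "p_value") %in% names(records)))
  n <- nrow(records)
  get_col <- function(col, default) {
    if (col %in% names(records)) records[[col]] else rep(default, n)
  }
  is_intercept <- get_col("is_intercept", FALSE)
  is_f_test <- get_col("is_f_test", FALSE)
  outcome_rank <- get_col("outcome_rank", 1L)
  reason <- rep(NA_character_, n)
  reason[outcome_rank > 1] <- "secondary_outcome"
  reason[records$p_value < 0.001] <- "p<0.001"
  reason[is_f_test] <- "f_test"
  reason[is_intercept] <- "intercept"
  dropped <- records[!is.na(reason), , drop = FALSE]
  if (nrow(dropped)) dropped$drop_reason <- reason[!is.na(reason)]
  else dropped$drop_reason <- character(0)
  list(kept = records[is.na(reason), , drop = FALSE], dropped = dropped)
}

#' Convert filtered p-value records to squared z-values
#'
#' Converts each two-sided p-value to its absolute z-value through
#' `|z| = |qnorm(p/2)|` and squares it.  The sign of the original estimate
#' is irrelevant here because only symmetric priors are entertained, and
#' z^2 is what the Gamma model consumes.
#'
#' @param records Data frame with columns `study_id` and `p_value`
#'   (typically the `kept` element of [apply_collection_filters()]).
#' @return A data frame with columns `study_id` and `z2`, suitable for
#'   [fit_conditional()] and [fit_marginal()].
#' @export
to_zdataset <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("study_id", "p_value") %in% names(records)))
  .check_p(records$p_value)
  data.frame(study_id = records$study_id,
             z2 = p_to_absz(records$p_value)^2)
}
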