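#' Construct a table of confidence-rated trials
#'
#' One row per trial of a two-choice task ("identical" vs "different" shape
#' judgments) with a retrospective confidence rating. `correct` is always
#' derived as `response == stimulus`, never taken from the input.
#'
#' @param subject_id Vector of subject identifiers.
#' @param stimulus,response Character vectors with values `"identical"` or
#'   `"different"`.
#' @param confidence Integer ratings in `1..n_levels`.
#' @param n_levels Number of points on the confidence scale (default 4).
#' @param group,region Optional per-trial metadata columns.
#' @param trial_index Optional 1-based trial index per subject.
#' @return A `data.frame` of class `trial_table` with columns
#'   `subject_id, stimulus, response, confidence, correct` (plus any
#'   metadata supplied).
#' @export
trial_table <- function(subject_id, stimulus, response, confidence,
                        n_levels = 4L, group = NULL, region = NULL,
                        trial_index = NULL) {
  n <- length(stimulus)
  if (n == 0L) abort("no trials")
  stimulus <- as.character(stimulus)
  response <- as.character(response)
  lv <- c("identical", "different")
  bad <- which(!(stimulus %in% lv))
  if (length(bad)) abort("invalid stimulus at trial %d: '%s'", bad[1], stimulus[bad[1]])
  bad <- which(!(response %in% lv))
  if (length(bad)) abort("invalid response at trial %d: '%s'", bad[1], response[bad[1]])
  confidence <- as.integer(confidence)
  bad <- which(is.na(confidence) | confidence < 1L | confidence > n_levels)
  if (length(bad))
    abort("confidence out of range 1..%d at trial %d (subject %s)",
          n_levels, bad[1], as.character(subject_id[bad[1]]))
  out <- data.frame(subject_id = as.character(subject_id),
                    stimulus = stimulus, response = response,
                    confidence = confidence,
                    correct = stimulus == response,
                    stringsAsFactors = FALSE)
  if (!is.null(group))  out$group  <- as.character(group)
  if (!is.null(region)) out$region <- as.character(region)
  if (!is.null(trial_index)) out$trial_index <- as.integer(trial_index)
  attr(out, "n_levels") <- as.integer(n_levels)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Read a trials CSV
#'
#' Expects columns `subject_id, stimulus, response, confidence` and
#' optionally `group, region, trial_index`.
#'
#' @param path Path to a CSV file.
#' @param n_levels Confidence scale length.
#' @return A [trial_table()].
#' @export
read_trials <- function(path, n_levels = 4L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "stimulus", "response", "confidence")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort("trials file missing columns: %s", paste(miss, collapse = ", "))
  trial_table(d$subject_id, d$stimulus, d$response, d$confidence,
              n_levels = n_levels, group = d$group, region = d$region,
              trial_index = d$trial_index)
}

#' Write a trials CSV
#' @param trials A [trial_table()] (or compatible data.frame).
#' @param path Output path.
#' @export
write_trials <- function(trials, path) {
  cols <- intersect(c("subject_id", "group", "region", "trial_index",
                      "stimulus", "response", "confidence"), names(trials))
  utils::write.csv(as.data.frame(trials)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
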