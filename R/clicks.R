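# Click streams: one participant x recording x repetition sequence of
# response times, plus the cohort-level CSV interchange format.

#' Create a click stream
#'
#' @param times numeric vector of click times in seconds; sorted
#'   internally, must lie in `[0, total_duration)` when a duration is
#'   supplied.
#' @param participant_id,recording_id identifiers.
#' @param repetition listening number, 1 or 2.
#' @param total_duration optional recording duration used to validate the
#'   click times.
#' @return Object of class `click_stream`.
#' @export
click_stream <- function(times, participant_id, recording_id,
                         repetition = 1L, total_duration = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("missing click times")
  repetition <- as.integer(repetition)
  if (!repetition %in% c(1L, 2L)) stop("repetition must be 1 or 2")
  if (!is.null(total_duration) &&
      any(times < 0 | times >= total_duration))
    stop(sprintf("click time(s) outside [0, %g) for participant '%s'",
                 total_duration, participant_id))
  else if (any(times < 0)) stop("negative click times")
  structure(list(participant_id = as.character(participant_id),
                 recording_id = as.character(recording_id),
                 repetition = repetition,
                 times = sort(times)),
            class = "click_stream")
}

#' @export
print.click_stream <- function(x, ...) {
  cat(sprintf("Click stream %s / %s rep %d: %d clicks\n",
              x$participant_id, x$recording_id, x$repetition,
              length(x$times)))
  invisible(x)
}

#' Read a cohort click table
#'
#' Columns: `participant_id, recording_id, repetition, time_s` (header
#' required; `#` comment lines ignored).
#'
#' @param path CSV file.
#' @return data.frame with those four columns, sorted by participant,
#'   repetition and time.
#' @export
read_clicks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("participant_id", "recording_id", "repetition", "time_s")
  if (!all(need %in% names(tab)))
    stop("click CSV must have header columns ", paste(need, collapse = ", "))
  tab <- tab[, need]
  tab$participant_id <- as.character(tab$participant_id)
  tab$recording_id <- as.character(tab$recording_id)
  tab$repetition <- as.integer(tab$repetition)
  tab$time_s <- as.numeric(tab$time_s)
  if (anyNA(tab$time_s)) stop("non-numeric click times in ", path)
  tab[order(tab$participant_id, tab$repetition, tab$time_s), ,
      drop = FALSE]
}

#' Write a cohort click table
#' @param clicks data.frame as returned by [read_clicks()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_clicks <- function(clicks, path) {
  need <- c("participant_id", "recording_id", "repetition", "time_s")
  stopifnot(all(need %in% names(clicks)))
  write.csv(clicks[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a cohort click table into click_stream objects.
split_streams <- function(clicks, total_duration = NULL) {
  key <- interaction(clicks$participant_id, clicks$repetition, drop = TRUE)
  lapply(split(clicks, key), function(d)
    click_stream(d$time_s, d$participant_id[1], d$recording_id[1],
                 d$repetition[1], total_duration))
}
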