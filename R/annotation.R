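# Hierarchical boundary-region annotations and the derived timeline
# partition.  All intervals are half-open [t_start, t_end) in float
# seconds, so a click landing exactly on a shared endpoint belongs to the
# following segment.  Interstitial gaps shorter than GAP_EPS are dropped.

GAP_EPS <- 1e-9

new_annotation_set <- function(regions, recording_id, total_duration) {
  structure(
    list(recording_id = recording_id,
         total_duration = total_duration,
         regions = regions),
    class = "annotation_set")
}

#' Create a validated annotation set
#'
#' An annotation set is the inventory of expert-defined boundary regions
#' (EDBRs) of one recording: non-overlapping half-open intervals, each
#' carrying a hierarchy level (1 = section end, 2 = phrase end).  Regions
#' are stored *exclusively*: a region carries its highest level only, so
#' per-level counts add up to the total.  Use `level_mode = "inclusive"`
#' in downstream functions to treat Level 1 regions as Level 2 regions as
#' well (a section end is de facto also a phrase end).
#'
#' @param regions data.frame with columns `region_id`, `level` (1 or 2),
#'   `t_start`, `t_end` (seconds) and optionally `label`.
#' @param recording_id identifier of the recording the regions annotate.
#' @param total_duration recording duration in seconds; defaults to the
#'   largest `t_end`.
#' @return An object of class `annotation_set`.
#' @examples
#' ann <- annotation_set(
#'   data.frame(region_id = "r1", level = 2, t_start = 10, t_end = 13.4),
#'   recording_id = "demo", total_duration = 20)
#' summarize_annotations(ann)
#' @export
annotation_set <- function(regions, recording_id = "recording",
                           total_duration = NULL) {
  stopifnot(is.data.frame(regions))
  required <- c("region_id", "level", "t_start", "t_end")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"label" %in% names(regions))
    regions$label <- rep(NA_character_, nrow(regions))
  regions <- regions[, c(required, "label")]
  regions$region_id <- as.character(regions$region_id)
  regions$level <- as.integer(regions$level)
  regions$t_start <- as.numeric(regions$t_start)
  regions$t_end <- as.numeric(regions$t_end)

  if (anyNA(regions$t_start) || anyNA(regions$t_end))
    stop("non-numeric or missing region times")
  if (anyNA(regions$level) || !all(regions$level %in% c(1L, 2L))) {
    bad <- regions$region_id[is.na(regions$level) |
                               !regions$level %in% c(1L, 2L)]
    stop("unknown level for region(s): ", paste(bad, collapse = ", "),
         " (levels must be 1 or 2)")
  }
  bad <- regions$t_start >= regions$t_end
  if (any(bad))
    stop("t_start >= t_end for region(s): ",
         paste(regions$region_id[bad], collapse = ", "))
  if (any(regions$t_start < 0))
    stop("negative t_start for region(s): ",
         paste(regions$region_id[regions$t_start < 0], collapse = ", "))
  if (anyDuplicated(regions$region_id))
    stop("duplicated region_id: ",
         paste(unique(regions$region_id[duplicated(regions$region_id)]),
               collapse = ", "))

  regions <- regions[order(regions$t_start), , drop = FALSE]
  rownames(regions) <- NULL
  if (nrow(regions) > 1) {
    overlap <- which(regions$t_start[-1] < regions$t_end[-nrow(regions)])
    if (length(overlap)) {
      i <- overlap[1]
      stop(sprintf("regions overlap: '%s' [%g, %g) and '%s' [%g, %g)",
                   regions$region_id[i], regions$t_start[i],
                   regions$t_end[i], regions$region_id[i + 1],
                   regions$t_start[i + 1], regions$t_end[i + 1]))
    }
  }
  if (is.null(total_duration))
    total_duration <- if (nrow(regions)) max(regions$t_end) else 0
  total_duration <- as.numeric(total_duration)
  # absorb round-trip float noise from text serialisation
  if (nrow(regions) && max(regions$t_end) > total_duration &&
      max(regions$t_end) - total_duration < 1e-9)
    total_duration <- max(regions$t_end)
  if (nrow(regions) && max(regions$t_end) > total_duration)
    stop("regions extend beyond total_duration (",
         max(regions$t_end), " > ", total_duration, ")")
  new_annotation_set(regions, as.character(recording_id), total_duration)
}

#' Read boundary annotations from disk
#'
#' Two plain-text formats are supported: a CSV with header columns
#' `region_id, level, t_start_s, t_end_s, label`, and an Audacity label
#' track (tab-separated `start<TAB>end<TAB>label` with labels `"L1"` /
#' `"L2"`).  Times are seconds.
#'
#' @param path file to read.
#' @param format `"csv"` or `"audacity_tsv"`; guessed from the file
#'   extension when omitted.
#' @param recording_id,total_duration passed to [annotation_set()]; the
#'   CSV reader also honours `#` comment headers written by
#'   [write_annotations()].
#' @return An `annotation_set`.
#' @export
read_annotations <- function(path, format = c("csv", "audacity_tsv"),
                             recording_id = NULL, total_duration = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (missing(format)) {
    format <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
      "audacity_tsv" else "csv"
  }
  format <- match.arg(format)
  if (format == "csv") {
    tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("region_id", "level", "t_start_s", "t_end_s")
    if (!all(need %in% names(tab)))
      stop("annotation CSV must have header columns ",
           paste(need, collapse = ", "))
    regions <- data.frame(region_id = tab$region_id, level = tab$level,
                          t_start = tab$t_start_s, t_end = tab$t_end_s,
                          label = if ("label" %in% names(tab)) tab$label
                                  else NA_character_,
                          stringsAsFactors = FALSE)
    if (is.null(recording_id) && "recording_id" %in% names(tab) &&
        nrow(tab))
      recording_id <- tab$recording_id[1]
    if (is.null(total_duration) && "total_duration_s" %in% names(tab) &&
        nrow(tab))
      total_duration <- tab$total_duration_s[1]
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3)
      stop("Audacity label track needs 3 tab-separated columns")
    names(tab)[1:3] <- c("start", "end", "label")
    lev <- ifelse(toupper(trimws(tab$label)) == "L1", 1L,
                  ifelse(toupper(trimws(tab$label)) == "L2", 2L, NA))
    if (anyNA(lev))
      stop("unknown level label(s) in Audacity track: ",
           paste(unique(tab$label[is.na(lev)]), collapse = ", "),
           " (expected 'L1' or 'L2')")
    regions <- data.frame(region_id = sprintf("r%d", seq_len(nrow(tab))),
                          level = lev,
                          t_start = as.numeric(tab$start),
                          t_end = as.numeric(tab$end),
                          label = tab$label, stringsAsFactors = FALSE)
  }
  if (is.null(recording_id))
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  annotation_set(regions, recording_id = recording_id,
                 total_duration = total_duration)
}

#' Write an annotation set to disk
#'
#' @param ann an `annotation_set`.
#' @param path output file.
#' @param format `"csv"` (default, round-trips `recording_id` and
#'   `total_duration`) or `"audacity_tsv"` (spans only).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, format = c("csv", "audacity_tsv")) {
  stopifnot(inherits(ann, "annotation_set"))
  format <- match.arg(format)
  if (format == "csv") {
    out <- data.frame(region_id = ann$regions$region_id,
                      level = ann$regions$level,
                      t_start_s = ann$regions$t_start,
                      t_end_s = ann$regions$t_end,
                      label = ann$regions$label,
                      recording_id = ann$recording_id,
                      total_duration_s = ann$total_duration)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- sprintf("%.17g\t%.17g\tL%d", ann$regions$t_start,
                     ann$regions$t_end, ann$regions$level)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Partition a recording's timeline into EDBR and interstitial segments
#'
#' The complement of the boundary regions becomes "interstitial"
#' segments, yielding a contiguous, non-overlapping cover of
#' `[0, total_duration)` in which every EDBR appears as exactly one
#' segment.  Gaps shorter than `1e-9` s are dropped.
#'
#' @param ann an `annotation_set`.
#' @return A `timeline_partition`: a data.frame with columns `t_start`,
#'   `t_end`, `class` (`"L1"`, `"L2"` or `"interstitial"`), `region_id`
#'   (`NA` for interstitials) and `duration`, plus attributes
#'   `recording_id` and `total_duration`.
#' @examples
#' ann <- annotation_set(
#'   data.frame(region_id = "r1", level = 2, t_start = 5, t_end = 9),
#'   total_duration = 20)
#' build_partition(ann)
#' @export
build_partition <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  r <- ann$regions
  n <- nrow(r)
  starts <- c(0, r$t_end)
  ends <- c(r$t_start, ann$total_duration)
  seg <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    class = character(0), region_id = character(0),
                    stringsAsFactors = FALSE)
  rows <- vector("list", 2 * n + 1)
  for (i in seq_len(n + 1)) {
    if (ends[i] - starts[i] >= GAP_EPS)
      rows[[2 * i - 1]] <- data.frame(t_start = starts[i],
                                      t_end = ends[i],
                                      class = "interstitial",
                                      region_id = NA_character_,
                                      stringsAsFactors = FALSE)
    if (i <= n)
      rows[[2 * i]] <- data.frame(t_start = r$t_start[i],
                                  t_end = r$t_end[i],
                                  class = paste0("L", r$level[i]),
                                  region_id = r$region_id[i],
                                  stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(seg))
    seg <- data.frame(t_start = 0, t_end = ann$total_duration,
                      class = "interstitial", region_id = NA_character_,
                      stringsAsFactors = FALSE)
  # Absorb the sub-epsilon gaps into the following segment so the union
  # is exactly [0, total_duration).
  seg$t_start[1] <- 0
  if (nrow(seg) > 1) seg$t_start[-1] <- seg$t_end[-nrow(seg)]
  seg$t_end[nrow(seg)] <- ann$total_duration
  seg$duration <- seg$t_end - seg$t_start
  rownames(seg) <- NULL
  structure(seg, recording_id = ann$recording_id,
            total_duration = ann$total_duration,
            class = c("timeline_partition", "data.frame"))
}

#' Locate the segment containing a time point
#'
#' Half-open convention: a query equal to a segment's `t_start` returns
#' that segment; a query equal to its `t_end` returns the following one.
#'
#' @param partition a `timeline_partition`.
#' @param t numeric vector of query times, each in
#'   `[0, total_duration)`.
#' @return Integer vector of row indices into `partition`.
#' @export
segment_at <- function(partition, t) {
  stopifnot(inherits(partition, "timeline_partition"))
  total <- attr(partition, "total_duration")
  if (any(t < 0 | t >= total))
    stop("time(s) outside [0, ", total, "): ",
         paste(head(t[t < 0 | t >= total], 3), collapse = ", "))
  findInterval(t, partition$t_start)
}

#' Summarise an annotation set
#'
#' Region counts and duration statistics per level plus the overall
#' total, mirroring how boundary-region inventories are tabulated.
#'
#' @param ann an `annotation_set`.
#' @return data.frame with rows `L1`, `L2`, `total` and columns `n`,
#'   `dur_min`, `dur_max`, `dur_mean`, `dur_sd` (durations in seconds;
#'   `NA` when a level has no regions).
#' @export
summarize_annotations <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  dur <- ann$regions$t_end - ann$regions$t_start
  one <- function(d) {
    if (!length(d))
      return(data.frame(n = 0L, dur_min = NA_real_, dur_max = NA_real_,
                        dur_mean = NA_real_, dur_sd = NA_real_))
    data.frame(n = length(d), dur_min = min(d), dur_max = max(d),
               dur_mean = mean(d),
               dur_sd = if (length(d) > 1) sd(d) else NA_real_)
  }
  out <- rbind(one(dur[ann$regions$level == 1L]),
               one(dur[ann$regions$level == 2L]),
               one(dur))
  rownames(out) <- c("L1", "L2", "total")
  out
}

#' @export
summary.annotation_set <- function(object, ...) summarize_annotations(object)

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set '%s': %d regions (%d L1, %d L2) over %.1f s\n",
              x$recording_id, nrow(x$regions),
              sum(x$regions$level == 1L), sum(x$regions$level == 2L),
              x$total_duration))
  invisible(x)
}

# Row indices of partition segments belonging to a level under the given
# counting mode.  "exclusive": L2 means level-2-only regions; "inclusive":
# L2 also includes L1 regions (a section end is also a phrase end).
level_segments <- function(partition, level, level_mode = c("exclusive",
                                                            "inclusive")) {
  level_mode <- match.arg(level_mode)
  stopifnot(level %in% c(1L, 2L))
  classes <- if (level == 1L) "L1"
             else if (level_mode == "exclusive") "L2" else c("L1", "L2")
  which(partition$class %in% classes)
}

edbr_segments <- function(partition) which(partition$class != "interstitial")

interstitial_segments <- function(partition)
  which(partition$class == "interstitial")
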