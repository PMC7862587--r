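# Signal-detection scoring of click streams against a timeline
# partition: hits/false alarms per region, HR/FAR as binary per-region
# trials, d' with extreme-rate correction, and promptness scores.

#' Promptness scoring configuration
#'
#' Promptness maps a hit's position inside its boundary region to
#' `[0, 1]`: 1 at the region onset (a prompt, anticipatory response) and
#' 0 in the limit at the region end (a delayed response).  With `x` the
#' elapsed fraction of the region, the linear mode scores `a*x + b`
#' (defaults `a = -1`, `b = 1`, i.e. `1 - x`); the reciprocal mode uses a
#' hyperbolic falloff `c/(x + c)` rescaled so it is exactly 1 at the
#' onset and 0 at the end.  Scores are clamped to `[0, 1]`.
#'
#' @param mode `"linear"` (default; the two modes give similar orderings
#'   and the linear one is retained as canonical) or `"reciprocal"`.
#' @param a,b linear coefficients.
#' @param c reciprocal shape constant (> 0); smaller values fall off
#'   faster near the onset.
#' @return Object of class `promptness_config`.
#' @export
promptness_config <- function(mode = c("linear", "reciprocal"),
                              a = -1, b = 1, c = 0.5) {
  mode <- match.arg(mode)
  if (c <= 0) stop("reciprocal constant c must be > 0")
  structure(list(mode = mode, a = a, b = b, c = c),
            class = "promptness_config")
}

#' Promptness of a click within a boundary region
#'
#' @param time click time(s), seconds; must lie inside
#'   `[t_start, t_end)`.
#' @param t_start,t_end region span.
#' @param config a [promptness_config()].
#' @return Numeric score(s) in `[0, 1]`.
#' @examples
#' promptness_score(12, 10, 14)  # midpoint -> 0.5
#' @export
promptness_score <- function(time, t_start, t_end,
                             config = promptness_config()) {
  if (any(time < t_start | time >= t_end))
    stop("click outside its region: promptness undefined")
  x <- (time - t_start) / (t_end - t_start)
  p <- if (config$mode == "linear") {
    config$a * x + config$b
  } else {
    raw <- config$c / (x + config$c)
    lo <- config$c / (1 + config$c)
    (raw - lo) / (1 - lo)
  }
  pmin(1, pmax(0, p))
}

#' Classify clicks as hits or false alarms
#'
#' Each click is assigned to the unique partition segment whose half-open
#' span contains it.  Clicks inside an EDBR segment are hits; clicks in
#' interstitial segments are false alarms (a click immediately before or
#' after a region is not a hit).  The earliest click inside each EDBR is
#' flagged `first_in_region` and receives a promptness score; later
#' clicks in the same region do not.
#'
#' @param stream a [click_stream()].
#' @param partition a [build_partition()] result for the same recording.
#' @param config promptness configuration.
#' @return data.frame with one row per click: `time`, `segment` (row
#'   index into the partition), `class`, `region_id`, `klass` (`"hit"` /
#'   `"false_alarm"`), `first_in_region`, `promptness` (`NA` unless a
#'   first-in-region hit).
#' @export
classify_clicks <- function(stream, partition,
                            config = promptness_config()) {
  stopifnot(inherits(stream, "click_stream"),
            inherits(partition, "timeline_partition"))
  rec <- attr(partition, "recording_id")
  if (!is.null(rec) && !identical(stream$recording_id, rec))
    stop(sprintf("recording mismatch: stream '%s' vs partition '%s'",
                 stream$recording_id, rec))
  times <- stream$times
  seg <- segment_at(partition, times)
  klass <- ifelse(partition$class[seg] == "interstitial",
                  "false_alarm", "hit")
  first <- rep(FALSE, length(times))
  if (any(klass == "hit")) {
    hit_idx <- which(klass == "hit")
    first[hit_idx[!duplicated(seg[hit_idx])]] <- TRUE
  }
  prompt <- rep(NA_real_, length(times))
  fh <- which(first)
  if (length(fh))
    prompt[fh] <- promptness_score(times[fh], partition$t_start[seg[fh]],
                                   partition$t_end[seg[fh]], config)
  data.frame(time = times, segment = seg,
             class = partition$class[seg],
             region_id = partition$region_id[seg],
             klass = klass, first_in_region = first,
             promptness = prompt, stringsAsFactors = FALSE)
}

#' Hit rate at a hierarchy level
#'
#' One binary "signal present" trial per boundary region: the hit rate is
#' the number of regions of the requested level containing at least one
#' click, divided by the number of regions at that level.  Duplicate
#' clicks within a region do not inflate the rate.
#'
#' @param scored output of [classify_clicks()].
#' @param partition the partition the clicks were scored against.
#' @param level 1 or 2; `NULL` pools regions of both levels (as used for
#'   the overall sensitivity index).
#' @param level_mode `"exclusive"` (default; Level 2 = level-2-only
#'   regions, so the two levels partition the inventory) or
#'   `"inclusive"` (Level 2 also counts Level 1 regions).
#' @return Rate in `[0, 1]`.
#' @export
hit_rate <- function(scored, partition, level = NULL,
                     level_mode = c("exclusive", "inclusive")) {
  level_mode <- match.arg(level_mode)
  segs <- if (is.null(level)) edbr_segments(partition)
          else level_segments(partition, level, level_mode)
  if (!length(segs))
    stop("no regions at the requested level: hit rate undefined")
  hit_segs <- unique(scored$segment[scored$klass == "hit"])
  sum(segs %in% hit_segs) / length(segs)
}

#' False-alarm rate over interstitial space
#'
#' By default each interstitial segment is one binary "signal absent"
#' trial, mirroring the per-region hit trials.  The `"fixed_window"`
#' mode instead divides each interstitial segment into windows of a given
#' length (by default the recording's mean EDBR duration) and counts one
#' trial per window, which weights long interstitials more heavily.
#'
#' @inheritParams hit_rate
#' @param trial_mode `"per_segment"` (default) or `"fixed_window"`.
#' @param window window length in seconds for the fixed-window mode;
#'   defaults to the mean EDBR duration of the partition.
#' @return Rate in `[0, 1]`.
#' @export
false_alarm_rate <- function(scored, partition,
                             trial_mode = c("per_segment", "fixed_window"),
                             window = NULL) {
  trial_mode <- match.arg(trial_mode)
  inter <- interstitial_segments(partition)
  if (!length(inter))
    stop("no interstitial segments: false-alarm rate undefined")
  fa <- scored[scored$klass == "false_alarm", , drop = FALSE]
  if (trial_mode == "per_segment") {
    return(sum(inter %in% unique(fa$segment)) / length(inter))
  }
  if (is.null(window)) {
    ed <- edbr_segments(partition)
    window <- mean(partition$duration[ed])
  }
  if (!is.finite(window) || window <= 0)
    stop("fixed-window FAR needs a positive window length")
  n_trials <- 0L
  n_fa <- 0L
  for (s in inter) {
    dur <- partition$duration[s]
    k <- max(1L, ceiling(dur / window))
    edges <- partition$t_start[s] + dur * (0:k) / k
    t_in <- fa$time[fa$segment == s]
    occ <- unique(findInterval(t_in, edges, rightmost.closed = TRUE))
    n_trials <- n_trials + k
    n_fa <- n_fa + length(occ)
  }
  n_fa / n_trials
}

#' Sensitivity index d'
#'
#' Conventional signal-detection sensitivity, `z(HR) - z(FAR)` with `z`
#' the standard-normal quantile (probit).  Extreme rates of exactly 0 or
#' 1 are corrected with the log-linear rule -- 0 becomes `1/(2N)` and 1
#' becomes `1 - 1/(2N)`, `N` the number of trials of that type -- so the
#' index stays finite.
#'
#' @param hr,far hit and false-alarm rates in `[0, 1]`.
#' @param n_signal,n_noise trial counts used for the extreme-rate
#'   correction; required only when the respective rate is 0 or 1.
#' @return Finite numeric d'.
#' @examples
#' d_prime(0.8, 0.2)            # ~ 1.683
#' d_prime(1, 0, 10, 10)        # corrected, finite
#' @export
d_prime <- function(hr, far, n_signal = NULL, n_noise = NULL) {
  if (hr < 0 || hr > 1 || far < 0 || far > 1)
    stop("rates must lie in [0, 1]")
  for (nm in c("n_signal", "n_noise")) {
    n <- get(nm)
    if (!is.null(n) && (is.na(n) || n < 0))
      stop("negative or missing ", nm, " trial count")
  }
  fix <- function(rate, n, what) {
    if (rate > 0 && rate < 1) return(rate)
    if (is.null(n)) stop("need ", what, " trial count to correct a rate of ",
                         rate)
    n <- as.numeric(n)
    if (n == 0) stop(what, " trial count is zero: rate undefined")
    min(max(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
  }
  hr <- fix(hr, n_signal, "signal")
  far <- fix(far, n_noise, "noise")
  qnorm(hr) - qnorm(far)
}

#' Cumulative promptness at a level
#'
#' First-click promptness scores are summed across the hits at one
#' hierarchy level and normalised by the number of regions at that level,
#' giving a per-participant awareness score in `[0, 1]` (0 = no hits,
#' 1 = every region hit exactly at its onset).
#'
#' @param scored output of [classify_clicks()].
#' @param level 1 or 2.
#' @param n_regions number of regions at that level (>= 1).
#' @param level_mode see [hit_rate()].
#' @return Numeric in `[0, 1]`.
#' @export
cumulative_promptness <- function(scored, level, n_regions,
                                  level_mode = c("exclusive", "inclusive")) {
  level_mode <- match.arg(level_mode)
  if (is.na(n_regions) || n_regions < 1)
    stop("cumulative promptness undefined without regions at level ", level)
  classes <- if (level == 1) "L1"
             else if (level_mode == "exclusive") "L2" else c("L1", "L2")
  p <- scored$promptness[scored$first_in_region &
                           scored$class %in% classes]
  sum(p, na.rm = TRUE) / n_regions
}

#' Score one click stream
#'
#' Computes the full per-participant score set for a single listening:
#' level-wise and overall hit rates, the false-alarm rate, d' (from the
#' overall hit rate), and cumulative promptness at each level.
#'
#' @param stream a [click_stream()].
#' @param partition the recording's partition.
#' @param level_mode,trial_mode,config see [hit_rate()],
#'   [false_alarm_rate()], [promptness_config()].
#' @return One-row data.frame with identifiers, `scope`
#'   (`"rep1"`/`"rep2"`), counts, rates, `d_prime` and cumulative
#'   promptness columns.
#' @export
participant_scores <- function(stream, partition,
                               level_mode = c("exclusive", "inclusive"),
                               trial_mode = c("per_segment", "fixed_window"),
                               config = promptness_config()) {
  level_mode <- match.arg(level_mode)
  trial_mode <- match.arg(trial_mode)
  scored <- classify_clicks(stream, partition, config)
  n1 <- length(level_segments(partition, 1L, level_mode))
  n2 <- length(level_segments(partition, 2L, level_mode))
  n_sig <- length(edbr_segments(partition))
  n_noise <- length(interstitial_segments(partition))
  hr1 <- if (n1) hit_rate(scored, partition, 1L, level_mode) else NA_real_
  hr2 <- if (n2) hit_rate(scored, partition, 2L, level_mode) else NA_real_
  hr_all <- hit_rate(scored, partition, NULL)
  far <- false_alarm_rate(scored, partition, trial_mode)
  data.frame(participant_id = stream$participant_id,
             recording_id = stream$recording_id,
             scope = paste0("rep", stream$repetition),
             n_clicks = nrow(scored),
             n_hits = sum(scored$klass == "hit"),
             n_fa = sum(scored$klass == "false_alarm"),
             HR_L1 = hr1, HR_L2 = hr2, HR_all = hr_all, FAR = far,
             d_prime = d_prime(hr_all, far, n_sig, n_noise),
             cum_promptness_L1 = if (n1)
               cumulative_promptness(scored, 1L, n1, level_mode)
               else NA_real_,
             cum_promptness_L2 = if (n2)
               cumulative_promptness(scored, 2L, n2, level_mode)
               else NA_real_,
             n_signal = n_sig, n_noise = n_noise,
             stringsAsFactors = FALSE)
}

#' Average a participant's two listenings
#'
#' Rates, counts and cumulative promptness are averaged element-wise;
#' d' is recomputed from the averaged rates (not averaged itself), with
#' the same extreme-rate correction.
#'
#' @param s1,s2 one-row score frames from [participant_scores()] with
#'   scopes `"rep1"` and `"rep2"` for the same participant and
#'   recording.
#' @return One-row score frame with `scope = "averaged"`.
#' @export
average_over_repetitions <- function(s1, s2) {
  if (is.null(s2) || is.null(s1))
    stop("both repetitions are required to average scores")
  stopifnot(is.data.frame(s1), is.data.frame(s2),
            nrow(s1) == 1, nrow(s2) == 1)
  if (!identical(sort(c(s1$scope, s2$scope)), c("rep1", "rep2")))
    stop("scope mismatch: need one 'rep1' and one 'rep2' row, got ",
         s1$scope, " and ", s2$scope)
  if (!identical(s1$participant_id, s2$participant_id) ||
      !identical(s1$recording_id, s2$recording_id))
    stop("cannot average scores of different participants or recordings")
  out <- s1
  num <- c("n_clicks", "n_hits", "n_fa", "HR_L1", "HR_L2", "HR_all",
           "FAR", "cum_promptness_L1", "cum_promptness_L2")
  for (v in num) out[[v]] <- (s1[[v]] + s2[[v]]) / 2
  out$scope <- "averaged"
  out$d_prime <- d_prime(out$HR_all, out$FAR, s1$n_signal, s1$n_noise)
  out
}

#' Score a whole cohort
#'
#' Scores every participant x repetition stream in a click table and
#' appends the across-listening averages.  A participant with zero
#' clicks in a repetition is scored (all rates 0) with a warning, since
#' empty listenings occur in real cohorts.
#'
#' @param clicks cohort click table (see [read_clicks()]).
#' @param ann the recording's `annotation_set`.
#' @param ... passed to [participant_scores()].
#' @return data.frame of score rows, scopes `rep1`, `rep2` and
#'   `averaged` per participant.
#' @export
score_cohort <- function(clicks, ann, ...) {
  stopifnot(inherits(ann, "annotation_set"))
  bad <- unique(clicks$recording_id[clicks$recording_id !=
                                      ann$recording_id])
  if (length(bad))
    stop(sprintf("recording mismatch: clicks for '%s' vs annotations '%s'",
                 bad[1], ann$recording_id))
  partition <- build_partition(ann)
  participants <- unique(clicks$participant_id)
  rows <- list()
  for (p in participants) {
    reps <- list()
    for (r in 1:2) {
      t_pr <- clicks$time_s[clicks$participant_id == p &
                              clicks$repetition == r]
      if (!length(t_pr))
        warning(sprintf("participant '%s' has zero clicks in repetition %d",
                        p, r), call. = FALSE)
      st <- click_stream(t_pr, p, ann$recording_id, r,
                         ann$total_duration)
      reps[[r]] <- participant_scores(st, partition, ...)
    }
    rows[[p]] <- rbind(reps[[1]], reps[[2]],
                       average_over_repetitions(reps[[1]], reps[[2]]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled per-region click densities
#'
#' Clicks from all streams (participants and repetitions) are pooled;
#' for every partition segment -- boundary region or interstitial alike
#' -- the pooled count is divided by the segment duration, giving clicks
#' per second.  Higher density in a region means more inter-participant
#' agreement on it.
#'
#' @param clicks cohort click table, or a numeric vector of pooled click
#'   times.
#' @param partition a `timeline_partition`.
#' @return The partition data.frame with extra columns `click_count` and
#'   `density`.
#' @export
region_densities <- function(clicks, partition) {
  times <- if (is.data.frame(clicks)) clicks$time_s else as.numeric(clicks)
  seg <- segment_at(partition, times)
  counts <- tabulate(seg, nbins = nrow(partition))
  out <- as.data.frame(partition)
  out$click_count <- counts
  out$density <- counts / out$duration
  out
}

#' Fixed-width click histogram
#'
#' Counts pooled clicks in consecutive bins of `bin_width` seconds over
#' `[0, total_duration)`; the final partial bin is retained so the
#' counts always sum to the number of clicks.
#'
#' @param clicks click table or numeric vector of times.
#' @param total_duration recording duration in seconds.
#' @param bin_width bin width in seconds (> 0), default 1 s.
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
click_histogram <- function(clicks, total_duration, bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be positive")
  times <- if (is.data.frame(clicks)) clicks$time_s else as.numeric(clicks)
  if (any(times < 0 | times >= total_duration))
    stop("click time(s) outside [0, total_duration)")
  n_bins <- ceiling(total_duration / bin_width)
  idx <- pmin(floor(times / bin_width) + 1L, n_bins)
  data.frame(bin_start = (seq_len(n_bins) - 1) * bin_width,
             bin_end = pmin(seq_len(n_bins) * bin_width, total_duration),
             count = tabulate(idx, nbins = n_bins))
}

#' Musicianship composite score
#'
#' Years of instrument training and weekly practice hours are each
#' z-standardised within group (recording cohort); the composite is the
#' mean of the two z scores.  A participant missing one measure receives
#' the available z alone, flagged in the `partial` column.
#'
#' @param years_training,weekly_hours numeric vectors (NA = missing).
#' @param group group labels (e.g. assigned recording), same length.
#' @return data.frame with `group`, `z_years`, `z_hours`,
#'   `musicianship`, `partial`.
#' @export
musicianship_score <- function(years_training, weekly_hours, group) {
  n <- length(years_training)
  stopifnot(length(weekly_hours) == n, length(group) == n)
  group <- as.character(group)
  z_years <- z_hours <- rep(NA_real_, n)
  for (g in unique(group)) {
    idx <- group == g
    for (m in c("years", "hours")) {
      v <- if (m == "years") years_training[idx] else weekly_hours[idx]
      ok <- !is.na(v)
      if (sum(ok) < 2)
        stop(sprintf("fewer than 2 non-missing '%s' values in group '%s'",
                     m, g))
      s <- sd(v[ok])
      if (s == 0)
        stop(sprintf("zero variance in '%s' within group '%s'", m, g))
      z <- rep(NA_real_, sum(idx))
      z[ok] <- (v[ok] - mean(v[ok])) / s
      if (m == "years") z_years[idx] <- z else z_hours[idx] <- z
    }
  }
  comp <- rowMeans(cbind(z_years, z_hours), na.rm = TRUE)
  comp[is.na(z_years) & is.na(z_hours)] <- NA_real_
  data.frame(group = group, z_years = z_years, z_hours = z_hours,
             musicianship = comp,
             partial = xor(is.na(z_years), is.na(z_hours)),
             stringsAsFactors = FALSE)
}
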