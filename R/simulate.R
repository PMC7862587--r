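# Synthetic listeners: annotation-timeline generation shaped like the
# two study recordings, a generative click model per listener (per-level
# hit probabilities, Beta-distributed promptness, Poisson false alarms),
# cohort assembly with performance-independent musicianship covariates,
# and parameter recovery.

# Deterministic per-listener seed derived from (cohort seed,
# participant_id), so adding listeners never perturbs existing streams.
# Polynomial rolling hash over the id characters, folded with the cohort
# seed into [0, 2^31 - 1).
listener_seed <- function(cohort_seed, participant_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(participant_id)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (as.numeric(cohort_seed) %% 2147483647) * 48271) %%
               2147483647)
}

#' Configuration for a synthetic annotation timeline
#'
#' Defaults describe a Torī-like recording: 6 Level 1 + 13 Level 2
#' regions over roughly five minutes, with region durations drawn
#' uniformly from the observed per-level ranges.  See [tori_config()]
#' and [multani_config()] for the two packaged presets.
#'
#' @param n_L1,n_L2 region counts per level (>= 1).
#' @param L1_range,L2_range duration ranges in seconds, `c(min, max)`.
#' @param gap_range interstitial gap duration range in seconds.
#' @param target_duration approximate recording length in seconds; only
#'   used for a feasibility check (the realised duration is the sum of
#'   sampled spans).
#' @return Object of class `annotation_gen_config`.
#' @export
annotation_gen_config <- function(n_L1 = 6, n_L2 = 13,
                                  L1_range = c(1.8, 10.8),
                                  L2_range = c(1.9, 7.3),
                                  gap_range = c(6, 14),
                                  target_duration = 300) {
  stopifnot(n_L1 >= 1, n_L2 >= 1,
            length(L1_range) == 2, length(L2_range) == 2,
            length(gap_range) == 2,
            all(c(L1_range, L2_range) > 0), all(gap_range >= 0),
            L1_range[1] <= L1_range[2], L2_range[1] <= L2_range[2],
            gap_range[1] <= gap_range[2])
  structure(list(n_L1 = n_L1, n_L2 = n_L2, L1_range = L1_range,
                 L2_range = L2_range, gap_range = gap_range,
                 target_duration = target_duration),
            class = "annotation_gen_config")
}

#' Torī-like annotation preset (6 L1 + 13 L2 regions)
#' @return An [annotation_gen_config()].
#' @export
tori_config <- function() annotation_gen_config()

#' Multānī-like annotation preset (7 L1 + 27 L2 regions)
#' @return An [annotation_gen_config()].
#' @export
multani_config <- function()
  annotation_gen_config(n_L1 = 7, n_L2 = 27, L1_range = c(1.3, 7.8),
                        L2_range = c(1.3, 4.8), gap_range = c(2.5, 8))

#' Generate a synthetic annotation timeline
#'
#' Lays out an alternating gap/region sequence in which Level 1 regions
#' act as section enders: the Level 2 regions are split into `n_L1`
#' runs, each run closed by a Level 1 region (the performance also ends
#' with one).  Durations are drawn uniformly from the configured ranges.
#'
#' @param config an [annotation_gen_config()].
#' @param recording_id identifier for the generated recording.
#' @param seed optional integer seed; the same seed yields an identical
#'   annotation set.
#' @return An [annotation_set()].
#' @export
gen_annotation <- function(config = annotation_gen_config(),
                           recording_id = "synthetic", seed = NULL) {
  stopifnot(inherits(config, "annotation_gen_config"))
  if (!is.null(seed)) set.seed(seed)
  n1 <- config$n_L1; n2 <- config$n_L2
  # distribute the L2 regions over the n1 sections
  section_of <- sort(sample.int(n1, n2, replace = TRUE))
  levels <- unlist(lapply(seq_len(n1), function(s)
    c(rep(2L, sum(section_of == s)), 1L)))
  durs <- ifelse(levels == 1L,
                 runif(length(levels), config$L1_range[1],
                       config$L1_range[2]),
                 runif(length(levels), config$L2_range[1],
                       config$L2_range[2]))
  if (sum(durs) > config$target_duration)
    stop(sprintf(paste("infeasible packing: sampled region durations",
                       "(%.1f s) exceed the target duration (%.1f s)"),
                 sum(durs), config$target_duration))
  gaps <- runif(length(levels) + 1, config$gap_range[1],
                config$gap_range[2])
  t <- 0
  starts <- numeric(length(levels))
  for (i in seq_along(levels)) {
    t <- t + gaps[i]
    starts[i] <- t
    t <- t + durs[i]
  }
  total <- t + gaps[length(gaps)]
  annotation_set(
    data.frame(region_id = sprintf("r%02d", seq_along(levels)),
               level = levels, t_start = starts, t_end = starts + durs,
               label = paste0("L", levels), stringsAsFactors = FALSE),
    recording_id = recording_id, total_duration = total)
}

#' Generative model of one synthetic listener
#'
#' Each boundary region elicits a click with the level's hit
#' probability; a hit's position inside the region is drawn so that its
#' linear promptness is Beta(alpha, beta) distributed.  False alarms
#' arrive as a homogeneous Poisson process over interstitial time.
#' Optional motor jitter perturbs hit times (clipped inside the
#' region).
#'
#' @param p_hit_L1,p_hit_L2 per-region hit probabilities.
#' @param prompt_shape_L1,prompt_shape_L2 `c(alpha, beta)` of the
#'   promptness Beta distribution per level; the Level 1 default is
#'   shifted toward prompt (early) responses.
#' @param fa_rate false alarms per second of interstitial time.
#' @param motor_jitter_sd SD (seconds) of Gaussian jitter on hit times
#'   (0 = promptness placed exactly, so recovery is exact up to Beta
#'   sampling noise).
#' @param participant_id identifier.
#' @return Object of class `listener_model`.
#' @export
listener_model <- function(p_hit_L1 = 0.8, p_hit_L2 = 0.6,
                           prompt_shape_L1 = c(3, 2),
                           prompt_shape_L2 = c(2, 2),
                           fa_rate = 0.03, motor_jitter_sd = 0,
                           participant_id = "P01") {
  stopifnot(p_hit_L1 >= 0, p_hit_L1 <= 1, p_hit_L2 >= 0, p_hit_L2 <= 1,
            fa_rate >= 0, motor_jitter_sd >= 0,
            all(prompt_shape_L1 > 0), all(prompt_shape_L2 > 0))
  structure(list(p_hit_L1 = p_hit_L1, p_hit_L2 = p_hit_L2,
                 prompt_shape_L1 = prompt_shape_L1,
                 prompt_shape_L2 = prompt_shape_L2,
                 fa_rate = fa_rate, motor_jitter_sd = motor_jitter_sd,
                 participant_id = as.character(participant_id)),
            class = "listener_model")
}

#' Simulate one listener's click streams
#'
#' @param model a [listener_model()].
#' @param ann the recording's [annotation_set()].
#' @param n_reps number of listenings (default 2).
#' @param seed optional integer seed for determinism.
#' @return List of `n_reps` [click_stream()] objects.
#' @export
simulate_listener <- function(model, ann, n_reps = 2, seed = NULL) {
  stopifnot(inherits(model, "listener_model"),
            inherits(ann, "annotation_set"))
  if (!is.null(seed)) set.seed(seed)
  partition <- build_partition(ann)
  ed <- partition[partition$class != "interstitial", , drop = FALSE]
  inter <- partition[partition$class == "interstitial", , drop = FALSE]
  lapply(seq_len(n_reps), function(rep) {
    times <- numeric(0)
    if (nrow(ed)) {
      p <- ifelse(ed$class == "L1", model$p_hit_L1, model$p_hit_L2)
      hit <- runif(nrow(ed)) < p
      if (any(hit)) {
        cls <- ed$class[hit]
        u <- numeric(length(cls))
        i1 <- cls == "L1"
        u[i1] <- rbeta(sum(i1), model$prompt_shape_L1[1],
                       model$prompt_shape_L1[2])
        u[!i1] <- rbeta(sum(!i1), model$prompt_shape_L2[1],
                        model$prompt_shape_L2[2])
        tt <- ed$t_start[hit] + (1 - u) * ed$duration[hit]
        if (model$motor_jitter_sd > 0) {
          tt <- tt + rnorm(length(tt), 0, model$motor_jitter_sd)
          tt <- pmin(pmax(tt, ed$t_start[hit]),
                     ed$t_end[hit] - 1e-9)
        }
        times <- c(times, tt)
      }
    }
    if (model$fa_rate > 0 && nrow(inter)) {
      n_fa <- rpois(nrow(inter), model$fa_rate * inter$duration)
      for (i in which(n_fa > 0))
        times <- c(times, runif(n_fa[i], inter$t_start[i],
                                inter$t_end[i]))
    }
    click_stream(times, model$participant_id, ann$recording_id, rep,
                 ann$total_duration)
  })
}

#' Default heterogeneous cohort of listener models
#'
#' Per-listener hit probabilities and false-alarm rates are drawn from
#' wide uniform ranges (Level 1 stochastically higher than Level 2, as
#' observed for section vs phrase boundaries), producing cohorts whose
#' click counts span roughly 0-50 per listening.
#'
#' @param n cohort size (default 32, one study group).
#' @param seed integer seed for the parameter draws.
#' @param ... overrides passed to every [listener_model()] (fixed across
#'   the cohort, e.g. `fa_rate = 0`).
#' @return List of `n` `listener_model`s with ids `P01, P02, ...`.
#' @export
default_cohort <- function(n = 32, seed = 1, ...) {
  fixed <- list(...)
  lapply(seq_len(n), function(i) {
    id <- sprintf("P%02d", i)
    # per-listener parameter stream: extending the cohort never changes
    # the models (nor, downstream, the streams) of existing listeners
    set.seed(listener_seed(seed, paste0("model-", id)))
    args <- list(p_hit_L1 = runif(1, 0.45, 1),
                 p_hit_L2 = runif(1, 0.2, 0.9),
                 fa_rate = runif(1, 0, 0.06), participant_id = id)
    do.call(listener_model, modifyList(args, fixed))
  })
}

#' Simulate a cohort of listeners
#'
#' Each listener contributes two repetitions, generated from an RNG
#' stream seeded by `(seed, participant_id)` so that the cohort
#' composition never perturbs individual streams.  Musicianship
#' covariates (years of training, weekly practice hours) are drawn
#' independently of the performance parameters, matching a null
#' training effect by construction.
#'
#' @param models list of [listener_model()]s.
#' @param ann the recording's [annotation_set()].
#' @param seed cohort seed (integer).
#' @param n_reps listenings per participant (default 2).
#' @return List with `clicks` (cohort click table), `participants`
#'   (covariate table with `participant_id`, `group`, `years_training`,
#'   `weekly_hours`) and `models` (the generating truth).
#' @export
simulate_cohort <- function(models, ann, seed = 1, n_reps = 2) {
  stopifnot(length(models) >= 1)
  rows <- list()
  for (m in models) {
    streams <- simulate_listener(m, ann, n_reps,
                                 seed = listener_seed(seed,
                                                      m$participant_id))
    for (st in streams)
      rows[[length(rows) + 1L]] <-
        if (length(st$times))
          data.frame(participant_id = st$participant_id,
                     recording_id = st$recording_id,
                     repetition = st$repetition, time_s = st$times,
                     stringsAsFactors = FALSE)
        else NULL
  }
  clicks <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(clicks))
    clicks <- data.frame(participant_id = character(0),
                         recording_id = character(0),
                         repetition = integer(0), time_s = numeric(0))
  ids <- vapply(models, `[[`, "", "participant_id")
  set.seed(listener_seed(seed, "covariates"))
  participants <- data.frame(
    participant_id = ids,
    group = ann$recording_id,
    years_training = round(pmin(pmax(rnorm(length(ids), 8.5, 6.5), 0),
                                20), 1),
    weekly_hours = round(pmin(pmax(rnorm(length(ids), 6, 6.9), 0), 30),
                         1),
    stringsAsFactors = FALSE)
  list(clicks = clicks, participants = participants, models = models)
}

#' Recover generating parameters from simulated clicks
#'
#' Estimates the pooled hit probability per level (as the cohort mean
#' per-region hit rate), the mean promptness per level (mean first-click
#' promptness), and the false-alarm rate (false alarms per second of
#' interstitial time), and reports absolute errors against the
#' generating models.
#'
#' @param clicks cohort click table from [simulate_cohort()].
#' @param ann the annotation set used for simulation.
#' @param models the generating `listener_model`s (the truth).
#' @return data.frame with columns `parameter`, `truth`, `estimate`,
#'   `abs_error`.
#' @export
recover_parameters <- function(clicks, ann, models) {
  partition <- build_partition(ann)
  n_streams <- 0L
  hits1 <- hits2 <- 0L
  prompt1 <- prompt2 <- numeric(0)
  fa_count <- 0L
  n1 <- length(level_segments(partition, 1L))
  n2 <- length(level_segments(partition, 2L))
  inter_time <- sum(partition$duration[interstitial_segments(partition)])
  ids <- vapply(models, `[[`, "", "participant_id")
  for (p in ids) {
    for (r in 1:2) {
      t_pr <- clicks$time_s[clicks$participant_id == p &
                              clicks$repetition == r]
      st <- click_stream(t_pr, p, ann$recording_id, r,
                         ann$total_duration)
      sc <- classify_clicks(st, partition)
      n_streams <- n_streams + 1L
      hits1 <- hits1 + sum(sc$first_in_region & sc$class == "L1")
      hits2 <- hits2 + sum(sc$first_in_region & sc$class == "L2")
      prompt1 <- c(prompt1, sc$promptness[sc$first_in_region &
                                            sc$class == "L1"])
      prompt2 <- c(prompt2, sc$promptness[sc$first_in_region &
                                            sc$class == "L2"])
      fa_count <- fa_count + sum(sc$klass == "false_alarm")
    }
  }
  truth_mean <- function(field)
    mean(vapply(models, `[[`, numeric(1), field))
  beta_mean <- function(field) {
    sh <- vapply(models, `[[`, numeric(2), field)
    mean(sh[1, ] / colSums(sh))
  }
  est <- c(p_hit_L1 = hits1 / (n1 * n_streams),
           p_hit_L2 = hits2 / (n2 * n_streams),
           mean_promptness_L1 = mean(prompt1),
           mean_promptness_L2 = mean(prompt2),
           fa_rate = fa_count / (inter_time * n_streams))
  truth <- c(p_hit_L1 = truth_mean("p_hit_L1"),
             p_hit_L2 = truth_mean("p_hit_L2"),
             mean_promptness_L1 = beta_mean("prompt_shape_L1"),
             mean_promptness_L2 = beta_mean("prompt_shape_L2"),
             fa_rate = truth_mean("fa_rate"))
  data.frame(parameter = names(est), truth = unname(truth),
             estimate = unname(est),
             abs_error = unname(abs(est - truth)),
             stringsAsFactors = FALSE)
}
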