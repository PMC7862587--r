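# Pipeline layer: configuration, the score -> densities -> statistics
# chain, report assembly (stats.json) and reproducibility sidecars.

#' Pipeline run configuration
#'
#' Collects every tunable of the scoring pipeline with the canonical
#' defaults: linear promptness, one false-alarm trial per interstitial
#' segment, exclusive level counting, 1 s histogram bins, median as the
#' cohort central tendency, no multiplicity adjustment.
#'
#' @param promptness_mode,promptness_c see [promptness_config()].
#' @param far_trial_mode see [false_alarm_rate()].
#' @param level_mode see [hit_rate()].
#' @param bin_width histogram bin width, seconds.
#' @param central `"median"` (robust, canonical) or `"mean"`.
#' @param adjust `"none"` (canonical: follow-ups reported unadjusted) or
#'   `"holm"` for Holm-adjusted follow-up families.
#' @param dip_n_boot bootstrap replicates for the dip test.
#' @param seed integer seed for stochastic battery components.
#' @return Object of class `run_config`.
#' @export
run_config <- function(promptness_mode = "linear", promptness_c = 0.5,
                       far_trial_mode = "per_segment",
                       level_mode = "exclusive", bin_width = 1,
                       central = c("median", "mean"),
                       adjust = c("none", "holm"),
                       dip_n_boot = 1000, seed = 1) {
  central <- match.arg(central)
  adjust <- match.arg(adjust)
  structure(list(promptness_mode = promptness_mode,
                 promptness_c = promptness_c,
                 far_trial_mode = far_trial_mode,
                 level_mode = level_mode, bin_width = bin_width,
                 central = central, adjust = adjust,
                 dip_n_boot = dip_n_boot, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  do.call(run_config, yaml::read_yaml(path))
}

# Order-independent rolling hash of the configuration, recorded in
# every output sidecar.
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_sidecar <- function(path, config, extra = list()) {
  meta <- c(list(tool = "segbound",
                 version = as.character(packageVersion("segbound")),
                 config_hash = config_hash(unclass(config)),
                 seed = config$seed,
                 created = "run-time"),
            extra)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

central_fun <- function(config)
  if (config$central == "median") median else mean

#' Score a cohort and write the scoring outputs
#'
#' Runs the scoring stage end to end: reads (or accepts) the click table
#' and annotations, computes per-participant scores for both listenings
#' plus their average, and pooled per-region densities; optionally
#' writes `scores.csv` and `densities.csv` with reproducibility
#' sidecars.
#'
#' @param clicks click table or CSV path.
#' @param annotations an `annotation_set` or annotation CSV path.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param config a [run_config()].
#' @return List with `scores`, `densities`, `histogram` and the paths
#'   written (if any).
#' @export
run_scoring <- function(clicks, annotations, out_dir = NULL,
                        config = run_config()) {
  if (is.character(clicks)) clicks <- read_clicks(clicks)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  stopifnot(inherits(annotations, "annotation_set"))
  pconf <- promptness_config(config$promptness_mode,
                             c = config$promptness_c)
  scores <- score_cohort(clicks, annotations,
                         level_mode = config$level_mode,
                         trial_mode = config$far_trial_mode,
                         config = pconf)
  partition <- build_partition(annotations)
  densities <- region_densities(clicks, partition)
  histogram <- click_histogram(clicks, annotations$total_duration,
                               config$bin_width)
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sp <- file.path(out_dir, "scores.csv")
    dp <- file.path(out_dir, "densities.csv")
    write.csv(scores, sp, row.names = FALSE, quote = FALSE)
    write.csv(densities, dp, row.names = FALSE, quote = FALSE)
    write_sidecar(sp, config,
                  list(recording_id = annotations$recording_id,
                       n_rows = nrow(scores),
                       n_participants =
                         length(unique(scores$participant_id))))
    write_sidecar(dp, config,
                  list(recording_id = annotations$recording_id,
                       n_rows = nrow(densities),
                       n_clicks = sum(densities$click_count)))
    paths <- c(scores = sp, densities = dp)
  }
  list(scores = scores, densities = densities, histogram = histogram,
       paths = paths)
}

# Serialise one stat_result (or a skip record) for stats.json.
result_record <- function(name, res, provenance = NULL) {
  if (inherits(res, "stat_result")) {
    list(id = name, test = res$test_name,
         statistic = unname(res$statistic[1]),
         statistic_name = names(res$statistic)[1],
         df = res$df, p_value = res$p_value,
         effect_size = res$effect_size,
         effect_ci = res$effect_ci, n = res$n, note = res$note,
         seed = res$seed, provenance = provenance, skipped = FALSE)
  } else {
    list(id = name, skipped = TRUE, reason = as.character(res),
         provenance = provenance)
  }
}

try_test <- function(expr) tryCatch(expr, error = function(e)
  conditionMessage(e))

#' Run the inferential battery and assemble the stats report
#'
#' Applies the study's battery, in order, to one or two scored cohorts:
#' KS normality screens, Kruskal-Wallis across region types and
#' hierarchy levels, pairwise Wilcoxon contrasts (signed-rank within
#' recording, rank-sum across recordings), the recording x level
#' promptness ANOVA with simple effects, dip tests of promptness
#' unimodality, and musicianship correlations.  A test whose
#' preconditions fail is recorded as skipped with the reason, never
#' dropped silently.
#'
#' @param scoring one result of [run_scoring()], or a named list of two
#'   (one per recording) to enable the cross-recording tests.
#' @param participants optional covariate table(s) with
#'   `participant_id`, `years_training`, `weekly_hours` (and `group`);
#'   enables the musicianship correlations.
#' @param out path for `stats.json`, or `NULL` to skip writing.
#' @param config a [run_config()].
#' @return List of result records (invisibly the JSON structure).
#' @export
run_stats <- function(scoring, participants = NULL, out = NULL,
                      config = run_config()) {
  single <- !is.null(scoring$scores)
  runs <- if (single) stats::setNames(list(scoring), "recording")
          else scoring
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- paste0("recording", seq_along(runs))
  res <- list()
  add <- function(name, value, prov = NULL)
    res[[length(res) + 1L]] <<- result_record(name, value, prov)

  avg <- lapply(runs, function(r)
    r$scores[r$scores$scope == "averaged", , drop = FALSE])

  ## 1. normality screens + Kruskal-Wallis over region-type densities
  for (rec in names(runs)) {
    dens <- runs[[rec]]$densities
    add(paste0("density_normality_", rec),
        try_test(ks_normality(dens$density)), rec)
    add(paste0("density_kruskal_", rec), try_test(
      kruskal_wallis(list(L1 = dens$density[dens$class == "L1"],
                          L2 = dens$density[dens$class == "L2"],
                          interstitial =
                            dens$density[dens$class == "interstitial"]))),
      rec)
    ## 2. pairwise density contrasts
    follow <- list(
      L1_vs_interstitial = c("L1", "interstitial"),
      L2_vs_interstitial = c("L2", "interstitial"),
      L1_vs_L2 = c("L1", "L2"))
    fam <- list()
    for (cn in names(follow)) {
      pr <- pair_densities(dens, follow[[cn]])
      r <- try_test({
        sr <- wilcoxon_signed_rank(pr$x, pr$y)
        sr$note <- paste(sr$note, "; pairing:", pr$scheme)
        sr
      })
      fam[[cn]] <- r
      add(paste0("density_signedrank_", cn, "_", rec), r, rec)
    }
    if (config$adjust == "holm") {
      ps <- vapply(fam, function(r)
        if (inherits(r, "stat_result")) r$p_value else NA_real_, 0)
      adj <- stats::p.adjust(ps, "holm")
      for (i in seq_along(adj))
        res[[length(res) + 1L]] <- list(
          id = paste0("density_signedrank_", names(fam)[i], "_", rec,
                      "_holm"),
          p_value = unname(adj[i]), note = "Holm-adjusted",
          skipped = is.na(adj[i]))
    }
  }

  ## 3. hit-rate level effect within recording
  for (rec in names(runs)) {
    a <- avg[[rec]]
    add(paste0("hr_normality_", rec),
        try_test(ks_normality(c(a$HR_L1, a$HR_L2))), rec)
    add(paste0("hr_kruskal_level_", rec),
        try_test(kruskal_wallis(list(L1 = a$HR_L1, L2 = a$HR_L2))), rec)
    add(paste0("hr_signedrank_level_", rec),
        try_test(wilcoxon_signed_rank(a$HR_L1, a$HR_L2)), rec)
  }

  ## 4. cross-recording contrasts
  if (length(runs) == 2) {
    a1 <- avg[[1]]; a2 <- avg[[2]]
    for (lv in c("HR_L1", "HR_L2"))
      add(paste0("hr_ranksum_", lv),
          try_test(wilcoxon_rank_sum(a1[[lv]], a2[[lv]])),
          paste(names(runs), collapse = " vs "))
    for (cls in c("L1", "L2", "interstitial")) {
      d1 <- runs[[1]]$densities
      d2 <- runs[[2]]$densities
      add(paste0("density_ranksum_", cls),
          try_test(wilcoxon_rank_sum(d1$density[d1$class == cls],
                                     d2$density[d2$class == cls])),
          paste(names(runs), collapse = " vs "))
    }
    ## 5. promptness ANOVA
    long <- do.call(rbind, lapply(names(runs), function(rec) {
      a <- avg[[rec]]
      rbind(data.frame(participant = a$participant_id, raga = rec,
                       level = "L1", score = a$cum_promptness_L1),
            data.frame(participant = a$participant_id, raga = rec,
                       level = "L2", score = a$cum_promptness_L2))
    }))
    an <- try_test(factorial_anova(long))
    if (is.list(an) && !inherits(an, "stat_result")) {
      for (nm in names(an))
        add(paste0("promptness_anova_", nm), an[[nm]],
            paste(names(runs), collapse = " x "))
    } else add("promptness_anova", an)
  }

  ## 6. promptness dip tests (unimodality of response styles)
  set.seed(config$seed)
  null_cache <- new.env()
  for (rec in names(runs)) {
    a <- avg[[rec]]
    for (lv in c("L1", "L2")) {
      v <- a[[paste0("cum_promptness_", lv)]]
      v <- v[!is.na(v)]
      key <- as.character(length(v))
      r <- try_test({
        if (is.null(null_cache[[key]]))
          null_cache[[key]] <-
            dip_null_distribution(length(v), config$dip_n_boot)
        sr <- hartigan_dip(v, null_dips = null_cache[[key]])
        sr$seed <- config$seed
        sr
      })
      add(paste0("promptness_dip_", lv, "_", rec), r, rec)
    }
  }

  ## 7. musicianship correlations
  if (!is.null(participants)) {
    pt <- if (is.data.frame(participants)) participants
          else do.call(rbind, participants)
    if (!"group" %in% names(pt)) pt$group <- "all"
    mus <- try_test(musicianship_score(pt$years_training,
                                       pt$weekly_hours, pt$group))
    for (rec in names(runs)) {
      a <- avg[[rec]]
      if (is.data.frame(mus)) {
        m <- mus$musicianship[match(a$participant_id,
                                    pt$participant_id)]
        for (v in c("d_prime", "cum_promptness_L1",
                    "cum_promptness_L2", "HR_all", "FAR"))
          add(paste0("musicianship_corr_", v, "_", rec),
              try_test(pearson_corr(m, a[[v]])), rec)
      } else {
        add(paste0("musicianship_corr_", rec), mus, rec)
      }
    }
  }

  report <- list(tool = "segbound",
                 version = as.character(packageVersion("segbound")),
                 config_hash = config_hash(unclass(config)),
                 seed = config$seed,
                 central_tendency = config$central,
                 results = res)
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  }
  invisible(report)
}

#' Simulate a synthetic dataset and write it to disk
#'
#' Wraps [gen_annotation()], [default_cohort()] and [simulate_cohort()]:
#' generates (or loads) an annotation timeline, simulates a cohort, and
#' writes `annotations.csv`, `clicks.csv`, `participants.csv` and
#' `truth.json` (generating parameters and seeds) with sidecars.
#'
#' @param out_dir output directory.
#' @param preset `"tori"`, `"multani"`, or an [annotation_gen_config()].
#' @param n_listeners cohort size.
#' @param config a [run_config()]; its seed drives all draws.
#' @param models optional explicit list of [listener_model()]s.
#' @return List with `annotation`, `cohort` and written `paths`.
#' @export
run_simulation <- function(out_dir = NULL, preset = "tori",
                           n_listeners = 32, config = run_config(),
                           models = NULL) {
  gcfg <- if (inherits(preset, "annotation_gen_config")) preset
          else switch(preset, tori = tori_config(),
                      multani = multani_config(),
                      stop("unknown preset: ", preset))
  rec_id <- if (is.character(preset)) preset else "synthetic"
  ann <- gen_annotation(gcfg, recording_id = rec_id,
                        seed = config$seed)
  if (is.null(models))
    models <- default_cohort(n_listeners, seed = config$seed + 1)
  cohort <- simulate_cohort(models, ann, seed = config$seed + 2)
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ap <- file.path(out_dir, "annotations.csv")
    cp <- file.path(out_dir, "clicks.csv")
    pp <- file.path(out_dir, "participants.csv")
    tp <- file.path(out_dir, "truth.json")
    write_annotations(ann, ap)
    write_clicks(cohort$clicks, cp)
    write.csv(cohort$participants, pp, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           annotation_config = unclass(gcfg),
           models = lapply(models, unclass)),
      tp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    for (f in c(ap, cp, pp))
      write_sidecar(f, config, list(recording_id = rec_id))
    paths <- c(annotations = ap, clicks = cp, participants = pp,
               truth = tp)
  }
  list(annotation = ann, cohort = cohort, paths = paths)
}

#' Path to a packaged example data file
#'
#' The package ships two synthetic annotation fixtures shaped like the
#' study recordings (Torī-like: 6 L1 + 13 L2; Multānī-like: 7 L1 +
#' 27 L2, durations inside the observed ranges) and a small demo cohort.
#' These are synthetic stand-ins generated by [gen_annotation()] at a
#' fixed seed, not the study's own data.
#'
#' @param file file name, e.g. `"tori_annotations.csv"`; empty to list
#'   available files.
#' @return Full path (or vector of file names).
#' @export
segbound_example <- function(file = "") {
  if (file == "")
    return(dir(system.file("extdata", package = "segbound")))
  p <- system.file("extdata", file, package = "segbound")
  if (p == "") stop("no packaged file called '", file, "'")
  p
}
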