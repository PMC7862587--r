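# Click classification, SDT rates, d', promptness and the derived
# participant/region scores.

simple_ann <- function() annotation_set(
  data.frame(region_id = c("a", "b"), level = c(1, 2),
             t_start = c(5, 12), t_end = c(9, 16)),
  recording_id = "rec", total_duration = 20)

test_that("clicks are classified by containment with half-open bounds", {
  ann <- simple_ann()
  p <- build_partition(ann)
  st <- click_stream(c(4.999, 6.0, 7.0, 9.0, 13.0), "P1", "rec", 1, 20)
  sc <- classify_clicks(st, p)
  expect_equal(sc$klass,
               c("false_alarm", "hit", "hit", "false_alarm", "hit"))
  expect_equal(sc$first_in_region, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_true(is.na(sc$promptness[3]))   # only first click scores
  expect_false(is.na(sc$promptness[2]))
  expect_equal(sum(sc$klass == "hit") + sum(sc$klass == "false_alarm"),
               nrow(sc))
  expect_error(classify_clicks(click_stream(21, "P1", "rec", 1), p),
               "outside")
  expect_error(
    classify_clicks(click_stream(1, "P1", "other", 1), p),
    "mismatch")
})

test_that("hit and false-alarm rates are binary per-region trials", {
  n_reg <- 13
  ann <- many_region_ann(n_reg)
  p <- build_partition(ann)
  hit_regions <- which(p$class == "L2")[1:9]
  times <- p$t_start[hit_regions] + 0.5
  # duplicate clicks inside one region must not change the rate
  times2 <- c(times, times[1] + 0.1, times[1] + 0.2)
  for (tt in list(times, times2)) {
    sc <- classify_clicks(click_stream(tt, "P", "many", 1), p)
    expect_equal(hit_rate(sc, p, level = 2), 9 / 13)
  }
  sc_none <- classify_clicks(click_stream(numeric(0), "P", "many", 1), p)
  expect_equal(hit_rate(sc_none, p, level = 2), 0)
  expect_equal(false_alarm_rate(sc_none, p), 0)
  all_hits <- classify_clicks(
    click_stream(p$t_start[p$class == "L2"] + 0.1, "P", "many", 1), p)
  expect_equal(hit_rate(all_hits, p, level = 2), 1)
  expect_error(hit_rate(all_hits, p, level = 1), "no regions")

  inter <- which(p$class == "interstitial")
  sc_fa <- classify_clicks(
    click_stream(p$t_start[inter[1:3]] + 0.5, "P", "many", 1), p)
  expect_equal(false_alarm_rate(sc_fa, p), 3 / length(inter))
  sc_all_fa <- classify_clicks(
    click_stream(p$t_start[inter] + 0.5, "P", "many", 1), p)
  expect_equal(false_alarm_rate(sc_all_fa, p), 1)
})

test_that("inclusive level counting folds L1 regions into Level 2", {
  ann <- simple_ann()
  p <- build_partition(ann)
  sc <- classify_clicks(click_stream(c(6, 13), "P1", "rec", 1, 20), p)
  expect_equal(hit_rate(sc, p, 2, level_mode = "exclusive"), 1)
  expect_equal(hit_rate(sc, p, 2, level_mode = "inclusive"), 1)
  sc1 <- classify_clicks(click_stream(6, "P1", "rec", 1, 20), p)
  expect_equal(hit_rate(sc1, p, 2, level_mode = "exclusive"), 0)
  expect_equal(hit_rate(sc1, p, 2, level_mode = "inclusive"), 1 / 2)
})

test_that("fixed-window false-alarm trials weight long interstitials", {
  ann <- simple_ann()                      # interstitials: 5, 3, 4 s
  p <- build_partition(ann)
  sc <- classify_clicks(click_stream(c(1, 2), "P1", "rec", 1, 20), p)
  expect_equal(false_alarm_rate(sc, p), 1 / 3)
  # with 2 s windows: ceiling(5/2)+ceiling(3/2)+ceiling(4/2) = 7 trials,
  # clicks at 1 and 2 fall in 2 distinct windows of the first segment
  expect_equal(false_alarm_rate(sc, p, "fixed_window", window = 2),
               2 / 7)
})

test_that("d' matches the probit oracle and stays finite at the extremes", {
  oracle <- function(hr, far) probit_bisect(hr) - probit_bisect(far)
  expect_equal(d_prime(0.8, 0.2), oracle(0.8, 0.2), tolerance = 1e-6)
  expect_equal(d_prime(0.8, 0.2), 1.683242, tolerance = 1e-6)
  expect_equal(d_prime(0.37, 0.37), 0)
  corrected <- d_prime(1, 0, n_signal = 10, n_noise = 10)
  expect_true(is.finite(corrected))
  expect_equal(corrected, oracle(1 - 1 / 20, 1 / 20), tolerance = 1e-6)
  expect_error(d_prime(0.5, 0.2, n_signal = -1), "\\[0, 1\\]|negative")
  expect_error(d_prime(1, 0.2, n_signal = -1), "negative")
  expect_error(d_prime(1.2, 0.2), "\\[0, 1\\]")
})

test_that("d' increases in HR and decreases in FAR after correction", {
  hrs <- seq(0, 1, by = 0.1)
  d_hr <- vapply(hrs, function(h) d_prime(h, 0.3, 10, 10), 0)
  expect_true(all(diff(d_hr) > 0))
  d_far <- vapply(hrs, function(f) d_prime(0.7, f, 10, 10), 0)
  expect_true(all(diff(d_far) < 0))
})

test_that("promptness is 1 at onset, 0.5 at midpoint, 0 toward the end", {
  expect_equal(promptness_score(10, 10, 14), 1)
  expect_equal(promptness_score(12, 10, 14), 0.5)
  expect_equal(promptness_score(14 - 1e-9, 10, 14), 0,
               tolerance = 1e-8)
  expect_error(promptness_score(9.9, 10, 14), "outside")
  # reciprocal mode shares the endpoints and is monotone decreasing
  rc <- promptness_config("reciprocal", c = 0.5)
  expect_equal(promptness_score(10, 10, 14, rc), 1)
  expect_equal(promptness_score(14 - 1e-9, 10, 14, rc), 0,
               tolerance = 1e-7)
  ts <- seq(10, 13.99, by = 0.01)
  expect_true(all(diff(promptness_score(ts, 10, 14, rc)) < 0))
  # reciprocal falls off faster than linear early in the region
  expect_lt(promptness_score(11, 10, 14, rc),
            promptness_score(11, 10, 14))
})

test_that("promptness is invariant to shifting and scaling the timeline", {
  set.seed(5)
  for (i in 1:1000) {
    t0 <- runif(1, 0, 100)
    dur <- runif(1, 0.5, 10)
    u <- runif(1)
    click <- t0 + u * dur * 0.999
    shift <- runif(1, -50, 50)
    scale <- runif(1, 0.1, 10)
    p0 <- promptness_score(click, t0, t0 + dur)
    p1 <- promptness_score(click + shift, t0 + shift, t0 + dur + shift)
    p2 <- promptness_score(click * scale, t0 * scale,
                           (t0 + dur) * scale)
    expect_equal(p1, p0, tolerance = 1e-9)
    expect_equal(p2, p0, tolerance = 1e-9)
  }
})

test_that("cumulative promptness normalises by the region count", {
  ann <- many_region_ann(5)
  p <- build_partition(ann)
  # hits at the very start of region 1 (promptness 1) and the midpoint
  # of region 2 (promptness 0.5)
  l2 <- which(p$class == "L2")
  st <- click_stream(c(p$t_start[l2[1]],
                       (p$t_start[l2[2]] + p$t_end[l2[2]]) / 2),
                     "P", "many", 1)
  sc <- classify_clicks(st, p)
  expect_equal(cumulative_promptness(sc, 2, 5), 0.3)
  sc0 <- classify_clicks(click_stream(numeric(0), "P", "many", 1), p)
  expect_equal(cumulative_promptness(sc0, 2, 5), 0)
  all_start <- classify_clicks(
    click_stream(p$t_start[l2], "P", "many", 1), p)
  expect_equal(cumulative_promptness(all_start, 2, 5), 1)
  expect_error(cumulative_promptness(sc, 2, 0), "undefined")
})

test_that("averaging repetitions recomputes d' from mean rates", {
  ann <- simple_ann()
  p <- build_partition(ann)
  s1 <- participant_scores(click_stream(c(6, 13), "P1", "rec", 1, 20), p)
  s2 <- participant_scores(click_stream(6, "P1", "rec", 2, 20), p)
  avg <- average_over_repetitions(s1, s2)
  expect_equal(avg$scope, "averaged")
  expect_equal(avg$HR_L2, (s1$HR_L2 + s2$HR_L2) / 2)
  expect_equal(avg$d_prime,
               d_prime((s1$HR_all + s2$HR_all) / 2,
                       (s1$FAR + s2$FAR) / 2, 2, 3))
  # identical repetitions leave the scores unchanged
  s2b <- s1; s2b$scope <- "rep2"
  same <- average_over_repetitions(s1, s2b)
  expect_equal(same$HR_all, s1$HR_all)
  expect_equal(same$d_prime, s1$d_prime)
  expect_error(average_over_repetitions(s1, s1), "scope")
  expect_error(average_over_repetitions(s1, NULL), "required")
  s3 <- s2; s3$participant_id <- "P9"
  expect_error(average_over_repetitions(s1, s3), "different")
})

test_that("every click lands in exactly one tally: hits + false alarms", {
  set.seed(11)
  for (i in 1:30) {
    ann <- random_ann(n = sample(3:10, 1))
    p <- build_partition(ann)
    st <- random_stream(ann, n = sample(0:40, 1))
    sc <- classify_clicks(st, p)
    expect_equal(sum(sc$klass == "hit") + sum(sc$klass == "false_alarm"),
                 length(st$times))
    # segment assignment is a function: one segment per click
    expect_true(all(sc$segment >= 1 & sc$segment <= nrow(p)))
  }
})

test_that("region densities equal a brute-force per-click count", {
  set.seed(21)
  for (i in 1:20) {
    ann <- random_ann(n = sample(3:8, 1))
    p <- build_partition(ann)
    times <- runif(50, 0, ann$total_duration - 1e-9)
    dens <- region_densities(times, p)
    brute <- vapply(seq_len(nrow(p)), function(s)
      sum(times >= p$t_start[s] & times < p$t_end[s]), 0)
    expect_equal(dens$click_count, as.integer(brute))
    expect_equal(dens$density, brute / p$duration)
  }
  # linearity: doubling the clicks doubles every density
  ann <- random_ann(3)
  p <- build_partition(ann)
  times <- runif(30, 0, ann$total_duration - 1e-9)
  d1 <- region_densities(times, p)
  d2 <- region_densities(c(times, times), p)
  expect_equal(d2$density, 2 * d1$density)
})

test_that("click histograms conserve counts and keep the partial bin", {
  h <- click_histogram(c(0.5, 1.5, 1.9), total_duration = 3.5)
  expect_equal(h$count, c(1L, 2L, 0L, 0L))
  expect_equal(h$bin_end[nrow(h)], 3.5)
  expect_error(click_histogram(1, 10, bin_width = 0), "positive")
  one <- click_histogram(c(0.5, 3), 10, bin_width = 10)
  expect_equal(nrow(one), 1)
  expect_equal(one$count, 2L)
  set.seed(3)
  for (i in 1:10) {
    total <- runif(1, 5, 50)
    times <- runif(sample(1:60, 1), 0, total - 1e-9)
    bw <- runif(1, 0.3, 4)
    expect_equal(sum(click_histogram(times, total, bw)$count),
                 length(times))
  }
})

test_that("musicianship composite is a within-group z average", {
  years <- c(2, 4, 6, 10, 20, 3)
  hours <- c(1, 3, 5, 9, 12, 2)
  grp <- c(rep("tori", 5), "tori")
  m <- musicianship_score(years, hours, grp)
  expect_equal(mean(m$musicianship), 0, tolerance = 1e-12)
  # participant exactly at both group means scores 0
  years2 <- c(0, 10, 20, 10)
  hours2 <- c(0, 5, 10, 5)
  m2 <- musicianship_score(years2, hours2, rep("g", 4))
  expect_equal(m2$musicianship[c(2, 4)], c(0, 0))
  # one SD above on years, at the mean on hours -> 0.5
  y4 <- c(8, 10, 12)            # mean 10, sd 2
  h4 <- c(4, 5, 6)              # mean 5, sd 1
  m4 <- musicianship_score(c(y4, 12), c(h4, 5), rep("g", 4))
  z_y <- (12 - mean(c(y4, 12))) / sd(c(y4, 12))
  z_h <- (5 - mean(c(h4, 5))) / sd(c(h4, 5))
  expect_equal(m4$musicianship[4], (z_y + z_h) / 2)
  # missing one measure: available z used, flagged
  m5 <- musicianship_score(c(1, 5, 9), c(2, NA, 6), rep("g", 3))
  expect_true(m5$partial[2])
  expect_equal(m5$musicianship[2], m5$z_years[2])
  expect_error(musicianship_score(c(3, 3, 3), c(1, 2, 3), rep("g", 3)),
               "zero variance.*years.*g")
})

test_that("zero-click participants are scored with a warning", {
  ann <- simple_ann()
  clicks <- data.frame(participant_id = "P1", recording_id = "rec",
                       repetition = 1L, time_s = 6)
  expect_warning(sc <- score_cohort(clicks, ann), "zero clicks")
  r2 <- sc[sc$scope == "rep2", ]
  expect_equal(r2$HR_all, 0)
  expect_equal(r2$FAR, 0)
  expect_equal(nrow(sc), 3)   # rep1, rep2, averaged
  expect_error(score_cohort(transform(clicks, recording_id = "zzz"),
                            ann),
               "mismatch.*zzz.*rec")
})
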