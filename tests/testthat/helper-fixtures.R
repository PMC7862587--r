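# Random fixtures for property-style tests, built directly (not through
# the package's own generator) so they exercise the data model
# independently.

random_ann <- function(seed = NULL, n = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- sample(3:12, 1)
  durs <- runif(n, 0.5, 8)
  gaps <- runif(n + 1, 0, 6)
  gaps[sample(n + 1, sample(0:2, 1))] <- 0    # exercise adjacency
  starts <- cumsum(gaps)[1:n] + c(0, cumsum(durs))[1:n]
  annotation_set(
    data.frame(region_id = sprintf("r%d", 1:n),
               level = sample(1:2, n, replace = TRUE),
               t_start = starts, t_end = starts + durs),
    recording_id = "rand",
    total_duration = sum(durs) + sum(gaps))
}

random_stream <- function(ann, n = 30, rep = 1, pid = "P1") {
  click_stream(runif(n, 0, ann$total_duration - 1e-6), pid,
               ann$recording_id, rep, ann$total_duration)
}

# An annotation set of n_regions identical regions at one level, for
# high-precision recovery checks.
many_region_ann <- function(n_regions, level = 2L, dur = 3, gap = 2) {
  starts <- gap + (0:(n_regions - 1)) * (dur + gap)
  annotation_set(
    data.frame(region_id = sprintf("r%d", seq_len(n_regions)),
               level = level, t_start = starts, t_end = starts + dur),
    recording_id = "many",
    total_duration = n_regions * (dur + gap) + gap)
}
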