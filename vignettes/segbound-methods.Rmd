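---
title: "Scoring boundary-segmentation click experiments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring boundary-segmentation click experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segbound)
```

## The measurement problem

In a real-time segmentation experiment, listeners press a key ("click")
whenever they feel a phrase has just ended, while an expert analysis of
the same recording provides *boundary regions*: the interval between the
onset of the last melodic pitch of one phrase and the first of the next.
Boundary regions form a two-level hierarchy — Level 1 regions close
larger sections (returns to scale degree 1 in an ālāp performance),
Level 2 regions close phrases within sections.  A section end is de
facto also a phrase end, so the package stores regions *exclusively* (a
region carries its highest level; per-level counts then add up) and
offers an `inclusive` counting mode where Level 2 means "Level 1 or
Level 2".

Everything downstream is defined on the **timeline partition**: the
boundary regions plus the complementary *interstitial* segments, a
contiguous cover of `[0, total_duration)`.  All intervals are half-open
`[t_start, t_end)`, which makes click assignment at shared endpoints
unambiguous; gaps shorter than $10^{-9}$ s are absorbed rather than kept
as degenerate segments.

## Scoring model

Following signal detection theory, a click inside a boundary region is
a *hit*; a click in interstitial space is a *false alarm*.  Clicks
immediately before or after a region are deliberately **not** rescued as
anticipations or late responses — the analysis is about real-time
awareness of grouping completion, so only within-region clicks count.

* **Hit rate** — one binary trial per region: the fraction of regions
  (of a given level) containing at least one click.  Duplicate clicks in
  one region count once.
* **False-alarm rate** — by default, symmetrically, one binary trial per
  interstitial segment.  The exact construction of "signal absent"
  trials is a genuine design choice (interstitial spans vary widely in
  length); an alternative `fixed_window` mode divides interstitial time
  into windows of the mean region duration.  The per-segment rule is the
  default because it mirrors the per-region hit trial exactly and is
  robust to a single very long gap; results produced under either rule
  carry the rule in their configuration hash.
* **Sensitivity** — $d' = z(\mathrm{HR}) - z(\mathrm{FAR})$ with $z$ the
  probit, computed from the *overall* hit rate (all regions, both
  levels).  Rates of exactly 0 or 1 are corrected by the log-linear rule
  ($0 \to 1/2N$, $1 \to 1 - 1/2N$, $N$ the trial count of that type) so
  $d'$ stays finite.
* **Promptness** — for the first click in each region,
  $1 - (t - t_\mathrm{start})/(t_\mathrm{end} - t_\mathrm{start})$:
  1 at the region onset (the listener anticipated the completion), 0 in
  the limit at its end (the listener waited out the gap).  A reciprocal
  variant ($c/(x+c)$, rescaled to hit 1 and 0 at the endpoints,
  `c = 0.5` by default) is available; the linear form is canonical since
  both orderings agree in practice.  *Cumulative promptness* sums the
  first-click promptness over a level's hits and divides by the number
  of regions at that level, giving a `[0, 1]` per-participant awareness
  score.
* **Repetitions** — each listener hears the recording twice.  Rates and
  promptness are averaged across the two listenings; $d'$ is
  *recomputed from the averaged rates*, not averaged itself, because the
  probit is nonlinear.
* **Cohort summaries** use the median, which is robust to the long tail
  of click counts.

Per-region **click densities** pool every click from every listener and
repetition and divide each segment's count by its duration; dense
regions are regions the cohort agrees on.

The **musicianship composite** z-standardises years of training and
weekly practice hours within each recording group and averages the two
z-scores; a participant missing one measure keeps the available z,
flagged.

## The inferential battery

The battery mirrors how such data are analysed: a normality screen
first, then nonparametric tests with effect sizes.

* `ks_normality()` standardises by the sample mean/SD and applies the
  one-sample Kolmogorov–Smirnov test.  Estimating the parameters from
  the same sample makes the classical p value conservative (the
  Lilliefors situation); the result carries that caveat, and
  `p_method = "lilliefors"` gives the calibrated corrected p value.
  The package keeps the conservative variant as the default because it
  is the conventional screen in this literature; it errs only toward
  declaring distributions "normal enough", and the battery proceeds
  nonparametrically regardless.
* `kruskal_wallis()` reports the tie-corrected H with
  $\eta^2 = (H - k + 1)/(n - k)$, clamped at 0.
* `wilcoxon_signed_rank()` uses the *sum of positive ranks* convention,
  drops zero differences, and is exact (signed-rank distribution) up to
  25 untied pairs, switching to a tie-corrected normal approximation
  with continuity correction beyond.  `wilcoxon_rank_sum()` reports the
  first sample's pooled rank sum, exact for small untied samples.
* **Pairing schemes.**  Comparing region-type densities pairwise needs a
  pairing rule because the classes have different sizes.  The default
  pairs each boundary region with the interstitial segment immediately
  following it — the natural "did listeners stop clicking when the
  phrase resumed?" contrast, and the one consistent with all-positive
  rank sums reaching their theoretical maximum on strongly clustered
  data.  For region-vs-region contrasts (L1 vs L2) the fallback pairs in
  timeline order and truncates; both schemes are recorded in the output
  and switchable.  This is an interpretation, and results are labelled
  with the scheme used.
* `factorial_anova()` fits the 2×2 recording × level design on
  cumulative promptness.  The default treats each participant × level
  row as an independent observation (error df $N - 4$), the design
  consistent with the conventional reporting of such tables; a
  `mixed_within_level` variant nests level within participant and tests
  the recording effect against the between-participant stratum.  Effects
  are Type-III (sum-to-zero contrasts) with partial
  $\eta_p^2 = SS_e/(SS_e + SS_{err})$ and a 95% CI obtained by
  inverting the noncentral-F CDF at the observed F (bisection via
  `uniroot`, converted through $\eta^2 = \lambda/(\lambda+df_1+df_2+1)$).
  Simple effects use the pooled error term.
* **Multiple testing**: follow-ups are reported unadjusted, matching
  standard practice for planned contrasts in this design; a Holm option
  exists behind the configuration.

### The dip test

No unimodality test is available among the package's dependencies, so
the dip statistic is implemented from first principles in C++: the
minimal sup-norm distance between the empirical CDF and any unimodal
distribution function (convex before the mode, concave after, an atom
allowed at the mode).  Feasibility of a candidate distance $d$ is
decided per candidate mode knot via the hull criterion — a convex
function fits inside the band $[F_i - d,\; F_{i-1} + d]$ iff the
greatest convex minorant of the upper corners stays above the lower
corners — plus chord-extrapolation bounds for the junction of the two
sides; the statistic is then found by bisection over $d$.  The test
suite validates this implementation against an independent
linear-programming oracle that solves the same minimisation by brute
force over modes (including virtual interior modes).

P values come from a seeded uniform(0,1) bootstrap at the observed
sample size — the asymptotically least-favourable unimodal null — with
the add-one convention $(1 + \#\{d^*_b \ge d\})/(B + 1)$.  Because the
same statistic generates both the observation and its null sample, the
p value is exactly calibrated by construction, which the suite confirms
empirically.  `dip_null_distribution()` lets a battery reuse one null
sample across many tests at the same $n$.

## The synthetic-listener generator

The generator exists so the whole pipeline can be exercised and
validated end to end without the study's raw data.  It emulates the
study conditions:

* **Timelines** shaped like the two recordings: a Torī-like preset
  (6 Level 1 + 13 Level 2 regions, L1 durations 1.8–10.8 s, L2
  1.9–7.3 s) and a Multānī-like preset (7 + 27; 1.3–7.8 s and
  1.3–4.8 s), durations drawn uniformly within those ranges, Level 1
  regions closing sections of Level 2 runs, and interstitial gaps sized
  so the whole performance lasts on the order of five minutes (gap
  ranges 6–14 s and 2.5–8 s respectively).  Those gap ranges are the
  package's own choice — gap statistics are not published — set so that
  expected total region time plus gap time matches the ~300 s
  recordings.
* **Listeners**: each region elicits a click with a per-level hit
  probability; the hit's promptness is Beta-distributed (Level 1
  defaults `Beta(3,2)`, mean 0.6; Level 2 `Beta(2,2)`, mean 0.5 —
  placeholders expressing the observed "sections are detected more
  promptly" direction, not published values); false alarms form a
  homogeneous Poisson process over interstitial time.  The default
  heterogeneous cohort draws per-listener parameters from wide uniform
  ranges (hit probabilities 0.45–1 at Level 1, 0.2–0.9 at Level 2,
  false-alarm rates 0–0.06 s⁻¹), which lands simulated click counts in
  the observed 0–50 per listening and reproduces the observed Level 1 >
  Level 2 hit-rate ordering without forcing it deterministically.
* **Covariates** (years of training, practice hours) are drawn from
  distributions shaped like the cohort demographics but *independently
  of performance*, so the musicianship null effect holds by
  construction.
* **Determinism**: every listener's stream is seeded by a hash of
  (cohort seed, participant id), so the same seed reproduces the same
  CSV byte for byte and extending a cohort never perturbs existing
  listeners.

What passing tests on synthetic cohorts do *not* show: real listeners
are not conditionally independent Bernoulli clickers — they drift in
attention, respond to surface cues the generator does not model, and
produce motor latencies correlated across regions.  The generator
validates the *scoring arithmetic and inferential machinery*, not any
cognitive claim.

## Parameter recovery

`recover_parameters()` closes the loop: per-level hit probabilities are
recovered as pooled per-region hit rates, promptness means as the mean
first-click promptness (exact up to Beta sampling noise because hits
are placed so that their linear promptness *is* the Beta draw, jitter
off by default), and the false-alarm rate as false alarms per second of
interstitial time.  On a 32-listener cohort over the Torī-like fixture
this recovers hit probabilities within ±0.05 (binomial SE ≈ 0.02 at
400–800 trials) and the false-alarm rate within ±20% (Poisson SE ≈ 5%
at ~400 counts), which is what the acceptance checks assert.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite (cohorts of 12–65, 2000-replicate
  calibration loops, 1000-replicate bootstraps) were chosen as the
  smallest sizes at which the Monte-Carlo tolerances above are a small
  multiple of the corresponding standard errors.
* Zero-click listenings are scored (all rates 0, finite corrected d′)
  with a warning, since empty listenings occur in real cohorts.
* Degenerate statistics fail loudly, never silently: zero variance,
  empty groups, all-zero paired differences and missing repetitions are
  errors; the pipeline layer converts them into recorded "skipped"
  entries with reasons in `stats.json`.
* The dip bisection runs 40 iterations on `[0, 0.5]` (precision ≈
  5·10⁻¹³); band comparisons use a 10⁻¹² slack so hull ties do not
  flip feasibility.
* Annotation CSVs round-trip `total_duration` explicitly; a parsed
  region end exceeding the stated duration by < 10⁻⁹ s (text
  serialisation noise) is absorbed rather than rejected.

## Known limitations

* The per-segment false-alarm trial rule and the density pairing scheme
  are documented interpretations of under-specified analysis details;
  both are configurable and recorded in outputs.
* The default ANOVA treats participant × level rows as independent;
  use the mixed variant when the repeated-measures structure matters.
* The dip test's null is the uniform distribution; for very small n the
  uniform null is mildly conservative against peaked unimodal
  alternatives.
* Audacity label tracks carry no recording duration, so reading one
  without `total_duration` treats the last region end as the duration.
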