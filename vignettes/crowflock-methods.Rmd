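---
title: "Methods: mark-resight flock estimation and fission-fusion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mark-resight flock estimation and fission-fusion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowflock)
```

`crowflock` implements an analysis pipeline for a free-ranging,
partially colour-ringed crow population monitored by repeated transect
scans of a bounded urban site (the motivating system is a zoo used by
carrion and hooded crows). The pipeline estimates daily local flock
size by mark-resight correction, classifies marked birds into residency
categories from their sighting histories, detects foraging subgroups
spatially, tests seasonal shifts with a resampling battery, and
quantifies environmental effects with all-subsets count-model
averaging. A bundled agent-based generator produces synthetic sighting
data with ground truth, which is what every quantitative guarantee in
the test suite is evaluated against.

## 1. The mark-resight flock size estimator

Unmarked crows cannot be told apart, so repeated sightings of the same
unmarked bird within a day inflate raw counts. The within-day
resighting ratio of *marked* birds is used as a correction factor,

$$CF = \frac{CM_t - CM_{ind}}{CM_t},$$

where $CM_t$ counts all sightings of marked birds that day (including
resightings across transects) and $CM_{ind}$ the unique marked
individuals. The daily local flock size estimate is

$$FS_e = CM_{ind} + \frac{CU - CU \cdot CF}{T},$$

with $CU$ the unmarked sightings and $T$ the number of transects; the
effort division applies only to the unmarked term because unique marked
individuals are known exactly. The per-transect variant used as the
model response is $CM_{ind,t} + CU_t (1 - CF_{day})$ — the only form
consistent with the daily estimator (the alternative reading,
multiplying by $CF$ rather than $1-CF$, would *keep* the estimated
resightings instead of removing them).

**Bias structure.** Writing $d$ for the probability that a present bird
is seen at least once during a day and $p$ for the per-transect
detection probability, the estimator's expectation is approximately
$N_m d + N_u d / T$ for $N_m$ marked and $N_u$ unmarked birds present.
It is a deliberately *conservative minimum* estimate: the extra $1/T$
on the unmarked term means the estimator approaches the truth only when
detection is high and marked birds dominate. The estimator-recovery
test therefore evaluates it under those conditions — two transects per
day, per-session detection 0.85, 110 marked versus 11 unmarked birds
with identical detection — where the analysis above predicts a mean
relative error of about $-7\%$; the test requires $|\text{mean
relative error}| < 10\%$ over more than 100 days. Under unmarked-heavy
conditions the estimator undershoots by design, which is why no
recovery claim is made there.

**Edge cases.** Days with $CM_t = 0$ have an undefined $CF$; the
study-period mean $CF$ is substituted (and flagged in the output)
rather than dropping the day, keeping the daily series complete.
Unidentifiable marked birds (ring seen, identity not) are real birds of
unknown resighting status: they are excluded from identity-level
analyses but counted with $CU$ for abundance. Only fully identical
duplicate rows of an identified bird are de-duplicated; a bird genuinely
recorded twice in one session is a real resighting. $FS_e$ is kept as a
real number; rounding to integer counts happens once, at the count-model
stage.

## 2. Residency classification

For every identified marked bird we compute three sighting-history
features: days seen, the longest interior period without observation,
and the standard deviation (sample, $n-1$) of those periods. Gaps are
measured in *monitoring* days — days on which at least one transect ran
— because absence is observable only when observers were present;
calendar-day gaps would inflate every bird's gaps by observation
pauses. Leading and trailing censored intervals are excluded by
default (a `censored` flag includes them for sensitivity analyses),
since a bird ringed late or departed early has no observable absence
there.

Birds seen on fewer than 5 days are classified as rare visitors a
priori. The remaining birds are standardised to z-scores and clustered
by complete-linkage agglomeration on Euclidean distances; the tree is
cut at $k = 3$. $k$ is a parameter, not selected automatically: the
original analysis chose well-formed, long-branched clusters by
inspecting the dendrogram, which is not reproducible mechanically, so
the package defaults to the three non-rare categories that inspection
produced. The cluster-to-label mapping is deterministic: descending
mean days seen, ties broken by ascending mean maximum gap, yields
resident, continuous, periodic. Tie handling inside the linkage
follows `stats::hclust`; ties have probability zero on continuous
standardised features, and the brute-force linkage oracle in the test
suite uses continuous data for exactly that reason.

## 3. Subgroup detection

A subgroup is a maximal chain of nonflying birds in which every member
has a neighbour within 5 m with an unobstructed line of sight. The
implementation builds an association graph per session — an edge joins
two sightings when their Euclidean distance is at most the radius
(boundary inclusive, "within 5 m" read as $\le$) and the open segment
between them crosses no barrier — and takes connected components.
Barrier crossing uses strict interior intersection: touching a barrier
endpoint does not block, avoiding degenerate blocking by zero-measure
contacts. Components are computed per session and never span sessions.
Per-record subgroup sizes are size-biased by construction (a bird in a
group of $s$ contributes $s$), matching per-observation count models;
the per-subgroup table is kept alongside for unbiased summaries.

## 4. The seasonal resampling battery

Seasons follow breeding ecology: breeding (February–May), parental
care (June–September), nonbreeder (October–January). Daily
per-category proportions of unique identified birds feed the battery.

Days carry no natural pairing across seasons, so the bootstrap
Friedman and paired Wilcoxon tests pair days *by draw index*: each
iteration draws `sample_size` (default 38, the size of the smallest
season's day pool in the motivating study) day-triplets, one day per
season, and computes the test on the resulting blocks. Results are
reported as mean ± SE of the statistic and of the p-value over
iterations (default 10,000), with significance called by comparing the
mean p to the (Bonferroni-corrected) level.

**Size behaviour, honestly stated.** This battery is a reporting
convention, not a calibrated test, and the package documents both of
its biases. (i) Drawing days *with replacement* duplicates days across
blocks within an iteration, violating the block-independence assumption
of the Friedman statistic, and makes each single iteration
anti-conservative. (ii) Averaging p over many iterations concentrates
the mean away from the tail and makes the mean-p decision strongly
conservative as the iteration count grows. The `replace = FALSE`
variant re-pairs each day exactly once per iteration (a pure pairing
permutation), which keeps every iteration an exact-level test; the
calibration check in the test suite therefore evaluates type-I error
on per-replicate decisions of that variant under an exchangeable null
(1000 replicate datasets with 38 days per season), requiring the
rejection rate at $\alpha = 0.05$ to fall in $[0.03, 0.07]$. The
default (`replace = TRUE`, large `n_boot`, mean-p decision) reproduces
the reporting format of the motivating analysis and errs on the
conservative side.

Per-bird relative days seen (days seen / monitoring days, per season)
are compared with a Monte-Carlo Friedman test — within-block random
permutations generate the reference distribution, with
$p = (1 + \#\{\chi^2_{perm} \ge \chi^2_{obs}\})/(1 + n)$ — and with
exact paired Wilcoxon signed-rank tests. The exact signed-rank null
distribution is computed by shifted convolution over doubled midranks,
which remains exact under ties; zero differences are dropped
(Wilcoxon's original rule, matching the enumeration). Subgroup sizes
across the four categories use a tie-corrected Kruskal–Wallis omnibus
test and all pairwise two-tailed Mann–Whitney U tests at the
Bonferroni level $\alpha = 0.008$.

## 5. All-subsets model averaging

Environmental effects on the per-transect flock size estimate (rounded
to integer) and on subgroup size minus one (the negative binomial
convention for sizes starting at 1) are quantified by fitting *all*
subsets of the candidate fixed terms — $2^5 = 32$ flock models over
{weather, temperature, transect time, season, visitors} and
$2^{10} = 1024$ subgroup models over those plus {number of crows
present, age class, forested area, food, on building} — each as a
log-link count regression with a date-level random intercept (Laplace
approximation via `glmmTMB`; negative binomial dispersion estimated by
maximum likelihood). The flock family is Poisson: no family is
canonical for this response, but an intercept near $\log(\text{flock
size})$ with multiplicative covariate effects implies a log link, and a
Poisson count model is the simplest consistent choice.

Models are ranked by AIC and combined by Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$. The *full*
(zero-substitution) average assigns a term estimate 0 with a model's
weight wherever the term is absent, with the Burnham–Anderson
unconditional standard error
$\sqrt{\sum_i w_i (SE_i^2 + (b_i - \bar b)^2)}$ and a two-sided normal
p-value from $\bar b / SE$. Nonconverged fits (optimiser failure or
non-positive-definite Hessian) are dropped and the weights
renormalised, with a message. AIC (not AICc) is the default to match
the small-sample-uncorrected convention of the motivating analysis.
Reference levels are fixed so reported rows are the non-reference
levels: rain, cold, Morning, nonbreeder season, few visitors, in
forest, on building, juvenile, grass.

Effect recovery is validated against `simulate_model_table()`, which
generates covariates and a Poisson/NB response with known log-linear
coefficients and a date random intercept; the acceptance suite requires
every truly active coefficient's full-average estimate to fall within
±3 unconditional SE of truth at $n = 3000$ records, and inactive terms
to be shrunk relative to their full-model estimates. Agent-level
covariate effects (below) cannot serve that role: a log-linear modifier
of presence or grouping odds does not map one-to-one onto a regression
coefficient of the subgroup-size model, so agent-level injection is
checked only for sign consistency.

## 6. The synthetic data generator

The generator emulates the structure the analysis assumes, not any real
site. A rectangular-zone world (six zones with openness, building and
food attributes; a few sight-blocking wall segments) is monitored two
to three days a week for roughly thirteen months, with two transects a
day in winter and three in summer. The population mixes four residency
archetypes whose daily presence follows simple processes: residents,
daily Bernoulli with high probability (0.75); continuous visitors,
Bernoulli with low probability (0.15); periodic visitors, alternating
on/off blocks with negative-binomial lengths (geometric by default,
means 21/45 days) and Bernoulli presence (0.5) inside on-blocks; rare
visitors, a small number of days spread uniformly, with a site-fidelity
probability (0.25) governing whether a ringed bird ever returns at all
— emulating the large fraction of ringed birds never resighted.
Seasonal multipliers (residents less present during breeding,
continuous visitors more present during parental care, periodic
visitors concentrated around breeding) produce the seasonal category
shifts the battery targets. Defaults (322 marked, 180 unmarked birds;
per-session detection 0.5; 13.8% identification failure) were chosen
once to give resighting, correction-factor and flock-size magnitudes of
the same order as a real urban campaign, and are not tuned thereafter.

Detected birds either join a shared foraging point — with age- and
zone-dependent propensity, scattered within 2.5 m of the point so that
groups are detectable under the 5 m chain rule — or forage solo
uniformly in their zone. Covariates (weather, temperature band,
visitor pressure) are drawn independently per day with season-dependent
distributions and are exogenous unless log-linear presence/grouping
effects are configured. Ground truth emitted alongside the records
(true daily flock size, per-bird archetypes) enables the recovery
tests; marked and unmarked birds share one presence/detection process,
which is precisely the estimator's core assumption.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: within-session movement paths,
territoriality and dominance, pair bonds, detection heterogeneity among
individuals or habitats, observer drift, misidentification (identity
errors, as opposed to identification failure), and any mechanistic
weather–presence coupling beyond log-linear modifiers.

**The well-separated recovery cohort.** The classifier-recovery test
uses 80 birds in three archetypes with deliberately separated
parameters (resident presence 0.85; continuous 0.30; periodic on/off
25/80 days with low block-length dispersion, presence 0.8 in
on-blocks; perfect detection). Under geometric block lengths the
periodic class's gap features have a within-class diameter larger than
the resident–continuous separation, and no distance-based clustering
can recover the archetypes reliably — the separation stipulated by the
recovery claim requires regular periodicity, hence the block-length
dispersion parameter. Agreement of at least 0.9 per seed is required
over 20 seeds.

## 7. Problem sizes and numerical choices

The test suite runs the bootstrap battery at reduced iteration counts
(hundreds to a few thousand) and the calibration study at 1000
replicate datasets with single-draw decisions; the full pipeline smoke
run uses the default configuration with 2000 bootstrap iterations and a
five-term subgroup candidate set (32 models) — the ten-term, 1024-model
set is exposed through `subgroup_candidate_terms()` and
`run_config(subgroup_terms = ...)` for real analyses. Convergence of
the battery is asserted as mean-p drift below 0.005 between 5,000 and
10,000 iterations on a fixed dataset. Degenerate inputs are handled
explicitly: an all-tied Friedman block matrix has a zero tie-correction
denominator and is defined as statistic 0 (p = 1); all-zero signed-rank
differences yield no test, with a warning; constant features are
dropped before standardisation; a cohort of identical eligible birds
collapses to a single warned cluster labelled by the documented
days-then-gap rule.

## 8. Known limitations

The estimator is a conservative minimum, not an abundance estimator in
the capture–recapture sense; no detection model is fitted by design.
The category labels are constructs on a residency continuum; $k$ is
fixed, not selected. The bootstrap battery's mean-p decision is
conservative at large iteration counts (Section 4). Subgroup identity
is not tracked over time, so fission/fusion *events* are not detected,
only size distributions. Real-data coefficient tables of the
motivating study are not reproducible without its original dataset;
the package's claims are the structural and recovery properties its
tests compute.
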